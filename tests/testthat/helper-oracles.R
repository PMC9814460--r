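# Shared fixtures and independent oracles.
#
# The oracles deliberately take a different computational route from the
# package (lm() fits, dense grid searches, explicit polyline evaluation)
# so agreement is evidence, not tautology.

# Random harmonized set with L SNPs; two = TRUE adds a second exposure.
random_hset <- function(L, seed, two = FALSE) {
  withr::with_seed(seed, {
    gamma1 <- rnorm(L, 0.1, 0.05)
    gamma1[gamma1 == 0] <- 0.01
    se_g1 <- runif(L, 0.005, 0.02)
    gamma2 <- if (two) rnorm(L, 0.08, 0.05)
    se_g2 <- if (two) runif(L, 0.005, 0.02)
    Gamma <- 0.3 * gamma1 + (if (two) 0.2 * gamma2 else 0) +
      rnorm(L, 0, 0.02)
    se_G <- runif(L, 0.01, 0.05)
    harmonized_set(gamma1 = gamma1, se_g1 = se_g1, Gamma = Gamma,
                   se_G = se_G, gamma2 = gamma2, se_g2 = se_g2)
  })
}

# Weighted-regression oracles via lm(): coefficients and the
# fixed-effect summary-data SEs (lm's sigma divided out), inflated by
# the same max(1, sqrt(rss_w/df)) factor.
oracle_wls <- function(X, y, w, df_resid) {
  fit <- lm(y ~ 0 + X, weights = w)
  b <- unname(coef(fit))
  rss_w <- sum(w * resid(fit)^2)
  xtx_inv <- solve(t(X * w) %*% X)
  infl <- if (df_resid > 0) max(1, sqrt(rss_w / df_resid)) else 1
  list(coef = b, se = unname(sqrt(diag(xtx_inv)) * infl), rss_w = rss_w)
}

oracle_ivw <- function(hs) {
  df <- as.data.frame(hs)
  oracle_wls(cbind(df$gamma1), df$Gamma, 1 / df$se_G^2,
             df_resid = nrow(df) - 1)
}

oracle_egger <- function(hs) {
  df <- as.data.frame(hs)
  flip <- sign(df$gamma1)
  g <- df$gamma1 * flip
  G <- df$Gamma * flip
  oracle_wls(cbind(1, g), G, 1 / df$se_G^2, df_resid = nrow(df) - 2)
}

oracle_mvmr <- function(hs) {
  df <- as.data.frame(hs)
  oracle_wls(cbind(df$gamma1, df$gamma2), df$Gamma, 1 / df$se_G^2,
             df_resid = nrow(df) - 2)
}

# Exhaustive polyline evaluation of the weighted median: build the
# cumulative-weight polyline point by point and solve the 0.5 crossing
# by hand.
oracle_weighted_median <- function(ratios, weights) {
  ord <- order(ratios)
  th <- ratios[ord]
  w <- weights[ord] / sum(weights)
  p <- numeric(length(w))
  acc <- 0
  for (j in seq_along(w)) {
    p[j] <- acc + w[j] / 2
    acc <- acc + w[j]
  }
  if (0.5 <= p[1]) return(th[1])
  if (0.5 >= p[length(p)]) return(th[length(th)])
  for (j in seq_len(length(p) - 1)) {
    if (p[j] <= 0.5 && 0.5 <= p[j + 1]) {
      frac <- (0.5 - p[j]) / (p[j + 1] - p[j])
      return(th[j] + frac * (th[j + 1] - th[j]))
    }
  }
  stop("unreachable")
}

# Dense grid search for the conditional-F nuisance slope.
oracle_conditional_q <- function(hs, which = 1, step = 1e-4,
                                 range = c(-10, 10)) {
  df <- as.data.frame(hs)
  if (which == 1) {
    g <- df$gamma1; se_g <- df$se_g1; h <- df$gamma2; se_h <- df$se_g2
  } else {
    g <- df$gamma2; se_g <- df$se_g2; h <- df$gamma1; se_h <- df$se_g1
  }
  deltas <- seq(range[1], range[2], by = step)
  q <- vapply(deltas, function(d) {
    sum((g - d * h)^2 / (se_g^2 + d^2 * se_h^2))
  }, numeric(1))
  min(q)
}

# Tiny TSV writer for association fixtures.
write_assoc_tsv <- function(df, path = withr::local_tempfile(
                              fileext = ".tsv",
                              .local_envir = parent.frame())) {
  readr::write_tsv(df, path, na = "", progress = FALSE)
  path
}

assoc_fixture <- function(n = 3, seed = 42) {
  withr::with_seed(seed, {
    tibble::tibble(
      rsid = paste0("rs", seq_len(n)),
      effect_allele = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      other_allele = NA_character_,
      eaf = runif(n, 0.1, 0.9),
      beta = rnorm(n, 0, 0.05),
      se = runif(n, 0.005, 0.02),
      pvalue = runif(n),
      n = 10000
    ) -> df
    df$other_allele <- purrr::map_chr(
      df$effect_allele, ~ sample(setdiff(c("A", "C", "G", "T"), .x), 1))
    df
  })
}
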
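# Univariable two-sample MR estimators.
#
# Throughout, gamma1 (exposure beta), Gamma (outcome log-odds beta) and
# their SEs come from a harmonized_set. Causal effects theta are on the
# log-odds-per-category scale; odds ratios are exp(theta). P-values are
# two-sided from the normal distribution, the large-L summary-data
# convention; confidence intervals are theta +/- z_{1-alpha/2} * se.

new_mr_estimate <- function(method, theta, se, n_snp, alpha = 0.05,
                            q_stat = NULL, q_df = NULL,
                            egger_intercept = NULL, egger_intercept_se = NULL,
                            exposure = NULL, outcome = NULL, stratum = NULL) {
  z <- qnorm(1 - alpha / 2)
  est <- list(
    method = method,
    theta = theta, se = se,
    ci_low = theta - z * se, ci_high = theta + z * se,
    pvalue = 2 * pnorm(-abs(theta / se)),
    or = exp(theta), or_low = exp(theta - z * se),
    or_high = exp(theta + z * se),
    n_snp = as.integer(n_snp), alpha = alpha,
    exposure = exposure, outcome = outcome, stratum = stratum
  )
  if (!is.null(q_stat) && !is.null(q_df) && q_df >= 1) {
    est$q_stat <- q_stat
    est$q_df <- q_df
    est$q_pvalue <- pchisq(q_stat, df = q_df, lower.tail = FALSE)
  }
  if (!is.null(egger_intercept)) {
    est$egger_intercept <- egger_intercept
    est$egger_intercept_se <- egger_intercept_se
    est$egger_intercept_pvalue <-
      2 * pnorm(-abs(egger_intercept / egger_intercept_se))
  }
  structure(est, class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s, %d SNP(s)\n", x$method, x$n_snp))
  cat(sprintf("  theta = %.4f (se %.4f), OR = %.3f [%.3f, %.3f], p = %.3g\n",
              x$theta, x$se, x$or, x$or_low, x$or_high, x$pvalue))
  if (!is.null(x$q_stat)) {
    cat(sprintf("  Cochran's Q = %.2f on %d df, p = %.3g\n",
                x$q_stat, x$q_df, x$q_pvalue))
  }
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("  Egger intercept = %.4f (se %.4f), p = %.3g\n",
                x$egger_intercept, x$egger_intercept_se,
                x$egger_intercept_pvalue))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mr_estimate <- function(x, ...) {
  tibble(method = x$method, estimate = x$theta, std.error = x$se,
         conf.low = x$ci_low, conf.high = x$ci_high, p.value = x$pvalue,
         or = x$or, or.low = x$or_low, or.high = x$or_high,
         n_snp = x$n_snp)
}

#' @exportS3Method generics::glance
glance.mr_estimate <- function(x, ...) {
  tibble(method = x$method, n_snp = x$n_snp,
         q_stat = x$q_stat %||% NA_real_,
         q_df = x$q_df %||% NA_integer_,
         q_pvalue = x$q_pvalue %||% NA_real_,
         egger_intercept = x$egger_intercept %||% NA_real_,
         egger_intercept_pvalue = x$egger_intercept_pvalue %||% NA_real_)
}

#' Single-SNP Wald ratio estimate
#'
#' `theta = Gamma / gamma1` with first-order standard error
#' `se = se_G / |gamma1|`.
#'
#' @param set A one-row `harmonized_set` (or any harmonized set; pass
#'   `snp` to pick a row).
#' @param snp Row index or rsid selecting the SNP (default first row).
#' @param alpha Two-sided type-1 error for the confidence interval.
#' @return An `mr_estimate` with method `"wald"`.
#' @export
wald_ratio <- function(set, snp = 1L, alpha = 0.05) {
  df <- as_tibble(as.data.frame(set))
  if (is.character(snp)) snp <- match(snp, df$rsid)
  row <- df[snp, ]
  if (nrow(row) != 1 || is.na(row$gamma1)) abort("no such SNP")
  if (row$gamma1 == 0) abort("exposure beta is zero: Wald ratio undefined")
  new_mr_estimate("wald",
                  theta = row$Gamma / row$gamma1,
                  se = row$se_G / abs(row$gamma1),
                  n_snp = 1L, alpha = alpha)
}

#' Inverse-variance-weighted MR estimate
#'
#' Combines per-SNP Wald ratios with weights `w_j = 1 / se_Gj^2`,
#' equivalently a weighted regression of `Gamma` on `gamma1` through the
#' origin: `theta = sum(w g G) / sum(w g^2)`. The fixed-effect standard
#' error is `(sum w g^2)^{-1/2}`; the multiplicative random-effect model
#' inflates it by `max(1, sqrt(Q / (L - 1)))` where `Q` is Cochran's
#' heterogeneity statistic. In `"auto"` mode the random-effect SE is used
#' when the Q test rejects at `q_alpha`; the point estimate is identical
#' across modes.
#'
#' @param set A `harmonized_set`.
#' @param mode `"auto"` (default), `"fixed"` or `"random"`.
#' @param alpha Two-sided type-1 error for the confidence interval.
#' @param q_alpha Heterogeneity p-value threshold used by `"auto"`.
#' @return An `mr_estimate` with method `"ivw_fixed"` or `"ivw_random"`
#'   and Cochran's Q fields (for `L >= 2`).
#' @export
mr_ivw <- function(set, mode = c("auto", "fixed", "random"),
                   alpha = 0.05, q_alpha = 0.05) {
  mode <- match.arg(mode)
  df <- as_tibble(as.data.frame(set))
  L <- nrow(df)
  if (L < 1) abort("empty harmonized set")
  w <- 1 / df$se_G^2
  s_gg <- sum(w * df$gamma1^2)
  theta <- sum(w * df$gamma1 * df$Gamma) / s_gg
  se_fixed <- 1 / sqrt(s_gg)

  q_stat <- q_df <- NULL
  inflation <- 1
  random <- mode == "random"
  if (L >= 2) {
    q_stat <- sum(w * (df$Gamma - theta * df$gamma1)^2)
    q_df <- L - 1L
    q_p <- pchisq(q_stat, df = q_df, lower.tail = FALSE)
    if (mode == "auto") random <- q_p < q_alpha
    if (random) inflation <- max(1, sqrt(q_stat / q_df))
  } else if (mode == "auto") {
    random <- FALSE
  }

  new_mr_estimate(if (random) "ivw_random" else "ivw_fixed",
                  theta = theta, se = se_fixed * inflation,
                  n_snp = L, alpha = alpha,
                  q_stat = q_stat, q_df = q_df)
}

# Orient records so every exposure-1 beta is positive, flipping the
# outcome (and second-exposure) betas in step. Egger-type fits are not
# invariant to allele orientation; this is the standard convention.
orient_positive <- function(df) {
  flip <- df$gamma1 < 0
  df$gamma1[flip] <- -df$gamma1[flip]
  df$Gamma[flip] <- -df$Gamma[flip]
  if ("gamma2" %in% names(df)) df$gamma2[flip] <- -df$gamma2[flip]
  df
}

# Weighted least squares via the normal equations. Standard errors are
# the fixed-effect (X'WX)^{-1} diagonals inflated by
# max(1, sqrt(rss_w / df_resid)) -- the multiplicative overdispersion
# convention shared by every regression-based estimator here.
wls_fit <- function(X, y, w, df_resid) {
  XtW <- t(X * w)
  xtx <- XtW %*% X
  if (qr(xtx)$rank < ncol(X)) abort("rank-deficient design matrix")
  xtx_inv <- solve(xtx)
  b <- drop(xtx_inv %*% (XtW %*% y))
  resid <- y - drop(X %*% b)
  rss_w <- sum(w * resid^2)
  inflation <- if (df_resid > 0) max(1, sqrt(rss_w / df_resid)) else 1
  se <- sqrt(diag(xtx_inv)) * inflation
  list(coef = b, se = se, rss_w = rss_w, df_resid = df_resid,
       inflation = inflation)
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome betas on the exposure betas with
#' an unconstrained intercept, weights `1 / se_G^2`, after orienting all
#' records so `gamma1 > 0`. The slope is the pleiotropy-adjusted causal
#' estimate; the intercept is the average directional pleiotropic effect,
#' and its test is the directional-pleiotropy (InSIDE) diagnostic.
#' Standard errors carry the multiplicative overdispersion factor
#' `max(1, sqrt(Q_egger / (L - 2)))`.
#'
#' @inheritParams mr_ivw
#' @return An `mr_estimate` with method `"egger"`, residual Q on `L - 2`
#'   df, and the intercept fields.
#' @export
mr_egger <- function(set, alpha = 0.05) {
  df <- as_tibble(as.data.frame(set))
  L <- nrow(df)
  if (L < 3) abort("MR-Egger needs at least 3 SNPs")
  if (any(df$gamma1 == 0)) abort("zero exposure beta cannot be oriented")
  df <- orient_positive(df)
  if (length(unique(df$gamma1)) == 1) {
    abort("degenerate design: all exposure betas equal")
  }
  w <- 1 / df$se_G^2
  fit <- wls_fit(cbind(intercept = 1, slope = df$gamma1), df$Gamma, w,
                 df_resid = L - 2L)
  new_mr_estimate("egger",
                  theta = fit$coef[["slope"]], se = fit$se[[2]],
                  n_snp = L, alpha = alpha,
                  q_stat = fit$rss_w, q_df = L - 2L,
                  egger_intercept = fit$coef[["intercept"]],
                  egger_intercept_se = fit$se[[1]])
}

# Weighted-median point estimate on prepared ratios/weights: sort the
# per-SNP ratios, place each at the midpoint of its normalized cumulative
# weight, and linearly interpolate at probability 1/2.
weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  th <- ratios[ord]
  w <- weights[ord] / sum(weights)
  p <- cumsum(w) - w / 2
  approx(p, th, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted-median MR estimate
#'
#' The weighted median of the per-SNP Wald ratios `Gamma_j / gamma1_j`
#' with weights proportional to `(gamma1_j / se_Gj)^2` (inverse variance
#' of the ratio, to first order). Consistent when up to 50% of the
#' instrument weight comes from invalid instruments. The standard error is
#' a parametric bootstrap: exposure and outcome betas are resampled from
#' `Normal(beta, se)` and the median recomputed, under a caller-supplied
#' seed so results are reproducible.
#'
#' @inheritParams mr_ivw
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap (required).
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(set, n_boot = 1000, seed, alpha = 0.05) {
  if (missing(seed) || is.null(seed)) {
    abort("a seed is required for the weighted-median bootstrap")
  }
  df <- as_tibble(as.data.frame(set))
  L <- nrow(df)
  if (L < 3) abort("weighted median needs at least 3 SNPs")
  if (any(df$gamma1 == 0)) abort("zero exposure beta: ratio undefined")

  point <- weighted_median_point(df$Gamma / df$gamma1,
                                 (df$gamma1 / df$se_G)^2)
  boot <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(i) {
      g <- rnorm(L, df$gamma1, df$se_g1)
      G <- rnorm(L, df$Gamma, df$se_G)
      g[g == 0] <- .Machine$double.eps
      weighted_median_point(G / g, (g / df$se_G)^2)
    }, numeric(1))
  })
  new_mr_estimate("weighted_median", theta = point, se = sd(boot),
                  n_snp = L, alpha = alpha)
}

#' Between-stratum heterogeneity of MR estimates
#'
#' Cochran-type chi-squared test comparing estimates across strata (e.g.
#' men vs women, or anatomical subsites): the estimates are pooled by
#' inverse variance and `Q = sum((theta_s - pooled)^2 / se_s^2)` is
#' referred to chi-squared on `S - 1` degrees of freedom.
#'
#' @param estimates A data frame with columns `theta` and `se` (and
#'   optionally `label`), or a list of `mr_estimate` objects.
#' @return A one-row tibble: `q_stat`, `df`, `pvalue`, `pooled_theta`.
#' @examples
#' # men vs women direct effects back-computed from printed CIs
#' subgroup_heterogeneity(tibble::tibble(
#'   theta = log(c(1.75, 0.83)),
#'   se = c(se_from_ci(1.07, 2.89), se_from_ci(0.54, 1.25))))
#' @export
subgroup_heterogeneity <- function(estimates) {
  if (is.list(estimates) && !is.data.frame(estimates) &&
      all(purrr::map_lgl(estimates, inherits, "mr_estimate"))) {
    estimates <- purrr::map_dfr(estimates,
                                ~ tibble(theta = .x$theta, se = .x$se))
  }
  df <- as_tibble(estimates)
  if (nrow(df) < 2) abort("need at least 2 estimates")
  if (any(!is.finite(df$se)) || any(df$se <= 0)) {
    abort("all standard errors must be finite and positive")
  }
  w <- 1 / df$se^2
  pooled <- sum(w * df$theta) / sum(w)
  q <- sum(w * (df$theta - pooled)^2)
  k <- nrow(df) - 1L
  tibble(q_stat = q, df = k,
         pvalue = pchisq(q, df = k, lower.tail = FALSE),
         pooled_theta = pooled)
}

#' Standard error of a log odds ratio from a printed confidence interval
#'
#' `se = (log(hi) - log(lo)) / (2 z)`, the back-computation used when only
#' an OR with its 95% CI is reported.
#'
#' @param lo,hi Confidence bounds on the OR scale.
#' @param level Confidence level of the interval (default 0.95).
#' @return The standard error on the log-odds scale.
#' @export
se_from_ci <- function(lo, hi, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  (log(hi) - log(lo)) / (2 * z)
}
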
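# Seeded generators of two-sample MR summary statistics.
#
# The summary path draws per-SNP true effects on two correlated exposures,
# builds outcome log-odds effects from configurable direct effects plus
# optional pleiotropy, and adds sampling noise at the configured GWAS
# sizes. The individual-level path simulates genotypes, three-category
# exposures cut from latent traits, and a logistic outcome; it is slower
# and serves as an oracle for the summary path and the power formula.

#' Configuration for a simulated two-sample MR study
#'
#' Defaults emulate the motivating study design: two exposures whose
#' per-SNP genetic effects correlate at 0.61, instruments explaining 4.5%
#' and 6.4% of trait variance, an exposure GWAS of 453,169, and an outcome
#' case-control sample of 52,775 cases and 45,940 controls.
#'
#' @param n_snps Number of independent instrument SNPs.
#' @param maf_range Minor-allele-frequency interval, within `(0, 0.5]`.
#' @param rho Correlation of true per-SNP effects on the two exposures.
#' @param theta1,theta2 True direct log-odds effects per category of
#'   exposures 1 and 2 on the outcome.
#' @param pleio_mean,pleio_sd Mean and SD of per-SNP direct (pleiotropic)
#'   effects on the outcome; `(0, 0)` disables pleiotropy.
#' @param n_exposure_gwas Exposure discovery sample size.
#' @param n_cases,n_controls Outcome case/control counts.
#' @param r2_target_1,r2_target_2 Fraction of each exposure's variance the
#'   instrument explains; realized per-SNP effects are scaled to meet
#'   these exactly.
#' @param category_cuts Latent-percentile cut points defining the three
#'   ordered exposure categories in the individual-level path.
#' @param seed Integer seed; identical seed and config give byte-identical
#'   output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 300, maf_range = c(0.05, 0.5),
                       rho = 0.61, theta1 = 0, theta2 = log(1.3),
                       pleio_mean = 0, pleio_sd = 0,
                       n_exposure_gwas = 453169,
                       n_cases = 52775, n_controls = 45940,
                       r2_target_1 = 0.045, r2_target_2 = 0.064,
                       category_cuts = c(0.25, 0.75), seed = 1) {
  cfg <- list(n_snps = as.integer(n_snps), maf_range = maf_range,
              rho = rho, theta1 = theta1, theta2 = theta2,
              pleio_mean = pleio_mean, pleio_sd = pleio_sd,
              n_exposure_gwas = n_exposure_gwas,
              n_cases = n_cases, n_controls = n_controls,
              r2_target_1 = r2_target_1, r2_target_2 = r2_target_2,
              category_cuts = category_cuts, seed = as.integer(seed))
  if (cfg$n_snps < 1) abort("n_snps must be positive")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort("maf_range must be an interval within (0, 0.5]")
  }
  if (abs(rho) > 1) abort("rho must lie in [-1, 1]")
  if (any(c(cfg$n_exposure_gwas, cfg$n_cases, cfg$n_controls) <= 0)) {
    abort("sample sizes must be positive")
  }
  if (any(c(r2_target_1, r2_target_2) <= 0) ||
      any(c(r2_target_1, r2_target_2) >= 1)) {
    abort("r2 targets must lie in (0, 1)")
  }
  if (pleio_sd < 0) abort("pleio_sd must be non-negative")
  structure(cfg, class = "sim_config")
}

#' Simulate summary statistics for a two-sample MR study
#'
#' Per-SNP true exposure effects `(g1, g2)` are bivariate normal with
#' correlation `rho`, each column rescaled so the instrumented variance
#' `sum 2 maf (1 - maf) g^2` equals its target. True outcome log-odds
#' effects are `theta1 g1 + theta2 g2 + pleiotropy`. Observed betas add
#' Normal sampling noise with `se = sqrt(1 / (2 maf (1 - maf) N))` on the
#' exposure side and
#' `se = sqrt((1/n_cases + 1/n_controls) / (2 maf (1 - maf)))` on the
#' outcome side. Emitted tables follow the canonical schema; effect
#' alleles are oriented so the observed exposure-1 beta is positive.
#'
#' @param config A [sim_config()].
#' @return A list of class `simulated_study`: `exposure1`, `exposure2`,
#'   `outcome` (instrument sets), `truth` (per-SNP tibble of realized true
#'   values), and `config`.
#' @examples
#' study <- simulate_mr_summary(sim_config(n_snps = 50, seed = 7))
#' hs <- harmonize(study$exposure1, study$outcome)
#' mr_ivw(hs)
#' @export
simulate_mr_summary <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_mr_summary_impl(config))
}

simulate_mr_summary_impl <- function(cfg) {
  L <- cfg$n_snps
  maf <- runif(L, cfg$maf_range[1], cfg$maf_range[2])
  v <- 2 * maf * (1 - maf)

  z1 <- rnorm(L)
  z2 <- cfg$rho * z1 + sqrt(1 - cfg$rho^2) * rnorm(L)
  g1 <- z1 * sqrt(cfg$r2_target_1 / sum(v * z1^2))
  g2 <- z2 * sqrt(cfg$r2_target_2 / sum(v * z2^2))
  if (max(v * g1^2) >= 1 || max(v * g2^2) >= 1) {
    abort("infeasible r2 target for this n_snps / maf_range")
  }

  pleio <- if (cfg$pleio_sd > 0 || cfg$pleio_mean != 0) {
    rnorm(L, cfg$pleio_mean, cfg$pleio_sd)
  } else {
    rep(0, L)
  }
  Gamma_true <- cfg$theta1 * g1 + cfg$theta2 * g2 + pleio

  se1 <- sqrt(1 / (v * cfg$n_exposure_gwas))
  se2 <- se1
  se_G <- sqrt((1 / cfg$n_cases + 1 / cfg$n_controls) / v)

  b1 <- rnorm(L, g1, se1)
  b2 <- rnorm(L, g2, se2)
  bG <- rnorm(L, Gamma_true, se_G)

  rsid <- sprintf("rs%06d", seq_len(L))
  pairs <- matrix(c("A", "G", "C", "T", "A", "C", "G", "T"),
                  ncol = 2, byrow = TRUE)
  pick <- sample.int(nrow(pairs), L, replace = TRUE)
  ea <- pairs[pick, 1]
  oa <- pairs[pick, 2]
  eaf <- maf

  # orientation convention: effect allele increases exposure 1; the
  # truth table keeps the orientation sign so the unfolded effects
  # (g * orient) retain the generated joint distribution
  flip <- b1 < 0
  tmp <- ea[flip]; ea[flip] <- oa[flip]; oa[flip] <- tmp
  eaf[flip] <- 1 - eaf[flip]
  sgn <- ifelse(flip, -1, 1)
  b1 <- b1 * sgn; b2 <- b2 * sgn; bG <- bG * sgn
  g1 <- g1 * sgn; g2 <- g2 * sgn
  Gamma_true <- Gamma_true * sgn; pleio <- pleio * sgn

  mk <- function(beta, se, name, stratum, r2, n) {
    instrument_set(
      tibble(rsid = rsid, effect_allele = ea, other_allele = oa,
             eaf = eaf, beta = beta, se = se,
             pvalue = 2 * pnorm(-abs(beta / se)), n = n),
      exposure_name = name, stratum = stratum, r_squared = r2, n_gwas = n)
  }

  structure(list(
    exposure1 = mk(b1, se1, "exposure1", "overall", cfg$r2_target_1,
                   cfg$n_exposure_gwas),
    exposure2 = mk(b2, se2, "exposure2", "overall", cfg$r2_target_2,
                   cfg$n_exposure_gwas),
    outcome = mk(bG, se_G, "outcome", "overall", NULL,
                 cfg$n_cases + cfg$n_controls),
    truth = tibble(rsid = rsid, maf = maf, g1 = g1, g2 = g2,
                   pleio = pleio, Gamma_true = Gamma_true,
                   orient = sgn),
    config = cfg
  ), class = "simulated_study")
}

#' Simulate a two-sample MR study at the individual level
#'
#' The slow oracle path. Exposure sample: genotypes `Binomial(2, maf)`,
#' two latent continuous traits built from correlated per-SNP genetic
#' effects (latent-scale variance targets `r2_target_*`) plus independent
#' unit-variance-completing noise, each cut into three ordered categories
#' at the configured latent percentiles; per-SNP GWAS betas come from
#' simple linear regressions of category on genotype. Outcome sample: an
#' independent draw of `n_cases + n_controls` individuals with a logistic
#' outcome `logit p = a + theta1 (cat1 - 1) + theta2 (cat2 - 1) + G pleio`
#' (`a` set from the case fraction); per-SNP log-odds betas come from
#' linear-probability regressions rescaled by `1 / (K (1 - K))`.
#'
#' Because the GWAS is run on the category scale, emitted exposure betas
#' are attenuated relative to the latent per-allele effects by the
#' category-on-latent projection slope; causal-effect estimates are on
#' the per-category scale either way, so the two paths agree on theta.
#'
#' @param config A [sim_config()]. Total simulated individuals
#'   (`n_exposure_gwas + n_cases + n_controls`) must not exceed 1e6.
#' @return A `simulated_study` (see [simulate_mr_summary()]); `truth`
#'   reports latent-scale effects `g1`, `g2` and the category-projection
#'   slope.
#' @export
simulate_mr_individual <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  total <- config$n_exposure_gwas + config$n_cases + config$n_controls
  if (total > 1e6) {
    abort("individual-level path capped at 1e6 total individuals")
  }
  if (total * config$n_snps > 2e8) {
    abort("genotype matrix would exceed the memory guard")
  }
  withr::with_seed(config$seed, simulate_mr_individual_impl(config))
}

simulate_mr_individual_impl <- function(cfg) {
  L <- cfg$n_snps
  maf <- runif(L, cfg$maf_range[1], cfg$maf_range[2])
  v <- 2 * maf * (1 - maf)

  z1 <- rnorm(L)
  z2 <- cfg$rho * z1 + sqrt(1 - cfg$rho^2) * rnorm(L)
  g1 <- z1 * sqrt(cfg$r2_target_1 / sum(v * z1^2))
  g2 <- z2 * sqrt(cfg$r2_target_2 / sum(v * z2^2))

  draw_genotypes <- function(n) {
    matrix(rbinom(n * L, 2, rep(maf, each = n)), nrow = n)
  }
  categorize <- function(latent) {
    cuts <- quantile(latent, cfg$category_cuts)
    findInterval(latent, cuts)
  }
  latent_pair <- function(G) {
    e1 <- rnorm(nrow(G), 0, sqrt(max(1 - cfg$r2_target_1, 1e-12)))
    e2 <- rnorm(nrow(G), 0, sqrt(max(1 - cfg$r2_target_2, 1e-12)))
    list(l1 = drop(G %*% g1) + e1, l2 = drop(G %*% g2) + e2)
  }
  # vectorized per-SNP simple regressions of y on each genotype column
  gwas <- function(G, y) {
    g_mean <- colMeans(G)
    g_var <- colMeans(G^2) - g_mean^2
    beta <- (colMeans(G * y) - g_mean * mean(y)) / g_var
    resid_var <- pmax(var(y) - beta^2 * g_var, 1e-12)
    se <- sqrt(resid_var / (nrow(G) * g_var))
    list(beta = beta, se = se)
  }

  # exposure GWAS
  Gx <- draw_genotypes(cfg$n_exposure_gwas)
  lat <- latent_pair(Gx)
  cat1 <- categorize(lat$l1)
  cat2 <- categorize(lat$l2)
  gw1 <- gwas(Gx, cat1)
  gw2 <- gwas(Gx, cat2)
  proj_slope <- unname(coef(lm(cat1 ~ lat$l1))[2])

  # outcome sample
  n_out <- cfg$n_cases + cfg$n_controls
  k_target <- cfg$n_cases / n_out
  Gy <- draw_genotypes(n_out)
  laty <- latent_pair(Gy)
  c1y <- categorize(laty$l1)
  c2y <- categorize(laty$l2)
  pleio <- if (cfg$pleio_sd > 0 || cfg$pleio_mean != 0) {
    rnorm(L, cfg$pleio_mean, cfg$pleio_sd)
  } else {
    rep(0, L)
  }
  eta <- log(k_target / (1 - k_target)) +
    cfg$theta1 * (c1y - 1) + cfg$theta2 * (c2y - 1) +
    drop(Gy %*% pleio)
  y <- rbinom(n_out, 1, stats::plogis(eta))
  k_hat <- min(max(mean(y), 1e-6), 1 - 1e-6)
  gwy <- gwas(Gy, y)
  scale <- 1 / (k_hat * (1 - k_hat))

  rsid <- sprintf("rs%06d", seq_len(L))
  mk <- function(beta, se, name, n) {
    instrument_set(
      tibble(rsid = rsid, effect_allele = "A", other_allele = "G",
             eaf = maf, beta = beta, se = se,
             pvalue = 2 * pnorm(-abs(beta / se)), n = n),
      exposure_name = name, n_gwas = n)
  }

  structure(list(
    exposure1 = mk(gw1$beta, gw1$se, "exposure1", cfg$n_exposure_gwas),
    exposure2 = mk(gw2$beta, gw2$se, "exposure2", cfg$n_exposure_gwas),
    outcome = mk(gwy$beta * scale, gwy$se * scale, "outcome", n_out),
    truth = tibble(rsid = rsid, maf = maf, g1 = g1, g2 = g2,
                   pleio = pleio, proj_slope = proj_slope,
                   Gamma_true = cfg$theta1 * proj_slope * g1 +
                     cfg$theta2 * proj_slope * g2 + pleio),
    config = cfg
  ), class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<simulated_study> %d SNPs, rho = %.2f, theta = (%.3f, %.3f), seed = %d\n",
    cfg$n_snps, cfg$rho, cfg$theta1, cfg$theta2, cfg$seed))
  invisible(x)
}

#' Write a simulated study's tables as canonical TSVs
#'
#' Emits `exposure1.tsv`, `exposure2.tsv`, `outcome.tsv` and `truth.tsv`
#' under `dir`.
#'
#' @param study A `simulated_study`.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_simulated_study <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_associations(study$exposure1, file.path(dir, "exposure1.tsv"))
  write_associations(study$exposure2, file.path(dir, "exposure2.tsv"))
  write_associations(study$outcome, file.path(dir, "outcome.tsv"))
  readr::write_tsv(study$truth, file.path(dir, "truth.tsv"),
                   progress = FALSE)
  invisible(dir)
}

#' Harmonized set straight from a simulated study
#'
#' @param study A `simulated_study`.
#' @param exposures 1 (first exposure only) or 2.
#' @return A `harmonized_set`.
#' @export
harmonize_simulated <- function(study, exposures = 2) {
  stopifnot(inherits(study, "simulated_study"))
  harmonize(study$exposure1, study$outcome,
            exposure2 = if (exposures == 2) study$exposure2)
}
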
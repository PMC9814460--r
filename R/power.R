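# A priori analytic power for binary-outcome two-sample MR, plus an
# individual-level simulation oracle used to validate the approximation.

#' Analytic power for binary-outcome MR
#'
#' Two-stage normal approximation: with total outcome sample `N`, case
#' fraction `K`, instrument variance explained `R^2` and per-category
#' odds ratio `OR`, the noncentrality is
#' `z = |log(OR)| * sqrt(N R^2 K (1 - K))` and
#' `power = Phi(z - z_{1 - alpha/2})`. Vectorized over all arguments.
#'
#' @param n_cases,n_controls Outcome case/control counts.
#' @param r_squared Fraction of exposure variance explained by the
#'   instrument, in `(0, 1)`.
#' @param odds_ratio Per-category effect size to detect, `> 0`.
#' @param alpha Two-sided type-1 error (default 0.05).
#' @return Power as a fraction in `(0, 1)`.
#' @examples
#' mr_power_binary(52775, 45940, r_squared = 0.045, odds_ratio = 1.10)
#' @export
mr_power_binary <- function(n_cases, n_controls, r_squared, odds_ratio,
                            alpha = 0.05) {
  if (any(n_cases <= 0 | n_controls <= 0)) abort("counts must be positive")
  if (any(r_squared <= 0 | r_squared >= 1)) {
    abort("r_squared must lie in (0, 1)")
  }
  if (any(odds_ratio <= 0)) abort("odds_ratio must be positive")
  if (any(alpha <= 0 | alpha >= 1)) abort("alpha must lie in (0, 1)")
  n <- n_cases + n_controls
  k <- n_cases / n
  z <- abs(log(odds_ratio)) * sqrt(n * r_squared * k * (1 - k))
  pnorm(z - qnorm(1 - alpha / 2))
}

#' Minimum detectable odds ratio at a target power
#'
#' Smallest `OR > 1` whose analytic power reaches `target_power`, found by
#' bisection on the odds ratio to within 1e-6.
#'
#' @inheritParams mr_power_binary
#' @param target_power Required power, in `(alpha, 1)`.
#' @return The minimum detectable odds ratio.
#' @examples
#' min_detectable_or(52775, 45940, r_squared = 0.064)
#' @export
min_detectable_or <- function(n_cases, n_controls, r_squared,
                              target_power = 0.8, alpha = 0.05) {
  if (target_power <= alpha || target_power >= 1) {
    abort("target_power must lie in (alpha, 1)")
  }
  p_at <- function(or) mr_power_binary(n_cases, n_controls, r_squared,
                                       or, alpha)
  lo <- 1
  hi <- 1.5
  while (p_at(hi) < target_power) hi <- hi * 2
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (p_at(mid) >= target_power) hi <- mid else lo <- mid
  }
  hi
}

#' Power over a grid of odds ratios
#'
#' @inheritParams mr_power_binary
#' @param or_grid Odds ratios to evaluate (default 1.05 to 1.50 by 0.05).
#' @return A tibble of class `mr_power_curve` with columns `odds_ratio`
#'   and `power`.
#' @export
mr_power_curve <- function(n_cases, n_controls, r_squared,
                           or_grid = seq(1.05, 1.50, by = 0.05),
                           alpha = 0.05) {
  structure(
    tibble(odds_ratio = or_grid,
           power = mr_power_binary(n_cases, n_controls, r_squared,
                                   or_grid, alpha)),
    class = c("mr_power_curve", class(tibble())))
}

#' Empirical power by individual-level simulation through IVW
#'
#' The oracle behind the analytic formula: for each replicate an outcome
#' sample is simulated at the individual level (genotypes, a
#' unit-variance exposure with the requested instrumented variance, a
#' logistic outcome with effect `log(odds_ratio)` per exposure unit), the
#' per-SNP log-odds associations are estimated, and the IVW test of the
#' causal effect is run against two-sided `alpha`. Exposure-side betas
#' are the truth plus Normal noise at the exposure-GWAS sample size.
#' The rejection frequency estimates power.
#'
#' Per-SNP log-odds betas are obtained from a linear-probability
#' regression rescaled by `1 / (K (1 - K))`, the standard small-effect
#' equivalence; per-SNP effects here are far inside its validity range.
#'
#' @inheritParams mr_power_binary
#' @param n_snps Number of independent instrument SNPs (default 25).
#' @param n_exposure_gwas Exposure discovery sample size used for the
#'   exposure-beta noise (default 453169).
#' @param n_reps Number of simulation replicates.
#' @param seed Integer seed.
#' @return A list: `power` (rejection rate), `n_reps`, `mc_se` (binomial
#'   Monte-Carlo standard error).
#' @export
mr_power_empirical <- function(n_cases, n_controls, r_squared, odds_ratio,
                               alpha = 0.05, n_snps = 25,
                               n_exposure_gwas = 453169,
                               n_reps = 2000, seed) {
  if (missing(seed)) abort("a seed is required")
  n_out <- n_cases + n_controls
  if (n_out * n_snps > 5e8) abort("simulation size guard exceeded")
  theta <- log(odds_ratio)
  k_target <- n_cases / n_out

  rej <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_reps), function(rep) {
      sim <- simulate_power_cohort(
        n = n_out, n_snps = n_snps, r_squared = r_squared,
        maf_range = c(0.1, 0.4), theta = theta, k_target = k_target)
      # exposure betas: truth + GWAS-scale noise (two-sample design)
      se_x <- sqrt(1 / (2 * sim$maf * (1 - sim$maf) * n_exposure_gwas))
      gamma_hat <- rnorm(n_snps, sim$gamma, se_x)
      hs <- harmonized_set(gamma1 = gamma_hat, se_g1 = se_x,
                           Gamma = sim$beta_logit, se_G = sim$se_logit)
      est <- mr_ivw(hs, mode = "fixed")
      est$pvalue < alpha
    }, logical(1))
  })
  p <- mean(rej)
  list(power = p, n_reps = n_reps,
       mc_se = sqrt(p * (1 - p) / n_reps))
}

# One individual-level outcome-sample draw for the power oracle: a
# unit-variance exposure (genetic score explaining r_squared, plus
# noise), a logistic outcome, and vectorized per-SNP associations.
simulate_power_cohort <- function(n, n_snps, r_squared, maf_range,
                                  theta, k_target) {
  maf <- runif(n_snps, maf_range[1], maf_range[2])
  v <- 2 * maf * (1 - maf)
  g <- rnorm(n_snps)
  g <- g * sqrt(r_squared / sum(v * g^2))

  G <- matrix(rbinom(n * n_snps, 2, rep(maf, each = n)), nrow = n)
  exposure <- drop(G %*% g) +
    rnorm(n, 0, sqrt(max(1 - r_squared, 1e-12)))

  eta <- log(k_target / (1 - k_target)) +
    theta * (exposure - mean(exposure))
  y <- rbinom(n, 1, stats::plogis(eta))
  k_hat <- min(max(mean(y), 1e-6), 1 - 1e-6)

  # per-SNP linear-probability regressions, vectorized
  g_mean <- colMeans(G)
  g_var <- colMeans(G^2) - g_mean^2
  beta_lin <- (colMeans(G * y) - g_mean * k_hat) / g_var
  resid_var <- k_hat * (1 - k_hat)           # null-dominated residual
  se_lin <- sqrt(resid_var / (n * g_var))
  scale <- 1 / (k_hat * (1 - k_hat))

  list(maf = maf, gamma = g,
       beta_logit = beta_lin * scale,
       se_logit = se_lin * scale)
}
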
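# Multivariable MR: direct effects of two correlated exposures, with
# conditional instrument-strength and pleiotropy diagnostics.

new_mvmr_fit <- function(method, coefs, ses, L, df_resid, rss_w, alpha,
                         intercept = NULL, intercept_se = NULL) {
  z <- qnorm(1 - alpha / 2)
  terms <- tibble(
    term = names(coefs),
    estimate = unname(coefs), std.error = unname(ses),
    conf.low = unname(coefs - z * ses), conf.high = unname(coefs + z * ses),
    p.value = 2 * pnorm(-abs(unname(coefs / ses))),
    or = exp(unname(coefs)), or.low = exp(unname(coefs - z * ses)),
    or.high = exp(unname(coefs + z * ses))
  )
  structure(list(method = method, terms = terms, n_snp = as.integer(L),
                 df_resid = df_resid, rss_w = rss_w, alpha = alpha,
                 intercept = intercept, intercept_se = intercept_se,
                 intercept_pvalue = if (!is.null(intercept))
                   2 * pnorm(-abs(intercept / intercept_se))),
            class = "mvmr_fit")
}

#' @export
print.mvmr_fit <- function(x, ...) {
  cat(sprintf("<mvmr_fit> %s, %d SNPs\n", x$method, x$n_snp))
  for (i in seq_len(nrow(x$terms))) {
    r <- x$terms[i, ]
    cat(sprintf("  %s: theta = %.4f (se %.4f), OR = %.3f [%.3f, %.3f], p = %.3g\n",
                r$term, r$estimate, r$std.error, r$or, r$or.low, r$or.high,
                r$p.value))
  }
  if (!is.null(x$intercept)) {
    cat(sprintf("  intercept = %.4f (se %.4f), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_pvalue))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mvmr_fit <- function(x, ...) {
  dplyr::mutate(x$terms, method = x$method, n_snp = x$n_snp,
                .before = 1)
}

#' @exportS3Method generics::glance
glance.mvmr_fit <- function(x, ...) {
  tibble(method = x$method, n_snp = x$n_snp, rss_w = x$rss_w,
         df_resid = x$df_resid,
         intercept = x$intercept %||% NA_real_,
         intercept_pvalue = x$intercept_pvalue %||% NA_real_)
}

#' Multivariable IVW estimate of direct effects
#'
#' Weighted least squares of the outcome betas on the two exposure beta
#' columns with no intercept, weights `1 / se_G^2`. The coefficients are
#' the direct effects of each exposure conditional on the other; standard
#' errors carry the multiplicative overdispersion factor
#' `max(1, sqrt(rss_w / (L - 2)))`.
#'
#' @param set A `harmonized_set` with two exposures.
#' @param alpha Two-sided type-1 error for confidence intervals.
#' @return An `mvmr_fit` with terms `exposure1` and `exposure2`; use
#'   [tidy()] for a per-term tibble.
#' @export
mvmr_ivw <- function(set, alpha = 0.05) {
  df <- require_two_exposures(set)
  L <- nrow(df)
  if (L < 3) abort("multivariable IVW needs at least 3 SNPs")
  w <- 1 / df$se_G^2
  X <- cbind(exposure1 = df$gamma1, exposure2 = df$gamma2)
  fit <- wls_fit(X, df$Gamma, w, df_resid = L - 2L)
  new_mvmr_fit("mvmr_ivw", setNames(fit$coef, colnames(X)),
               setNames(fit$se, colnames(X)), L = L,
               df_resid = fit$df_resid, rss_w = fit$rss_w, alpha = alpha)
}

#' Multivariable MR-Egger
#'
#' Adds an unconstrained intercept to the multivariable IVW regression
#' after orienting records so all first-exposure betas are positive. The
#' intercept test probes directional pleiotropy not captured by either
#' exposure; the slopes are pleiotropy-adjusted direct effects. Residual
#' degrees of freedom are `L - 3`.
#'
#' @inheritParams mvmr_ivw
#' @return An `mvmr_fit` with intercept fields.
#' @export
mvmr_egger <- function(set, alpha = 0.05) {
  df <- require_two_exposures(set)
  L <- nrow(df)
  if (L < 4) abort("multivariable MR-Egger needs at least 4 SNPs")
  df <- orient_positive(df)
  w <- 1 / df$se_G^2
  X <- cbind(intercept = 1, exposure1 = df$gamma1, exposure2 = df$gamma2)
  fit <- wls_fit(X, df$Gamma, w, df_resid = L - 3L)
  new_mvmr_fit("mvmr_egger",
               setNames(fit$coef[-1], c("exposure1", "exposure2")),
               setNames(fit$se[-1], c("exposure1", "exposure2")),
               L = L, df_resid = fit$df_resid, rss_w = fit$rss_w,
               alpha = alpha,
               intercept = fit$coef[[1]], intercept_se = fit$se[[1]])
}

#' Conditional F-statistic for one exposure given the other
#'
#' Measures how much instrument signal remains for one exposure after
#' projecting out the other. The statistic minimizes
#' `Q_x(delta) = sum_j (g_j - delta h_j)^2 /
#'   (se_g_j^2 + delta^2 se_h_j^2 - 2 delta cov_j)`
#' over the nuisance slope `delta` (bounded scalar minimization), where
#' `g` is the exposure of interest and `h` the other; the conditional F is
#' `Q_x(delta_hat) / (L - 1)`. Values below 10 flag conditionally weak
#' instruments.
#'
#' @param set A `harmonized_set` with two exposures.
#' @param which Exposure of interest, `1` or `2`.
#' @param cross_cov Per-SNP sampling covariance between the two exposure
#'   betas (scalar or vector, default 0). See `cov_correlation` in
#'   [conditional_strength()] for the shared-sample correction.
#' @param bounds Search interval for `delta` (default `c(-100, 100)`).
#' @param tol Convergence tolerance of the minimization (default 1e-8).
#' @return A list: `f_cond`, `delta` (minimizer), `q_x` (minimized Q),
#'   `n_snp`.
#' @export
conditional_f <- function(set, which = 1, cross_cov = 0,
                          bounds = c(-100, 100), tol = 1e-8) {
  df <- require_two_exposures(set)
  L <- nrow(df)
  if (L < 2) abort("conditional F needs at least 2 SNPs")
  if (which == 1) {
    g <- df$gamma1; se_g <- df$se_g1
    h <- df$gamma2; se_h <- df$se_g2
  } else {
    g <- df$gamma2; se_g <- df$se_g2
    h <- df$gamma1; se_h <- df$se_g1
  }
  cov_j <- rep_len(cross_cov, L)
  q_x <- function(delta) {
    denom <- se_g^2 + delta^2 * se_h^2 - 2 * delta * cov_j
    if (any(denom <= 0)) return(Inf)
    sum((g - delta * h)^2 / denom)
  }
  opt <- optimize(q_x, interval = bounds, tol = tol)
  if (!is.finite(opt$objective)) {
    abort("conditional F minimization failed: non-finite objective")
  }
  # When the other exposure carries no signal the objective has no
  # interior minimum (larger |delta| only inflates the denominator) and
  # the minimizer drifts to the search boundary. delta is then not
  # identified; fall back to the weighted projection slope of g on h
  # (zero when h is null), which restores the unconditional statistic.
  span <- diff(bounds)
  at_boundary <- min(opt$minimum - bounds[1], bounds[2] - opt$minimum) <
    0.01 * span
  if (at_boundary) {
    s_hh <- sum(h^2 / se_g^2)
    delta <- if (s_hh > 0) sum(g * h / se_g^2) / s_hh else 0
    return(list(f_cond = q_x(delta) / (L - 1), delta = delta,
                q_x = q_x(delta), n_snp = L))
  }
  list(f_cond = opt$objective / (L - 1), delta = opt$minimum,
       q_x = opt$objective, n_snp = L)
}

#' Q_a pleiotropy statistic for a multivariable fit
#'
#' Heterogeneity of the outcome betas around the fitted two-exposure
#' model, with a denominator that propagates both exposure-beta and
#' outcome-beta sampling error:
#' `Q_a = sum_j (Gamma_j - t1 g1j - t2 g2j)^2 /
#'   (se_G^2 + t1^2 se_g1^2 + t2^2 se_g2^2)`,
#' referred to chi-squared on `L - 2` degrees of freedom. High values
#' indicate heterogeneity and potential pleiotropy even after
#' conditioning on the second exposure.
#'
#' @param set The `harmonized_set` the fit was produced from.
#' @param fit An `mvmr_fit` from [mvmr_ivw()] on the same set.
#' @return A one-row tibble: `q_a`, `df`, `pvalue`.
#' @export
mvmr_qa <- function(set, fit) {
  df <- require_two_exposures(set)
  if (!inherits(fit, "mvmr_fit")) abort("fit must be an mvmr_fit")
  if (fit$n_snp != nrow(df)) {
    abort("fit was not produced from this harmonized set")
  }
  t1 <- fit$terms$estimate[fit$terms$term == "exposure1"]
  t2 <- fit$terms$estimate[fit$terms$term == "exposure2"]
  resid <- df$Gamma - t1 * df$gamma1 - t2 * df$gamma2
  denom <- df$se_G^2 + t1^2 * df$se_g1^2 + t2^2 * df$se_g2^2
  q <- sum(resid^2 / denom)
  k <- nrow(df) - 2L
  tibble(q_a = q, df = k, pvalue = pchisq(q, df = k, lower.tail = FALSE))
}

#' Conditional instrument strength and pleiotropy report
#'
#' Bundles the three multivariable diagnostics: conditional F for each
#' exposure and the Q_a statistic of the IVW fit.
#'
#' @inheritParams mvmr_ivw
#' @param cov_correlation Optional scalar phenotypic correlation `r`
#'   between the two exposures measured in the same sample; when nonzero
#'   the per-SNP sampling covariance is taken as `r * se_g1 * se_g2`.
#'   Default 0 (no correction).
#' @param fit Optional precomputed [mvmr_ivw()] fit.
#' @return A list of class `conditional_strength`: `f_cond_1`, `f_cond_2`,
#'   `delta_1`, `delta_2`, `q_a`, `q_a_df`, `q_a_pvalue`, `n_snp`.
#' @export
conditional_strength <- function(set, cov_correlation = 0, fit = NULL) {
  df <- require_two_exposures(set)
  cov_j <- cov_correlation * df$se_g1 * df$se_g2
  c1 <- conditional_f(set, which = 1, cross_cov = cov_j)
  c2 <- conditional_f(set, which = 2, cross_cov = cov_j)
  fit <- fit %||% mvmr_ivw(set)
  qa <- mvmr_qa(set, fit)
  structure(list(f_cond_1 = c1$f_cond, f_cond_2 = c2$f_cond,
                 delta_1 = c1$delta, delta_2 = c2$delta,
                 q_a = qa$q_a, q_a_df = qa$df, q_a_pvalue = qa$pvalue,
                 n_snp = nrow(df)),
            class = "conditional_strength")
}

#' @export
print.conditional_strength <- function(x, ...) {
  cat(sprintf("<conditional_strength> %d SNPs\n", x$n_snp))
  cat(sprintf("  conditional F: exposure1 = %.2f, exposure2 = %.2f\n",
              x$f_cond_1, x$f_cond_2))
  cat(sprintf("  Q_a = %.2f on %d df, p = %.3g\n",
              x$q_a, x$q_a_df, x$q_a_pvalue))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.conditional_strength <- function(x, ...) {
  tibble(statistic = c("f_cond_1", "f_cond_2", "q_a"),
         value = c(x$f_cond_1, x$f_cond_2, x$q_a),
         df = c(NA_integer_, NA_integer_, x$q_a_df),
         pvalue = c(NA_real_, NA_real_, x$q_a_pvalue))
}

require_two_exposures <- function(set) {
  df <- as_tibble(as.data.frame(set))
  if (!all(c("gamma2", "se_g2") %in% names(df))) {
    abort("a harmonized set with two exposures is required")
  }
  df
}
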
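test_that("multivariable IVW recovers exact noiseless direct effects", {
  withr::with_seed(31, {
    g1 <- rnorm(12, 0.1, 0.04)
    g2 <- rnorm(12, 0.1, 0.04)
    hs <- harmonized_set(gamma1 = g1, se_g1 = rep(0.01, 12),
                         Gamma = 0 * g1 + 0.3 * g2, se_G = rep(0.02, 12),
                         gamma2 = g2, se_g2 = rep(0.01, 12))
    fit <- mvmr_ivw(hs)
    est <- tidy(fit)
    expect_equal(est$estimate[est$term == "exposure1"], 0,
                 tolerance = 1e-12)
    expect_equal(est$estimate[est$term == "exposure2"], 0.3,
                 tolerance = 1e-12)
    expect_equal(fit$rss_w, 0, tolerance = 1e-20)
  })
})

test_that("multivariable IVW matches a two-column GLS oracle", {
  for (seed in 1:8) {
    hs <- random_hset(20, seed = 400 + seed, two = TRUE)
    fit <- mvmr_ivw(hs)
    orc <- oracle_mvmr(hs)
    est <- tidy(fit)
    expect_equal(est$estimate, orc$coef, tolerance = 1e-10)
    expect_equal(est$std.error, orc$se, tolerance = 1e-10)
  }
})

test_that("rank-deficient designs and tiny sets are rejected", {
  g <- c(0.1, 0.2, 0.3, 0.4)
  hs_collinear <- harmonized_set(gamma1 = g, se_g1 = rep(0.01, 4),
                                 Gamma = rnorm(4), se_G = rep(0.02, 4),
                                 gamma2 = 2 * g, se_g2 = rep(0.01, 4))
  expect_error(mvmr_ivw(hs_collinear), "rank")
  expect_error(mvmr_ivw(random_hset(2, seed = 1, two = TRUE)), "at least 3")
})

test_that("theta1 equals the univariable IVW when the cross-moment vanishes", {
  # construct gamma2 exactly w-orthogonal to gamma1 so S12 = 0
  withr::with_seed(55, {
    L <- 15
    g1 <- rnorm(L, 0.1, 0.05)
    se_G <- runif(L, 0.01, 0.05)
    w <- 1 / se_G^2
    raw <- rnorm(L, 0.05, 0.03)
    g2 <- raw - g1 * sum(w * g1 * raw) / sum(w * g1^2)
    expect_equal(sum(w * g1 * g2), 0, tolerance = 1e-12)
    Gamma <- 0.2 * g1 + 0.1 * g2 + rnorm(L, 0, 0.01)
    hs2 <- harmonized_set(g1, rep(0.01, L), Gamma, se_G,
                          gamma2 = g2, se_g2 = rep(0.01, L))
    hs1 <- harmonized_set(g1, rep(0.01, L), Gamma, se_G)
    est2 <- tidy(mvmr_ivw(hs2))
    expect_equal(est2$estimate[est2$term == "exposure1"],
                 mr_ivw(hs1, mode = "fixed")$theta, tolerance = 1e-10)
  })
})

test_that("conditional F reduces to the mean chi-squared when gamma2 is null", {
  withr::with_seed(61, {
    L <- 10
    g1 <- rnorm(L, 0.1, 0.03)
    se1 <- runif(L, 0.01, 0.02)
    hs <- harmonized_set(g1, se1, Gamma = rnorm(L), se_G = rep(0.02, L),
                         gamma2 = rep(0, L), se_g2 = rep(0.01, L))
    got <- conditional_f(hs, which = 1)
    expect_equal(got$f_cond, sum((g1 / se1)^2) / (L - 1), tolerance = 1e-6)
    expect_equal(got$delta, 0, tolerance = 1e-4)
  })
})

test_that("the minimized conditional Q matches a dense grid search", {
  for (seed in 1:4) {
    hs <- random_hset(15, seed = 500 + seed, two = TRUE)
    got <- conditional_f(hs, which = 1)
    grid_min <- oracle_conditional_q(hs, which = 1, step = 1e-4)
    expect_equal(got$q_x, grid_min, tolerance = 1e-3)
    got2 <- conditional_f(hs, which = 2)
    grid_min2 <- oracle_conditional_q(hs, which = 2, step = 1e-4)
    expect_equal(got2$q_x, grid_min2, tolerance = 1e-3)
  }
})

test_that("conditional F weakens as the exposure effects grow collinear", {
  f_at_rho <- function(rho) {
    study <- simulate_mr_summary(sim_config(n_snps = 150, rho = rho,
                                            seed = 77))
    conditional_f(harmonize_simulated(study), which = 1)$f_cond
  }
  fs <- vapply(c(0.1, 0.5, 0.9), f_at_rho, numeric(1))
  expect_true(all(diff(fs) < 0))
})

test_that("the shared-sample covariance option shifts conditional F", {
  hs <- random_hset(20, seed = 88, two = TRUE)
  base <- conditional_strength(hs)
  adj <- conditional_strength(hs, cov_correlation = 0.5)
  expect_false(isTRUE(all.equal(base$f_cond_1, adj$f_cond_1)))
  expect_gte(base$f_cond_1, 0)
  expect_gte(adj$f_cond_1, 0)
})

test_that("Q_a is zero on exact fits and catches a gross outlier", {
  withr::with_seed(41, {
    L <- 20
    g1 <- rnorm(L, 0.1, 0.04)
    g2 <- rnorm(L, 0.1, 0.04)
    Gamma <- 0.1 * g1 + 0.3 * g2
    hs <- harmonized_set(g1, rep(0.01, L), Gamma, rep(0.02, L),
                         gamma2 = g2, se_g2 = rep(0.01, L))
    fit <- mvmr_ivw(hs)
    qa <- mvmr_qa(hs, fit)
    expect_equal(qa$q_a, 0, tolerance = 1e-10)
    expect_equal(qa$pvalue, 1)

    # one grossly pleiotropic SNP pushes Q_a past the 95% quantile
    Gamma_out <- Gamma
    Gamma_out[1] <- Gamma_out[1] + 0.5
    hs_out <- harmonized_set(g1, rep(0.01, L), Gamma_out, rep(0.02, L),
                             gamma2 = g2, se_g2 = rep(0.01, L))
    qa_out <- mvmr_qa(hs_out, mvmr_ivw(hs_out))
    expect_gt(qa_out$q_a, qchisq(0.95, df = L - 2))
  })
})

test_that("Q_a equals its term-by-term hand summation", {
  hs <- random_hset(20, seed = 610, two = TRUE)
  fit <- mvmr_ivw(hs)
  qa <- mvmr_qa(hs, fit)
  df <- as.data.frame(hs)
  est <- tidy(fit)
  t1 <- est$estimate[est$term == "exposure1"]
  t2 <- est$estimate[est$term == "exposure2"]
  manual <- 0
  for (j in seq_len(nrow(df))) {
    manual <- manual +
      (df$Gamma[j] - t1 * df$gamma1[j] - t2 * df$gamma2[j])^2 /
      (df$se_G[j]^2 + t1^2 * df$se_g1[j]^2 + t2^2 * df$se_g2[j]^2)
  }
  expect_equal(qa$q_a, manual, tolerance = 1e-12)
  expect_equal(qa$df, 18)
  expect_error(mvmr_qa(random_hset(5, seed = 1, two = TRUE), fit),
               "not produced from")
})

test_that("multivariable Egger recovers a baked-in intercept exactly", {
  withr::with_seed(51, {
    L <- 15
    g1 <- abs(rnorm(L, 0.1, 0.04)) + 0.01
    g2 <- rnorm(L, 0.1, 0.04)
    hs <- harmonized_set(g1, rep(0.01, L),
                         Gamma = 0.02 + 0.1 * g1 + 0.3 * g2,
                         se_G = rep(0.02, L),
                         gamma2 = g2, se_g2 = rep(0.01, L))
    fit <- mvmr_egger(hs)
    expect_equal(fit$intercept, 0.02, tolerance = 1e-12)
    est <- tidy(fit)
    expect_equal(est$estimate, c(0.1, 0.3), tolerance = 1e-12)
  })
})

test_that("multivariable Egger is invariant to re-orienting one SNP", {
  hs <- random_hset(25, seed = 99, two = TRUE)
  base <- mvmr_egger(hs)
  df <- as.data.frame(hs)
  df$gamma1[3] <- -df$gamma1[3]
  df$gamma2[3] <- -df$gamma2[3]
  df$Gamma[3] <- -df$Gamma[3]
  flipped <- harmonized_set(df$gamma1, df$se_g1, df$Gamma, df$se_G,
                            gamma2 = df$gamma2, se_g2 = df$se_g2)
  got <- mvmr_egger(flipped)
  expect_equal(tidy(got)$estimate, tidy(base)$estimate, tolerance = 1e-12)
  expect_equal(got$intercept, base$intercept, tolerance = 1e-12)
})

test_that("multivariable Egger matches a three-column regression oracle", {
  for (seed in 1:5) {
    hs <- random_hset(25, seed = 700 + seed, two = TRUE)
    fit <- mvmr_egger(hs)
    df <- orient_df <- as.data.frame(hs)
    flip <- orient_df$gamma1 < 0
    for (col in c("gamma1", "gamma2", "Gamma")) {
      orient_df[[col]][flip] <- -orient_df[[col]][flip]
    }
    orc <- oracle_wls(cbind(1, orient_df$gamma1, orient_df$gamma2),
                      orient_df$Gamma, 1 / orient_df$se_G^2,
                      df_resid = nrow(df) - 3)
    expect_equal(fit$intercept, orc$coef[1], tolerance = 1e-10)
    expect_equal(tidy(fit)$estimate, orc$coef[2:3], tolerance = 1e-10)
    expect_equal(tidy(fit)$std.error, orc$se[2:3], tolerance = 1e-10)
  }
})
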
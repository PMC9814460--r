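test_that("Wald ratios follow Gamma / gamma with first-order SE", {
  hs <- harmonized_set(gamma1 = 0.10, se_g1 = 0.01, Gamma = 0.05,
                       se_G = 0.01)
  w <- wald_ratio(hs)
  expect_equal(w$theta, 0.5)
  expect_equal(w$se, 0.1)

  hs0 <- harmonized_set(gamma1 = 0.10, se_g1 = 0.01, Gamma = 0,
                        se_G = 0.01)
  expect_equal(wald_ratio(hs0)$theta, 0)

  hs_neg <- harmonized_set(gamma1 = -0.2, se_g1 = 0.01, Gamma = 0.05,
                           se_G = 0.02)
  w2 <- wald_ratio(hs_neg)
  expect_equal(w2$theta, -0.25)
  expect_equal(w2$se, 0.1)

  hz <- harmonized_set(gamma1 = 0, se_g1 = 0.01, Gamma = 0.1, se_G = 0.01)
  expect_error(wald_ratio(hz), "zero")
})

test_that("IVW reduces to the Wald ratio at L = 1 and to c under homogeneity", {
  hs1 <- harmonized_set(gamma1 = 0.12, se_g1 = 0.01, Gamma = 0.03,
                        se_G = 0.02)
  expect_equal(mr_ivw(hs1)$theta, wald_ratio(hs1)$theta)
  expect_equal(mr_ivw(hs1)$se, wald_ratio(hs1)$se)

  g <- c(0.1, 0.2, 0.35)
  hs <- harmonized_set(gamma1 = g, se_g1 = rep(0.01, 3),
                       Gamma = 0.4 * g, se_G = c(0.01, 0.03, 0.02))
  est <- mr_ivw(hs)
  expect_equal(est$theta, 0.4)
  expect_equal(est$q_stat, 0)
  expect_equal(est$q_df, 2)
})

test_that("IVW matches a weighted-through-origin regression oracle", {
  for (seed in 1:8) {
    hs <- random_hset(5 + seed, seed = seed)
    est <- mr_ivw(hs, mode = "fixed")
    orc <- oracle_ivw(hs)
    expect_equal(est$theta, orc$coef[1], tolerance = 1e-10)
    # fixed-effect SE has no inflation factor
    df <- as.data.frame(hs)
    expect_equal(est$se, 1 / sqrt(sum(df$gamma1^2 / df$se_G^2)),
                 tolerance = 1e-12)
  }
})

test_that("random-effect IVW never shrinks the SE and auto switches on Q", {
  for (seed in 1:10) {
    hs <- random_hset(12, seed = 100 + seed)
    fixed <- mr_ivw(hs, mode = "fixed")
    random <- mr_ivw(hs, mode = "random")
    auto <- mr_ivw(hs, mode = "auto")
    expect_equal(fixed$theta, random$theta)
    expect_gte(random$se, fixed$se)
    if (fixed$q_stat <= fixed$q_df) expect_equal(random$se, fixed$se)
    expect_equal(auto$method,
                 if (fixed$q_pvalue < 0.05) "ivw_random" else "ivw_fixed")
  }
})

test_that("IVW is invariant to allele re-orientation of any record", {
  hs <- random_hset(9, seed = 7)
  base <- mr_ivw(hs)
  df <- as.data.frame(hs)
  idx <- c(2, 5)
  df$gamma1[idx] <- -df$gamma1[idx]
  df$Gamma[idx] <- -df$Gamma[idx]
  flipped <- harmonized_set(df$gamma1, df$se_g1, df$Gamma, df$se_G)
  est <- mr_ivw(flipped)
  expect_equal(est$theta, base$theta, tolerance = 1e-12)
  expect_equal(est$se, base$se, tolerance = 1e-12)
})

test_that("MR-Egger recovers an exact affine relation with zero residual Q", {
  hs <- harmonized_set(gamma1 = c(0.1, 0.2, 0.3), se_g1 = rep(0.01, 3),
                       Gamma = c(0.03, 0.05, 0.07), se_G = rep(0.02, 3))
  est <- mr_egger(hs)
  expect_equal(est$theta, 0.2, tolerance = 1e-12)
  expect_equal(est$egger_intercept, 0.01, tolerance = 1e-12)
  expect_equal(est$q_stat, 0, tolerance = 1e-20)
  expect_equal(est$q_df, 1)
})

test_that("MR-Egger matches a weighted regression-with-intercept oracle", {
  for (seed in 1:8) {
    hs <- random_hset(10, seed = 200 + seed)
    est <- mr_egger(hs)
    orc <- oracle_egger(hs)
    expect_equal(est$egger_intercept, orc$coef[1], tolerance = 1e-10)
    expect_equal(est$theta, orc$coef[2], tolerance = 1e-10)
    expect_equal(est$egger_intercept_se, orc$se[1], tolerance = 1e-10)
    expect_equal(est$se, orc$se[2], tolerance = 1e-10)
  }
})

test_that("MR-Egger enforces its preconditions", {
  expect_error(mr_egger(random_hset(2, seed = 1)), "at least 3")
  hs_flat <- harmonized_set(gamma1 = rep(0.1, 4), se_g1 = rep(0.01, 4),
                            Gamma = rnorm(4), se_G = rep(0.02, 4))
  expect_error(mr_egger(hs_flat), "degenerate")
})

test_that("the weighted median interpolates the cumulative-weight polyline", {
  hs <- harmonized_set(gamma1 = c(1, 1, 1), se_g1 = rep(0.01, 3),
                       Gamma = c(0.1, 0.2, 0.3), se_G = rep(0.1, 3))
  est <- mr_weighted_median(hs, n_boot = 50, seed = 1)
  expect_equal(est$theta, 0.2)

  hs_c <- harmonized_set(gamma1 = c(0.1, 0.2, 0.4), se_g1 = rep(0.01, 3),
                         Gamma = 0.3 * c(0.1, 0.2, 0.4),
                         se_G = rep(0.001, 3))
  est_c <- mr_weighted_median(hs_c, n_boot = 200, seed = 2)
  expect_equal(est_c$theta, 0.3, tolerance = 1e-10)
  expect_lt(est_c$se, 0.05)

  for (seed in 1:6) {
    hs7 <- random_hset(7, seed = 300 + seed)
    df <- as.data.frame(hs7)
    est7 <- mr_weighted_median(hs7, n_boot = 50, seed = seed)
    expect_equal(est7$theta,
                 oracle_weighted_median(df$Gamma / df$gamma1,
                                        (df$gamma1 / df$se_G)^2),
                 tolerance = 1e-12)
  }
})

test_that("the weighted-median bootstrap is seed-reproducible", {
  hs <- random_hset(10, seed = 5)
  a <- mr_weighted_median(hs, n_boot = 100, seed = 42)
  b <- mr_weighted_median(hs, n_boot = 100, seed = 42)
  c <- mr_weighted_median(hs, n_boot = 100, seed = 43)
  expect_identical(a$se, b$se)
  expect_false(identical(a$se, c$se))
  expect_error(mr_weighted_median(hs, n_boot = 10), "seed")
})

test_that("all estimators recover the truth on strong, pleiotropy-free data", {
  study <- simulate_mr_summary(sim_config(
    n_snps = 200, rho = 0, theta1 = 0.25, theta2 = 0, seed = 17,
    r2_target_1 = 0.08, r2_target_2 = 0.05))
  hs <- harmonize(study$exposure1, study$outcome)
  for (est in list(mr_ivw(hs), mr_egger(hs),
                   mr_weighted_median(hs, n_boot = 200, seed = 17))) {
    expect_lt(abs(est$theta - 0.25), 3 * est$se)
  }
})

test_that("subgroup heterogeneity matches hand-computed Q and printed CIs", {
  # identical estimates: no heterogeneity at all
  same <- tibble::tibble(theta = c(0.2, 0.2), se = c(0.1, 0.1))
  res <- subgroup_heterogeneity(same)
  expect_equal(res$q_stat, 0)
  expect_equal(res$pvalue, 1)

  # three strata against a manual inverse-variance computation
  df <- tibble::tibble(theta = c(0.10, 0.25, -0.05), se = c(0.1, 0.2, 0.15))
  got <- subgroup_heterogeneity(df)
  w <- 1 / df$se^2
  pooled <- sum(w * df$theta) / sum(w)
  expect_equal(got$q_stat, sum(w * (df$theta - pooled)^2))
  expect_equal(got$df, 2)

  # men vs women direct effects back-computed from printed intervals
  sexes <- tibble::tibble(
    theta = log(c(1.75, 0.83)),
    se = c(se_from_ci(1.07, 2.89), se_from_ci(0.54, 1.25)))
  p <- subgroup_heterogeneity(sexes)$pvalue
  expect_gt(p, 0.015)
  expect_lt(p, 0.035)

  expect_error(subgroup_heterogeneity(same[1, ]), "at least 2")
})
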
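mk_set <- function(rsid, ea, oa, beta, se = 0.01, eaf = NA_real_,
                   name = "x") {
  instrument_set(tibble::tibble(
    rsid = rsid, effect_allele = ea, other_allele = oa,
    eaf = eaf, beta = beta, se = se), exposure_name = name)
}

test_that("matching alleles pass through and flipped alleles change sign", {
  exp <- mk_set(c("rs1", "rs2"), c("A", "A"), c("G", "G"), c(0.10, 0.10))
  out_same <- mk_set("rs1", "A", "G", 0.05)
  hs <- harmonize(exp, out_same)
  expect_equal(hs$gamma1, 0.10)
  expect_equal(hs$Gamma, 0.05)

  out_flip <- mk_set("rs2", "G", "A", 0.05)
  hs2 <- harmonize(exp, out_flip)
  expect_equal(hs2$Gamma, -0.05)
  expect_equal(hs2$gamma1, 0.10)
})

test_that("irreconcilable allele pairs are dropped and logged", {
  exp <- mk_set(c("rs1", "rs2"), c("A", "A"), c("G", "G"), c(0.1, 0.2))
  out <- mk_set(c("rs1", "rs2"), c("A", "A"), c("G", "C"), c(0.05, 0.07))
  expect_message(hs <- harmonize(exp, out), "dropped 1 SNP")
  expect_equal(hs$rsid, "rs1")
  dropped <- attr(hs, "dropped")
  expect_equal(dropped$rsid, "rs2")
  expect_match(dropped$reason, "allele_mismatch")

  out_all_bad <- mk_set("rs1", "A", "C", 0.05)
  expect_error(suppressMessages(harmonize(exp, out_all_bad)), "dropped")
  expect_error(harmonize(exp, mk_set("rs9", "A", "G", 0.1)),
               "no SNPs shared")
})

test_that("palindromic SNPs are kept by default, droppable in strict mode", {
  exp <- mk_set(c("rs1", "rs2"), c("A", "C"), c("T", "G"), c(0.1, 0.2),
                eaf = c(0.50, 0.10))
  out <- mk_set(c("rs1", "rs2"), c("A", "C"), c("T", "G"), c(0.03, 0.04))
  hs <- harmonize(exp, out)
  expect_equal(nrow(hs), 2)

  # strict mode drops only the ambiguous-frequency palindrome
  expect_message(strict <- harmonize(exp, out, strict_palindromes = TRUE),
                 "palindromic")
  expect_equal(strict$rsid, "rs2")
})

test_that("harmonization is idempotent and orientation-symmetric", {
  study <- simulate_mr_summary(sim_config(n_snps = 40, seed = 3))
  hs1 <- harmonize(study$exposure1, study$outcome,
                   exposure2 = study$exposure2)

  # idempotence: re-harmonizing aligned tables changes nothing
  realign <- function(col, se_col, name) {
    instrument_set(tibble::tibble(
      rsid = hs1$rsid, effect_allele = hs1$effect_allele,
      other_allele = hs1$other_allele, eaf = NA_real_,
      beta = hs1[[col]], se = hs1[[se_col]]), exposure_name = name)
  }
  hs2 <- harmonize(realign("gamma1", "se_g1", "e1"),
                   realign("Gamma", "se_G", "out"),
                   exposure2 = realign("gamma2", "se_g2", "e2"))
  expect_equal(as.data.frame(hs2), as.data.frame(hs1))

  # flipping both alleles and the beta sign of outcome rows is a no-op
  flipped_out <- as.data.frame(study$outcome)
  idx <- seq(1, nrow(flipped_out), by = 2)
  tmp <- flipped_out$effect_allele[idx]
  flipped_out$effect_allele[idx] <- flipped_out$other_allele[idx]
  flipped_out$other_allele[idx] <- tmp
  flipped_out$beta[idx] <- -flipped_out$beta[idx]
  flipped_out$eaf[idx] <- 1 - flipped_out$eaf[idx]
  hs3 <- harmonize(study$exposure1, instrument_set(flipped_out),
                   exposure2 = study$exposure2)
  expect_equal(as.data.frame(hs3), as.data.frame(hs1))
})

test_that("harmonized size never exceeds the smallest input table", {
  for (seed in 1:5) {
    study <- simulate_mr_summary(sim_config(n_snps = 20, seed = seed))
    out_sub <- as.data.frame(study$outcome)[1:11, ]
    hs <- harmonize(study$exposure1, instrument_set(out_sub))
    expect_lte(nrow(hs), 11)
  }
})

test_that("instrument union without LD is the plain union", {
  s1 <- mk_set(paste0("rs", 1:3), "A", "G", c(0.1, 0.2, 0.3))
  s2 <- mk_set(paste0("rs", 4:5), "A", "G", c(0.1, 0.2))
  expect_setequal(union_instrument_set(s1, s2), paste0("rs", 1:5))
})

test_that("LD pruning keeps the smaller-p SNP of a correlated pair", {
  s1 <- instrument_set(tibble::tibble(
    rsid = "rs1", effect_allele = "A", other_allele = "G",
    beta = 0.1, se = 0.01, pvalue = 1e-10))
  s2 <- instrument_set(tibble::tibble(
    rsid = "rs2", effect_allele = "A", other_allele = "G",
    beta = 0.1, se = 0.01, pvalue = 1e-8))
  ld <- matrix(c(1, 0.5, 0.5, 1), 2, 2,
               dimnames = list(c("rs1", "rs2"), c("rs1", "rs2")))
  expect_equal(union_instrument_set(s1, s2, ld = ld), "rs1")

  bad <- ld; bad[1, 2] <- 0.7
  expect_error(union_instrument_set(s1, s2, ld = bad), "symmetric")
})

test_that("greedy LD pruning matches a brute-force reimplementation", {
  withr::with_seed(99, {
    n <- 10
    ids <- paste0("rs", 1:n)
    p <- runif(n, 1e-12, 1e-6)
    # chained correlations: neighbours correlated above threshold
    ld <- diag(n)
    for (i in 1:(n - 1)) ld[i, i + 1] <- ld[i + 1, i] <- runif(1, 0, 0.9)
    dimnames(ld) <- list(ids, ids)

    half <- ceiling(n / 2)
    s1 <- instrument_set(tibble::tibble(
      rsid = ids[1:half], effect_allele = "A", other_allele = "G",
      beta = 0.1, se = 0.01, pvalue = p[1:half]))
    s2 <- instrument_set(tibble::tibble(
      rsid = ids[(half + 1):n], effect_allele = "A", other_allele = "G",
      beta = 0.1, se = 0.01, pvalue = p[(half + 1):n]))

    got <- union_instrument_set(s1, s2, ld = ld, r2_threshold = 0.3)

    # independent greedy: same visiting order, exhaustive pair checks
    ordered <- ids[order(p, ids)]
    kept <- character()
    for (snp in ordered) {
      ok <- TRUE
      for (k in kept) if (ld[snp, k] > 0.3) ok <- FALSE
      if (ok) kept <- c(kept, snp)
    }
    expect_equal(got, kept)
  })
})

test_that("LD matrices round-trip through the TSV reader", {
  ids <- c("rs1", "rs2", "rs3")
  m <- diag(3); m[1, 2] <- m[2, 1] <- 0.4
  dimnames(m) <- list(ids, ids)
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::as_tibble(m) |>
                     dplyr::mutate(rsid = ids, .before = 1), path)
  back <- read_ld_matrix(path)
  expect_equal(unname(back), unname(m))
  expect_equal(rownames(back), ids)
})
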
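# Allele harmonization: align exposure and outcome records to a shared
# effect allele per SNP before estimation. All input GWAS are assumed to be
# reported on the forward strand, so palindromic (A/T, C/G) SNPs are
# treated like any other pair unless strict mode is requested.

#' Harmonize exposure and outcome summary statistics
#'
#' Restricts to SNPs present in all supplied tables and aligns every record
#' to the first exposure's effect allele. Where a table reports the
#' complementary orientation (its effect allele is the reference table's
#' other allele), the beta sign is flipped and the effect-allele frequency
#' complemented. SNPs whose allele pairs cannot be reconciled are dropped
#' and recorded in the `dropped` attribute with a reason code.
#'
#' @param exposure An [instrument_set()] for the (first) exposure.
#' @param outcome An [instrument_set()] of outcome associations (log-odds).
#' @param exposure2 Optional second exposure for multivariable analysis.
#' @param strict_palindromes If `TRUE`, palindromic SNPs whose exposure
#'   effect-allele frequency is missing or inside (0.42, 0.58) are dropped
#'   as strand-ambiguous. Off by default: under the forward-strand
#'   assumption palindromic SNPs carry no ambiguity.
#' @return A tibble of class `harmonized_set` with columns `rsid`,
#'   `effect_allele`, `other_allele`, `gamma1`, `se_g1` (and `gamma2`,
#'   `se_g2` when `exposure2` is given), `Gamma`, `se_G`. Attributes:
#'   `n_exposures` and `dropped` (a tibble of rsid/reason pairs).
#' @examples
#' exp <- instrument_set(tibble::tibble(
#'   rsid = "rs1", effect_allele = "A", other_allele = "G",
#'   beta = 0.10, se = 0.02))
#' out <- instrument_set(tibble::tibble(
#'   rsid = "rs1", effect_allele = "G", other_allele = "A",
#'   beta = 0.05, se = 0.01))
#' harmonize(exp, out)  # outcome beta becomes -0.05
#' @export
harmonize <- function(exposure, outcome, exposure2 = NULL,
                      strict_palindromes = FALSE) {
  e1 <- as_tibble(as.data.frame(exposure))
  out <- as_tibble(as.data.frame(outcome))
  e2 <- if (!is.null(exposure2)) as_tibble(as.data.frame(exposure2))

  shared <- intersect(e1$rsid, out$rsid)
  if (!is.null(e2)) shared <- intersect(shared, e2$rsid)
  if (length(shared) == 0) abort("no SNPs shared between the input tables")

  e1 <- e1[match(shared, e1$rsid), ]
  out <- out[match(shared, out$rsid), ]
  if (!is.null(e2)) e2 <- e2[match(shared, e2$rsid), ]

  dropped <- tibble(rsid = character(), reason = character())
  drop_mask <- rep(FALSE, length(shared))
  note_drop <- function(mask, reason) {
    new <- mask & !drop_mask
    if (any(new)) {
      dropped <<- dplyr::bind_rows(
        dropped, tibble(rsid = shared[new], reason = reason))
      drop_mask <<- drop_mask | mask
    }
  }

  # Align a table's rows onto the reference alleles. status: 1 = as-is,
  # -1 = flip (beta sign, eaf complement), 0 = irreconcilable.
  orient <- function(tab) {
    same <- tab$effect_allele == e1$effect_allele &
      tab$other_allele == e1$other_allele
    flip <- tab$effect_allele == e1$other_allele &
      tab$other_allele == e1$effect_allele
    ifelse(same, 1, ifelse(flip, -1, 0))
  }

  o_out <- orient(out)
  note_drop(o_out == 0, "allele_mismatch_outcome")
  if (!is.null(e2)) {
    o_e2 <- orient(e2)
    note_drop(o_e2 == 0, "allele_mismatch_exposure2")
  }

  if (strict_palindromes) {
    pal <- is_palindromic(e1$effect_allele, e1$other_allele)
    ambiguous <- pal & (is.na(e1$eaf) | (e1$eaf > 0.42 & e1$eaf < 0.58))
    note_drop(ambiguous, "palindromic_ambiguous")
  }

  keep <- !drop_mask
  if (!any(keep)) abort("all shared SNPs were dropped during harmonization")

  res <- tibble(
    rsid = shared[keep],
    effect_allele = e1$effect_allele[keep],
    other_allele = e1$other_allele[keep],
    gamma1 = e1$beta[keep],
    se_g1 = e1$se[keep]
  )
  if (!is.null(e2)) {
    res$gamma2 <- (e2$beta * o_e2)[keep]
    res$se_g2 <- e2$se[keep]
  }
  res$Gamma <- (out$beta * o_out)[keep]
  res$se_G <- out$se[keep]

  if (nrow(dropped) > 0) {
    inform(paste0("harmonize: dropped ", nrow(dropped), " SNP(s): ",
                  paste0(dropped$rsid, " [", dropped$reason, "]",
                         collapse = ", ")))
  }

  new_harmonized_set(res, n_exposures = if (is.null(e2)) 1L else 2L,
                     dropped = dropped)
}

new_harmonized_set <- function(data, n_exposures, dropped = NULL) {
  stopifnot(all(data$se_g1 > 0), all(data$se_G > 0),
            !anyDuplicated(data$rsid))
  if (n_exposures == 2L) stopifnot(all(data$se_g2 > 0))
  structure(as_tibble(data),
            class = c("harmonized_set", class(tibble())),
            n_exposures = as.integer(n_exposures),
            dropped = dropped %||% tibble(rsid = character(),
                                          reason = character()))
}

#' Assemble a harmonized set directly from aligned beta vectors
#'
#' Convenience constructor for simulated or already-aligned data, skipping
#' allele bookkeeping.
#'
#' @param gamma1,se_g1 First-exposure betas and standard errors.
#' @param Gamma,se_G Outcome log-odds betas and standard errors.
#' @param gamma2,se_g2 Optional second-exposure betas and standard errors.
#' @param rsid Optional SNP identifiers (defaults to `snp_1 ... snp_L`).
#' @return A `harmonized_set` tibble.
#' @export
harmonized_set <- function(gamma1, se_g1, Gamma, se_G,
                           gamma2 = NULL, se_g2 = NULL, rsid = NULL) {
  L <- length(gamma1)
  rsid <- rsid %||% paste0("snp_", seq_len(L))
  data <- tibble(rsid = rsid,
                 effect_allele = rep("A", L), other_allele = rep("G", L),
                 gamma1 = gamma1, se_g1 = se_g1)
  two <- !is.null(gamma2)
  if (two) {
    data$gamma2 <- gamma2
    data$se_g2 <- se_g2
  }
  data$Gamma <- Gamma
  data$se_G <- se_G
  new_harmonized_set(data, n_exposures = if (two) 2L else 1L)
}

n_exposures <- function(set) attr(set, "n_exposures") %||% 1L

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Merge two instrument SNP lists, optionally pruning by LD
#'
#' Returns the union of the SNPs instrumenting two exposures, as used to
#' build a multivariable instrument. When an LD matrix is supplied, pairs
#' correlated above `r2_threshold` are resolved greedily: SNPs are visited
#' in order of increasing exposure p-value (the smaller p-value across the
#' two sets) and a SNP is retained only if its r-squared with every
#' already-retained SNP is at or below the threshold.
#'
#' @param set1,set2 [instrument_set()] objects.
#' @param ld Optional square r-squared matrix with rsid dimnames covering
#'   every SNP in the union (see [read_ld_matrix()]).
#' @param r2_threshold LD pruning threshold (default 0.001).
#' @return Character vector of retained rsids.
#' @export
union_instrument_set <- function(set1, set2, ld = NULL,
                                 r2_threshold = 0.001) {
  assoc <- dplyr::bind_rows(
    as_tibble(as.data.frame(set1))[, c("rsid", "pvalue")],
    as_tibble(as.data.frame(set2))[, c("rsid", "pvalue")]
  )
  assoc <- assoc |>
    dplyr::group_by(.data$rsid) |>
    dplyr::summarise(pvalue = suppressWarnings(min(.data$pvalue,
                                                   na.rm = TRUE)),
                     .groups = "drop") |>
    dplyr::mutate(pvalue = ifelse(is.finite(.data$pvalue), .data$pvalue, 1))

  if (is.null(ld)) return(assoc$rsid)

  ld <- as.matrix(ld)
  if (is.null(rownames(ld)) || is.null(colnames(ld))) {
    abort("LD matrix needs rsid dimnames")
  }
  missing_snp <- setdiff(assoc$rsid, rownames(ld))
  if (length(missing_snp) > 0) {
    abort(paste0("LD matrix does not cover: ",
                 paste(missing_snp, collapse = ", ")))
  }
  if (!isTRUE(all.equal(ld, t(ld), tolerance = 1e-8)) ||
      any(abs(diag(ld) - 1) > 1e-8)) {
    abort("LD matrix must be symmetric with unit diagonal")
  }

  ordered <- assoc$rsid[order(assoc$pvalue, assoc$rsid)]
  kept <- character()
  for (snp in ordered) {
    if (length(kept) == 0 || all(ld[snp, kept] <= r2_threshold)) {
      kept <- c(kept, snp)
    }
  }
  kept
}

#' Read a square LD (r-squared) matrix from TSV
#'
#' Expects a header row of rsids and an rsid first column; entries in
#' `[0, 1]`.
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix with rsid dimnames.
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (any(m < 0 | m > 1, na.rm = TRUE)) {
    abort("LD r-squared values must lie in [0, 1]")
  }
  m
}
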
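# Reading, validating and writing GWAS summary-statistics tables.
#
# The canonical interchange format is a header-ed TSV with columns
# rsid, effect_allele, other_allele, eaf, beta, se, pvalue, n.
# Optional fields (eaf, pvalue, n) are written as empty strings and read
# back as NA. Supplementary tables from different sources rarely agree on
# column names, so reads go through a user-supplied column map.

CANONICAL_COLUMNS <- c("rsid", "effect_allele", "other_allele",
                       "eaf", "beta", "se", "pvalue", "n")

RESULT_COLUMNS <- c("exposure", "outcome", "stratum", "method", "n_snp",
                    "beta", "se", "or_", "ci_low", "ci_high", "pvalue",
                    "q_stat", "q_df", "q_pvalue", "egger_intercept",
                    "egger_intercept_se", "egger_intercept_pvalue")

#' Construct an instrument set from a data frame of SNP associations
#'
#' An instrument set is the package's atom of input: one row per SNP with
#' allele-coded effect estimate and standard error, plus set-level metadata
#' (exposure label, stratum, total variance explained, discovery sample
#' size). Rows are validated against the invariants every estimator relies
#' on; offending rows are reported by row number.
#'
#' @param data A data frame with columns `rsid`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, and optionally `eaf`, `pvalue`, `n`.
#' @param exposure_name Label for the trait the SNPs instrument.
#' @param stratum One of `"overall"`, `"men"`, `"women"`.
#' @param r_squared Optional total fraction of trait variance explained by
#'   the set, in `[0, 1)`.
#' @param n_gwas Optional discovery GWAS sample size.
#' @return A tibble of class `instrument_set`, one row per SNP, with the
#'   metadata stored as attributes (see [set_meta()]).
#' @examples
#' snps <- tibble::tibble(
#'   rsid = c("rs1", "rs2"), effect_allele = c("A", "C"),
#'   other_allele = c("G", "T"), beta = c(0.04, -0.03), se = c(0.01, 0.01)
#' )
#' instrument_set(snps, exposure_name = "early_life", n_gwas = 450000)
#' @export
instrument_set <- function(data, exposure_name = "exposure",
                           stratum = c("overall", "men", "women"),
                           r_squared = NULL, n_gwas = NULL) {
  stratum <- match.arg(stratum)
  data <- as_tibble(data)
  need <- c("rsid", "effect_allele", "other_allele", "beta", "se")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (opt in c("eaf", "pvalue", "n")) {
    if (!opt %in% names(data)) data[[opt]] <- NA_real_
  }
  data <- data[CANONICAL_COLUMNS]
  data$rsid <- as.character(data$rsid)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))
  for (num in c("eaf", "beta", "se", "pvalue", "n")) {
    data[[num]] <- as.numeric(data[[num]])
  }

  problems <- validate_associations(data)
  if (length(problems) > 0) {
    abort(paste0("invalid association rows:\n  ",
                 paste(problems, collapse = "\n  ")))
  }
  if (!is.null(r_squared) &&
      (!is.numeric(r_squared) || r_squared < 0 || r_squared >= 1)) {
    abort("r_squared must lie in [0, 1)")
  }
  if (nrow(data) < 1) abort("an instrument set needs at least one SNP")

  structure(data,
            class = c("instrument_set", class(tibble())),
            exposure_name = exposure_name,
            stratum = stratum,
            r_squared = r_squared,
            n_gwas = n_gwas)
}

# Row-by-row invariant checks; returns character vector of row-numbered
# messages, empty when the table is clean.
validate_associations <- function(data) {
  msgs <- character()
  bad <- function(cond, text) {
    idx <- which(cond)
    if (length(idx) > 0) {
      msgs <<- c(msgs, paste0("row ", idx, ": ", text))
    }
  }
  bad(is.na(data$rsid) | data$rsid == "", "empty rsid")
  bad(!data$effect_allele %in% c("A", "C", "G", "T"),
      "effect_allele must be a single base A/C/G/T")
  bad(!data$other_allele %in% c("A", "C", "G", "T"),
      "other_allele must be a single base A/C/G/T")
  bad(data$effect_allele == data$other_allele,
      "effect_allele equals other_allele")
  bad(is.na(data$beta) | !is.finite(data$beta), "beta missing or non-finite")
  bad(is.na(data$se) | !is.finite(data$se) | data$se <= 0,
      "se must be a positive finite number")
  bad(!is.na(data$eaf) & (data$eaf <= 0 | data$eaf >= 1),
      "eaf must lie in (0, 1)")
  bad(!is.na(data$pvalue) & (data$pvalue < 0 | data$pvalue > 1),
      "pvalue must lie in [0, 1]")
  dup <- duplicated(data$rsid) & !is.na(data$rsid) & data$rsid != ""
  if (any(dup)) {
    msgs <- c(msgs, paste0("row ", which(dup), ": duplicate rsid ",
                           data$rsid[dup]))
  }
  sort(msgs)
}

#' Metadata of an instrument set
#'
#' @param x An `instrument_set`.
#' @return A list with elements `exposure_name`, `stratum`, `r_squared`,
#'   `n_gwas`.
#' @export
set_meta <- function(x) {
  list(exposure_name = attr(x, "exposure_name"),
       stratum = attr(x, "stratum"),
       r_squared = attr(x, "r_squared"),
       n_gwas = attr(x, "n_gwas"))
}

#' @export
print.instrument_set <- function(x, ...) {
  m <- set_meta(x)
  cat(sprintf("<instrument_set> %s (%s): %d SNPs", m$exposure_name,
              m$stratum, nrow(x)))
  if (!is.null(m$r_squared)) cat(sprintf(", r2 = %.4g", m$r_squared))
  if (!is.null(m$n_gwas)) cat(sprintf(", N = %d", as.integer(m$n_gwas)))
  cat("\n")
  NextMethod()
}

#' Read a summary-statistics table into an instrument set
#'
#' Reads a tab-separated table with a header line, renames columns through
#' `column_map`, validates every row, and returns an [instrument_set()].
#' Empty strings in optional columns (`eaf`, `pvalue`, `n`) become `NA`.
#' Alleles are uppercased on read; indels and multi-character alleles are
#' rejected with a row-numbered message.
#'
#' @param path Path to a TSV file.
#' @param column_map Named character vector mapping canonical names to the
#'   names used in the file, e.g. `c(effect_allele = "EA")`. Canonical
#'   columns absent from the map are looked up under their own names.
#' @inheritParams instrument_set
#' @return An [instrument_set()].
#' @export
read_associations <- function(path, column_map = NULL,
                              exposure_name = "exposure",
                              stratum = c("overall", "men", "women"),
                              r_squared = NULL, n_gwas = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE)
  wanted <- setNames(CANONICAL_COLUMNS, CANONICAL_COLUMNS)
  if (!is.null(column_map)) wanted[names(column_map)] <- column_map
  required <- wanted[c("rsid", "effect_allele", "other_allele", "beta", "se")]
  missing_cols <- setdiff(unname(required), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("mapped column(s) not in header: ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- tibble(.rows = nrow(raw))
  for (canon in CANONICAL_COLUMNS) {
    src <- wanted[[canon]]
    out[[canon]] <- if (src %in% names(raw)) raw[[src]] else NA_character_
  }
  instrument_set(out, exposure_name = exposure_name, stratum = stratum,
                 r_squared = r_squared, n_gwas = n_gwas)
}

#' Write an instrument set (or any association table) as canonical TSV
#'
#' @param x An `instrument_set` or data frame with the canonical columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(x, path) {
  df <- as_tibble(as.data.frame(x))[CANONICAL_COLUMNS]
  readr::write_tsv(df, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write MR estimates as a results table
#'
#' One row per estimate with the method, analysis cell, point estimate on
#' the log-odds and odds-ratio scales, confidence bounds, heterogeneity
#' statistics and Egger intercept fields. Values round-trip through
#' [read_results_table()] losslessly to at least 10 significant digits.
#'
#' @param estimates A list of `mr_estimate` objects, or a tibble already in
#'   result-table form (e.g. from [run_univariable_grid()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(estimates, path) {
  tbl <- as_results_table(estimates)
  if (nrow(tbl) == 0) abort("no estimates to write")
  readr::write_tsv(tbl, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#'
#' @param path Path to the TSV file.
#' @return A tibble with the canonical result columns.
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  readr::read_tsv(path,
                  col_types = readr::cols(
                    exposure = "c", outcome = "c", stratum = "c",
                    method = "c", n_snp = "i", .default = "d"),
                  na = "", progress = FALSE)
}

#' Coerce MR estimates to the canonical result-table layout
#'
#' @param estimates A list of `mr_estimate` objects, a single estimate, or
#'   a data frame already carrying result columns (missing canonical
#'   columns are added as `NA`).
#' @return A tibble with the canonical result columns (see
#'   [write_results_table()]).
#' @export
as_results_table <- function(estimates) {
  if (is.data.frame(estimates)) {
    tbl <- as_tibble(estimates)
    for (col in RESULT_COLUMNS) {
      if (!col %in% names(tbl)) tbl[[col]] <- NA_real_
    }
    return(tbl[c(RESULT_COLUMNS, setdiff(names(tbl), RESULT_COLUMNS))])
  }
  if (inherits(estimates, "mr_estimate")) estimates <- list(estimates)
  if (!is.list(estimates) || length(estimates) == 0) {
    abort("estimates must be a non-empty list of mr_estimate objects")
  }
  purrr::map_dfr(estimates, function(e) {
    stopifnot(inherits(e, "mr_estimate"))
    tibble(
      exposure = e$exposure %||% NA_character_,
      outcome = e$outcome %||% NA_character_,
      stratum = e$stratum %||% NA_character_,
      method = e$method,
      n_snp = e$n_snp,
      beta = e$theta, se = e$se, or_ = e$or,
      ci_low = e$ci_low, ci_high = e$ci_high, pvalue = e$pvalue,
      q_stat = e$q_stat %||% NA_real_,
      q_df = e$q_df %||% NA_real_,
      q_pvalue = e$q_pvalue %||% NA_real_,
      egger_intercept = e$egger_intercept %||% NA_real_,
      egger_intercept_se = e$egger_intercept_se %||% NA_real_,
      egger_intercept_pvalue = e$egger_intercept_pvalue %||% NA_real_
    )
  })
}
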
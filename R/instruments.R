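# Instrument-strength diagnostics for univariable MR.

#' F-statistic for instrument strength
#'
#' `F = R^2 (N - 2) / (1 - R^2)`, where `R^2` is the fraction of exposure
#' variance explained by the instrument and `N` the discovery GWAS sample
#' size. Values below 10 are the conventional flag for weak-instrument
#' bias. Vectorized over both arguments.
#'
#' @param r_squared Fraction of variance explained, in `[0, 1)`.
#' @param n GWAS sample size, `> 2`.
#' @return The F value(s).
#' @examples
#' f_statistic(0.045, 453169)
#' @export
f_statistic <- function(r_squared, n) {
  if (any(r_squared < 0 | r_squared >= 1)) {
    abort("r_squared must lie in [0, 1)")
  }
  if (any(n <= 2)) abort("n must exceed 2")
  r_squared * (n - 2) / (1 - r_squared)
}

#' Per-SNP instrument strength report
#'
#' Computes an F-statistic per SNP and set-level summaries. When per-SNP
#' variance fractions are not supplied they are approximated from the
#' effect size and allele frequency as
#' `r2_j = 2 eaf (1 - eaf) beta^2 / var_trait`.
#'
#' @param set An [instrument_set()] with `n_gwas` metadata (or pass `n`).
#' @param per_snp_r2 Optional numeric vector, one `r^2` per SNP.
#' @param var_trait Trait variance used by the approximation (default 1,
#'   i.e. a standardized trait).
#' @param n Discovery sample size; defaults to the set's `n_gwas`.
#' @return A list of class `strength_report`: `per_snp` (tibble of rsid,
#'   r_squared, f), `min_f`, `r_squared_total`, `n_gwas`, and `weak`
#'   (`TRUE` when `min_f < 10`).
#' @export
strength_report <- function(set, per_snp_r2 = NULL, var_trait = 1,
                            n = NULL) {
  df <- as_tibble(as.data.frame(set))
  n <- n %||% set_meta(set)$n_gwas
  if (is.null(n)) abort("discovery sample size unknown: supply n or n_gwas")
  if (is.null(per_snp_r2)) {
    if (anyNA(df$eaf)) {
      abort("eaf needed to approximate per-SNP r^2; supply per_snp_r2")
    }
    per_snp_r2 <- 2 * df$eaf * (1 - df$eaf) * df$beta^2 / var_trait
  }
  if (length(per_snp_r2) != nrow(df)) {
    abort("per_snp_r2 must have one value per SNP")
  }
  f <- f_statistic(per_snp_r2, n)
  structure(
    list(per_snp = tibble(rsid = df$rsid, r_squared = per_snp_r2, f = f),
         min_f = min(f),
         r_squared_total = sum(per_snp_r2),
         n_gwas = n,
         weak = min(f) < 10),
    class = "strength_report")
}

#' @export
print.strength_report <- function(x, ...) {
  cat(sprintf(
    "<strength_report> %d SNPs, total r2 = %.4g, min F = %.2f (%s)\n",
    nrow(x$per_snp), x$r_squared_total, x$min_f,
    if (x$weak) "weak-instrument evidence" else "no weak-instrument evidence"))
  invisible(x)
}

#' @rdname strength_report
#' @param x A `strength_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.strength_report <- function(x, ...) x$per_snp

#' @rdname strength_report
#' @exportS3Method generics::glance
glance.strength_report <- function(x, ...) {
  tibble(n_snp = nrow(x$per_snp), r_squared_total = x$r_squared_total,
         min_f = x$min_f, n_gwas = x$n_gwas, weak = x$weak)
}
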
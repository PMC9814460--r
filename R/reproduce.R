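# End-to-end reproduction of the motivating study from its supplementary
# tables. The exposure/outcome summary statistics are distributed as
# spreadsheet supplements by the source publication and are not bundled
# here; export them to TSV and point this function at the files.

#' Reproduce the body-size / colorectal-cancer analysis from source tables
#'
#' Runs the univariable and multivariable grids on user-supplied exposure
#' and outcome summary-statistics tables: per-SNP exposure betas for
#' early-life and adult body size (overall and per sex), per-SNP outcome
#' betas for colorectal cancer overall and by subsite, and the SNP list
#' used for the multivariable fit.
#'
#' @param exposure_paths Named list of exposure TSV paths; names are
#'   `"<exposure>.<stratum>"`, e.g. `early_life.overall`.
#' @param outcome_paths Named list of outcome TSV paths; names are
#'   `"<outcome>.<stratum>"`, e.g. `colorectal.overall`.
#' @param mvmr_snp_path Optional path to a one-rsid-per-line file for the
#'   multivariable instrument; defaults to the union of the two exposure
#'   instruments.
#' @param column_map Optional column map passed to [read_associations()].
#' @param seed Seed for the weighted-median bootstrap.
#' @param n_boot Bootstrap replicates for the weighted median.
#' @return A list with `univariable` and `multivariable` result tibbles
#'   (one row per estimate; odds ratios in `or_`).
#' @export
reproduce_study <- function(exposure_paths, outcome_paths,
                            mvmr_snp_path = NULL, column_map = NULL,
                            seed = 1, n_boot = 1000) {
  split_key <- function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    list(name = parts[1],
         stratum = if (length(parts) > 1) parts[2] else "overall")
  }
  dir <- withr::local_tempdir()
  cfg_list <- list(
    seed = seed, n_boot = n_boot, ivw_mode = "auto",
    exposures = purrr::imap(unname_null(exposure_paths), function(p, k) {
      sk <- split_key(k)
      c(sk, list(path = p))
    }),
    outcomes = purrr::imap(unname_null(outcome_paths), function(p, k) {
      sk <- split_key(k)
      c(sk, list(path = p))
    }),
    mvmr_snp_list = mvmr_snp_path,
    column_map = as.list(column_map)
  )
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg_list, cfg_path)
  cfg <- read_analysis_config(cfg_path)
  list(univariable = run_univariable_grid(cfg),
       multivariable = run_multivariable_grid(cfg))
}

unname_null <- function(x) {
  x[!purrr::map_lgl(x, is.null)]
}
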
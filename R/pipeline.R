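# Orchestration of the full analysis grid: univariable and multivariable
# estimates for every exposure x outcome x stratum cell, plus the power
# report. Cells fail independently; failures are collected and summarized
# rather than aborting the grid.

#' Read and validate an analysis configuration
#'
#' The configuration is a YAML file listing exposure and outcome tables
#' (one entry per stratum), an optional multivariable SNP list, and mode
#' flags. Referenced paths are checked at read time. Relative paths are
#' resolved against the config file's directory.
#'
#' Recognized keys: `exposures` and `outcomes` (lists with `name`,
#' `stratum`, `path`, plus `n_gwas`/`r_squared` for exposures and
#' `n_cases`/`n_controls` for outcomes), `mvmr_snp_list` (optional path),
#' `ivw_mode`, `strict_palindromes`, `n_boot`, `seed`, `alpha`,
#' `out_dir`, and optional `column_map`.
#'
#' @param path Path to the YAML config.
#' @return A validated list of class `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config not found: ", path))
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    p
  }
  cfg$exposures <- purrr::map(cfg$exposures, function(e) {
    e$path <- resolve(e$path)
    e$stratum <- e$stratum %||% "overall"
    if (!file.exists(e$path)) abort(paste0("exposure table missing: ", e$path))
    e
  })
  cfg$outcomes <- purrr::map(cfg$outcomes, function(o) {
    o$path <- resolve(o$path)
    o$stratum <- o$stratum %||% "overall"
    if (!file.exists(o$path)) abort(paste0("outcome table missing: ", o$path))
    o
  })
  if (length(cfg$exposures) == 0 || length(cfg$outcomes) == 0) {
    abort("config needs at least one exposure and one outcome")
  }
  cfg$mvmr_snp_list <- resolve(cfg$mvmr_snp_list)
  if (!is.null(cfg$mvmr_snp_list) && !file.exists(cfg$mvmr_snp_list)) {
    abort(paste0("mvmr SNP list missing: ", cfg$mvmr_snp_list))
  }
  cfg$ivw_mode <- cfg$ivw_mode %||% "auto"
  cfg$strict_palindromes <- isTRUE(cfg$strict_palindromes)
  cfg$n_boot <- cfg$n_boot %||% 1000
  cfg$seed <- cfg$seed %||% 1
  cfg$alpha <- cfg$alpha %||% 0.05
  cfg$hash <- rlang::hash(cfg[c("exposures", "outcomes", "mvmr_snp_list",
                                "ivw_mode", "strict_palindromes",
                                "n_boot", "seed", "alpha")])
  structure(cfg, class = "analysis_config")
}

load_cell_set <- function(entry, column_map = NULL) {
  read_associations(entry$path, column_map = column_map,
                    exposure_name = entry$name,
                    stratum = entry$stratum %||% "overall",
                    r_squared = entry$r_squared,
                    n_gwas = entry$n_gwas)
}

cell_label <- function(exposure, outcome, stratum) {
  paste(exposure, outcome, stratum, sep = " / ")
}

# Run `fn` for one grid cell, converting any error into a failure row.
run_cell <- function(label, fn) {
  tryCatch(fn(), error = function(e) {
    message("[", label, "] failed: ", conditionMessage(e))
    tibble(cell = label, error = conditionMessage(e))
  })
}

#' Run the univariable analysis grid
#'
#' For every exposure x outcome pair sharing a stratum: harmonize, then
#' IVW (mode from the config), MR-Egger, and the weighted median. Each
#' estimate becomes one result row; rows carry the config hash and seed
#' for provenance. Failed cells are reported in the `failures` attribute.
#'
#' @param config An `analysis_config` from [read_analysis_config()].
#' @return A result-table tibble (see [write_results_table()]) with
#'   attributes `failures` (tibble) and `provenance`.
#' @export
run_univariable_grid <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  rows <- list()
  failures <- list()
  for (e in config$exposures) {
    for (o in config$outcomes) {
      if (!identical(e$stratum, o$stratum)) next
      label <- cell_label(e$name, o$name, o$stratum)
      res <- run_cell(label, function() {
        exp_set <- load_cell_set(e, config$column_map)
        out_set <- load_cell_set(o, config$column_map)
        hs <- harmonize(exp_set, out_set,
                        strict_palindromes = config$strict_palindromes)
        ests <- list(
          mr_ivw(hs, mode = config$ivw_mode, alpha = config$alpha),
          mr_egger(hs, alpha = config$alpha),
          mr_weighted_median(hs, n_boot = config$n_boot,
                             seed = config$seed, alpha = config$alpha)
        )
        tbl <- as_results_table(purrr::map(ests, function(x) {
          x$exposure <- e$name; x$outcome <- o$name; x$stratum <- o$stratum
          x
        }))
        tbl
      })
      if ("error" %in% names(res)) failures[[label]] <- res else
        rows[[label]] <- res
    }
  }
  finish_grid(rows, failures, config)
}

#' Run the multivariable analysis grid
#'
#' For every outcome x stratum cell with both exposures available in that
#' stratum: build the multivariable instrument (the supplied SNP list or
#' the union of the two instruments), harmonize with two exposures, then
#' multivariable IVW, conditional F for both exposures, Q_a, and
#' multivariable MR-Egger. When both `men` and `women` strata yield
#' estimates for an outcome, a between-sex heterogeneity p-value is
#' appended in the `sex_heterogeneity` attribute.
#'
#' @inheritParams run_univariable_grid
#' @return A tibble with one row per outcome x stratum x exposure term,
#'   columns for direct effects, conditional F and Q_a; attributes
#'   `failures`, `sex_heterogeneity`, `provenance`.
#' @export
run_multivariable_grid <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  snp_keep <- if (!is.null(config$mvmr_snp_list)) {
    readr::read_lines(config$mvmr_snp_list)
  }
  rows <- list()
  failures <- list()
  strata <- unique(purrr::map_chr(config$outcomes, "stratum"))
  for (st in strata) {
    exps <- purrr::keep(config$exposures, ~ identical(.x$stratum, st))
    if (length(exps) < 2) next
    e1 <- exps[[1]]; e2 <- exps[[2]]
    for (o in purrr::keep(config$outcomes, ~ identical(.x$stratum, st))) {
      label <- cell_label("mvmr", o$name, st)
      res <- run_cell(label, function() {
        s1 <- load_cell_set(e1, config$column_map)
        s2 <- load_cell_set(e2, config$column_map)
        out_set <- load_cell_set(o, config$column_map)
        keep <- snp_keep %||% union_instrument_set(s1, s2)
        s1k <- filter_set(s1, keep)
        s2k <- filter_set(s2, keep)
        hs <- harmonize(s1k, out_set, exposure2 = s2k,
                        strict_palindromes = config$strict_palindromes)
        fit <- mvmr_ivw(hs, alpha = config$alpha)
        cs <- conditional_strength(hs, fit = fit)
        eg <- mvmr_egger(hs, alpha = config$alpha)
        dplyr::bind_rows(
          dplyr::mutate(tidy(fit), outcome = o$name, stratum = st,
                        exposure = ifelse(.data$term == "exposure1",
                                          e1$name, e2$name),
                        f_cond = ifelse(.data$term == "exposure1",
                                        cs$f_cond_1, cs$f_cond_2),
                        q_a = cs$q_a, q_a_df = cs$q_a_df,
                        q_a_pvalue = cs$q_a_pvalue),
          dplyr::mutate(tidy(eg), outcome = o$name, stratum = st,
                        exposure = ifelse(.data$term == "exposure1",
                                          e1$name, e2$name),
                        egger_intercept = eg$intercept,
                        egger_intercept_pvalue = eg$intercept_pvalue)
        )
      })
      if ("error" %in% names(res)) failures[[label]] <- res else
        rows[[label]] <- res
    }
  }
  out <- finish_grid(rows, failures, config)

  # men-vs-women heterogeneity per outcome and exposure term
  het <- tibble()
  if (nrow(out) > 0 && all(c("stratum", "outcome") %in% names(out))) {
    mvmr_rows <- dplyr::filter(out, .data$method == "mvmr_ivw",
                               .data$stratum %in% c("men", "women"))
    if (nrow(mvmr_rows) > 0) {
      het <- mvmr_rows |>
        dplyr::group_by(.data$outcome, .data$term) |>
        dplyr::filter(dplyr::n() == 2) |>
        dplyr::summarise(
          p_heterogeneity = subgroup_heterogeneity(
            data.frame(theta = .data$estimate,
                       se = .data$std.error))$pvalue,
          .groups = "drop")
    }
  }
  attr(out, "sex_heterogeneity") <- het
  out
}

filter_set <- function(set, rsids) {
  m <- set_meta(set)
  df <- as_tibble(as.data.frame(set))
  df <- df[df$rsid %in% rsids, , drop = FALSE]
  if (nrow(df) == 0) abort("SNP filter removed every SNP")
  instrument_set(df, exposure_name = m$exposure_name, stratum = m$stratum,
                 r_squared = m$r_squared, n_gwas = m$n_gwas)
}

finish_grid <- function(rows, failures, config) {
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else tibble()
  if (nrow(out) > 0) {
    out$config_hash <- config$hash
    out$seed <- config$seed
  }
  fail_tbl <- if (length(failures) > 0) dplyr::bind_rows(failures) else
    tibble(cell = character(), error = character())
  if (nrow(fail_tbl) > 0) {
    message(nrow(fail_tbl), " grid cell(s) failed; see attr(, 'failures')")
  }
  attr(out, "failures") <- fail_tbl
  attr(out, "provenance") <- list(config_hash = config$hash,
                                  seed = config$seed)
  out
}

#' Run the a priori power report
#'
#' Analytic power at an odds-ratio grid (default 1.05 to 1.50 by 0.05)
#' for every exposure x outcome pair sharing a stratum, using the
#' exposure's `r_squared` and the outcome's case/control counts from the
#' config. Deterministic: regenerating with the same config is
#' byte-identical.
#'
#' @inheritParams run_univariable_grid
#' @param or_grid Odds ratios to evaluate.
#' @return A tibble: exposure, outcome, stratum, odds_ratio, power,
#'   plus provenance columns.
#' @export
run_power_report <- function(config, or_grid = seq(1.05, 1.50, by = 0.05)) {
  stopifnot(inherits(config, "analysis_config"))
  rows <- list()
  for (e in config$exposures) {
    for (o in config$outcomes) {
      if (!identical(e$stratum, o$stratum)) next
      if (is.null(e$r_squared) || is.null(o$n_cases) ||
          is.null(o$n_controls)) next
      rows[[cell_label(e$name, o$name, o$stratum)]] <- tibble(
        exposure = e$name, outcome = o$name, stratum = o$stratum,
        odds_ratio = or_grid,
        power = mr_power_binary(o$n_cases, o$n_controls, e$r_squared,
                                or_grid, config$alpha))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) {
    out$config_hash <- config$hash
    out$seed <- config$seed
  }
  out
}

#' Plot-ready forest table
#'
#' Reduces a result table to the four columns external forest-plot tools
#' expect.
#'
#' @param results A result-table tibble.
#' @param path Optional TSV output path.
#' @return A tibble: `label`, `or_`, `ci_low`, `ci_high`, `group`.
#' @export
forest_table <- function(results, path = NULL) {
  tbl <- as_tibble(results)
  theta <- if ("beta" %in% names(tbl)) tbl$beta else tbl$estimate
  se <- if ("se" %in% names(tbl)) tbl$se else tbl$std.error
  z <- qnorm(0.975)
  out <- tibble(
    label = paste(tbl$exposure, tbl$outcome, tbl$stratum, sep = " | "),
    or_ = exp(theta),
    ci_low = exp(theta - z * se),
    ci_high = exp(theta + z * se),
    group = tbl$method
  )
  if (!is.null(path)) readr::write_tsv(out, path, progress = FALSE)
  out
}
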
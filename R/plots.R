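# ggplot2 displays for result tables and fitted objects.

#' Forest plot of MR estimates
#'
#' @param results A result-table tibble (from [run_univariable_grid()],
#'   [as_results_table()], or [forest_table()]).
#' @param log_scale Plot the OR axis on the log scale (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_forest <- function(results, log_scale = TRUE) {
  tbl <- if (all(c("label", "or_", "ci_low", "ci_high") %in%
                 names(results))) {
    as_tibble(results)
  } else {
    forest_table(results)
  }
  p <- ggplot2::ggplot(tbl, ggplot2::aes(x = .data$or_, y = .data$label,
                                         colour = .data$group)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high),
                             position = ggplot2::position_dodge(0.5)) +
    ggplot2::labs(x = "Odds ratio per category change", y = NULL,
                  colour = "Method") +
    ggplot2::theme_minimal()
  if (log_scale) p <- p + ggplot2::scale_x_log10()
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.mvmr_fit <- function(object, ...) {
  tbl <- tidy(object)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$or, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$or.low,
                                          xmax = .data$or.high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio per category change (direct effect)",
                  y = NULL, title = object$method) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.mr_power_curve <- function(object, target = 0.8, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$odds_ratio,
                                       y = .data$power)) +
    ggplot2::geom_hline(yintercept = target, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Odds ratio per category change", y = "Power") +
    ggplot2::theme_minimal()
}

#' Scatter display of a harmonized set with fitted slopes
#'
#' SNP-level exposure betas against outcome betas (oriented so exposure
#' betas are positive), with the IVW through-origin slope and, when
#' requested, the MR-Egger line.
#'
#' @param set A `harmonized_set` (single exposure).
#' @param egger Overlay the MR-Egger fit (default `TRUE` when `L >= 3`).
#' @return A ggplot object.
#' @export
plot_snp_effects <- function(set, egger = NULL) {
  df <- orient_positive(as_tibble(as.data.frame(set)))
  egger <- egger %||% (nrow(df) >= 3)
  ivw <- mr_ivw(set)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$gamma1, y = .data$Gamma)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$Gamma - .data$se_G,
                                        ymax = .data$Gamma + .data$se_G),
                           colour = "grey70", width = 0) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = 0, slope = ivw$theta,
                         colour = "#2166ac") +
    ggplot2::labs(x = "SNP effect on exposure (per category)",
                  y = "SNP effect on outcome (log odds)") +
    ggplot2::theme_minimal()
  if (egger) {
    eg <- mr_egger(set)
    p <- p + ggplot2::geom_abline(intercept = eg$egger_intercept,
                                  slope = eg$theta, colour = "#b2182b",
                                  linetype = "longdash")
  }
  p
}
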
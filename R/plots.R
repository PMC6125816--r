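#' Behavioral measures across the life span
#'
#' Scatter plots of SSRT, Go RT, and accuracies against age with linear
#' trends, one panel per measure.
#'
#' @param summaries Per-subject behavior tibble with `age_years` and the
#'   measures from [summarize_performance()].
#' @return A ggplot object.
#' @export
plot_behavior_age <- function(summaries) {
  long <- tidyr::pivot_longer(
    summaries[, c("age_years", "ssrt_ms", "go_rt_mean_ms", "go_accuracy", "nogo_accuracy")],
    -"age_years", names_to = "measure", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$age_years, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linewidth = 0.6, color = "firebrick") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "Age (years)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Peri-event component time courses by condition
#'
#' @param peri_tbl Tibble binding [peri_event_average()] results with a
#'   `condition` column (and optionally `component`).
#' @return A ggplot object.
#' @export
plot_peri_event <- function(peri_tbl) {
  p <- ggplot2::ggplot(peri_tbl,
                       ggplot2::aes(x = .data$time_s, y = .data$mean_response,
                                    color = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time from onset (s)", y = "Response (baseline-corrected)") +
    ggplot2::theme_minimal()
  if ("component" %in% names(peri_tbl)) {
    p <- p + ggplot2::facet_wrap(~component)
  }
  p
}

#' Connectivity matrix heat map
#'
#' @param conn_long Long connectivity tibble (`comp_i`, `comp_j`, `value`),
#'   e.g. group means from [subject_connectivity()] output.
#' @return A ggplot object.
#' @export
plot_connectivity_matrix <- function(conn_long) {
  sym <- bind_rows(conn_long,
                   dplyr::rename(conn_long, comp_i = "comp_j", comp_j = "comp_i"))
  ggplot2::ggplot(sym, ggplot2::aes(x = factor(.data$comp_i),
                                    y = factor(.data$comp_j),
                                    fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    ggplot2::labs(x = "Component", y = "Component", fill = "Connectivity") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.stopnet_prediction <- function(object, ...) {
  dat <- tibble(score = object$subject_scores, y = object$y_used)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$score, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "firebrick", linewidth = 0.6) +
    ggplot2::labs(x = "Held-out subject score (predicted SSRT)",
                  y = "Observed SSRT (covariate-adjusted)",
                  title = sprintf("r = %.3f", object$observed_r)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.stopnet_ica <- function(object, ...) {
  dat <- tidy.stopnet_ica(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$component),
                                    y = .data$stability,
                                    fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Component", y = "Stability index", fill = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
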
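#' Tidy a cross-validated prediction
#'
#' One row per training fold and feature: the shrinkage-regression weight.
#'
#' @param x A `stopnet_prediction`.
#' @param ... Unused.
#' @return Tibble `fold`, `feature`, `weight`, `gamma`.
#' @exportS3Method generics::tidy
tidy.stopnet_prediction <- function(x, ...) {
  bind_rows(lapply(seq_along(x$weights), function(f) {
    w <- x$weights[[f]]
    tibble(fold = f, feature = names(w) %||% as.character(seq_along(w)),
           weight = as.numeric(w), gamma = x$gamma[f])
  }))
}

#' @describeIn tidy.stopnet_prediction One-row model summary.
#' @exportS3Method generics::glance
glance.stopnet_prediction <- function(x, ...) {
  tibble(observed_r = x$observed_r, k = x$k, n = x$n,
         mean_gamma = mean(x$gamma))
}

#' Tidy a moderation analysis
#' @param x A `stopnet_moderation`.
#' @param ... Unused.
#' @return The coefficients tibble (term, estimate, t, p, partial_r).
#' @exportS3Method generics::tidy
tidy.stopnet_moderation <- function(x, ...) x$coefficients

#' @describeIn tidy.stopnet_moderation One-row fit summary.
#' @exportS3Method generics::glance
glance.stopnet_moderation <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r_squared = s$r.squared, adj_r_squared = s$adj.r.squared, n = x$n)
}

#' Tidy a group ICA decomposition
#' @param x A `stopnet_ica`.
#' @param ... Unused.
#' @return Tibble `component`, `stability`, `label`.
#' @exportS3Method generics::tidy
tidy.stopnet_ica <- function(x, ...) {
  tibble(component = seq_len(x$order_k),
         stability = x$stability_index,
         label = x$labels)
}

#' @describeIn tidy.stopnet_ica One-row decomposition summary.
#' @exportS3Method generics::glance
glance.stopnet_ica <- function(x, ...) {
  tibble(order_k = x$order_k, n_runs_used = x$n_runs_used,
         mean_stability = mean(x$stability_index),
         n_signal = sum(x$labels == "signal", na.rm = TRUE))
}

#' Tidy an SSRT estimate
#' @param x An `ssrt_estimate`.
#' @param ... Unused.
#' @return The per-block tibble.
#' @exportS3Method generics::tidy
tidy.ssrt_estimate <- function(x, ...) x$blocks

#' @describeIn tidy.ssrt_estimate One-row subject summary.
#' @exportS3Method generics::glance
glance.ssrt_estimate <- function(x, ...) {
  tibble(ssrt_ms = x$ssrt_ms, n_blocks = sum(x$blocks$estimable))
}

#' @export
print.stopnet_prediction <- function(x, ...) {
  cat(sprintf("Cross-validated prediction (k = %d, n = %d)\n", x$k, x$n))
  cat(sprintf("  observed r = %.3f; mean shrinkage gamma = %.3f\n",
              x$observed_r, mean(x$gamma)))
  invisible(x)
}

#' @export
print.stopnet_ica <- function(x, ...) {
  cat(sprintf("Group ICA: %d components from %d runs; mean stability %.3f\n",
              x$order_k, x$n_runs_used, mean(x$stability_index)))
  invisible(x)
}

#' @export
print.ssrt_estimate <- function(x, ...) {
  cat(sprintf("SSRT (block-based integration): %.1f ms over %d block(s)\n",
              x$ssrt_ms, sum(x$blocks$estimable)))
  invisible(x)
}
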
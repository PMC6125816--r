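#' Classify components as signal or physiological/scanner noise
#'
#' A component is labeled noise when the ratio of spectral power above
#' `freq_cut_hz` to power below it (computed on the group time course)
#' exceeds `ratio_threshold`, or when its spatial map correlates more
#' strongly with a designated non-neuronal reference map than with any
#' signal reference map.
#'
#' @param ica A `stopnet_ica` object.
#' @param tr_s Repetition time in seconds (sampling interval of the TCs).
#' @param freq_cut_hz Boundary between "low" and "high" frequency power
#'   (default 0.1 Hz).
#' @param ratio_threshold High/low power ratio above which a component is
#'   noise (default 0.9).
#' @param reference_maps Optional matrix `[references x voxels]` of
#'   template maps.
#' @param reference_labels Character vector (`"signal"` / `"noise"`) for the
#'   reference maps.
#' @return Tibble with `component`, `freq_ratio`, `best_reference`,
#'   `label`; the labels are also written into `ica$labels` when the result
#'   is passed to [set_component_labels()].
#' @export
classify_noise_components <- function(ica, tr_s, freq_cut_hz = 0.1,
                                      ratio_threshold = 0.9,
                                      reference_maps = NULL,
                                      reference_labels = NULL) {
  stopifnot(inherits(ica, "stopnet_ica"), tr_s > 0)
  k <- ica$order_k
  ratios <- vapply(seq_len(k), function(i) {
    spectral_ratio(ica$group_tcs[, i], tr_s, freq_cut_hz)
  }, numeric(1))
  label <- ifelse(ratios > ratio_threshold, "noise", "signal")
  best_ref <- rep(NA_character_, k)
  if (!is.null(reference_maps)) {
    stopifnot(!is.null(reference_labels),
              nrow(reference_maps) == length(reference_labels))
    r <- abs(cor(t(ica$spatial_maps), t(reference_maps)))
    for (i in seq_len(k)) {
      b <- which.max(r[i, ])
      best_ref[i] <- as.character(b)
      if (reference_labels[b] == "noise") label[i] <- "noise"
    }
  }
  tibble(component = seq_len(k), freq_ratio = ratios,
         best_reference = best_ref, label = label)
}

spectral_ratio <- function(tc, tr_s, freq_cut_hz) {
  n <- length(tc)
  pw <- Mod(fft(tc - mean(tc)))^2
  freq <- (seq_len(n) - 1) / (n * tr_s)
  keep <- freq > 0 & freq <= 1 / (2 * tr_s)
  hi <- sum(pw[keep & freq > freq_cut_hz])
  lo <- sum(pw[keep & freq <= freq_cut_hz])
  if (lo == 0) return(Inf)
  hi / lo
}

#' Write component labels into an ICA object
#' @param ica A `stopnet_ica`.
#' @param classification Result of [classify_noise_components()].
#' @return The `stopnet_ica` with `labels` filled.
#' @export
set_component_labels <- function(ica, classification) {
  ica$labels <- classification$label[order(classification$component)]
  ica
}
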
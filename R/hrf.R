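#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities: response peak at 6 s, undershoot
#' peaking at 16 s, peak-to-undershoot ratio 6, support truncated at 32 s.
#'
#' @param t Time in seconds (vector).
#' @return HRF values at `t` (zero outside \[0, 32\]).
#' @export
double_gamma_hrf <- function(t) {
  h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0 | t > 32] <- 0
  h
}

# Build one HRF-convolved regressor sampled on the TR grid.
# onsets: event onsets (s); amplitudes: per-event heights (recycled);
# durations currently 0 (delta events) -- convolution on a dt grid.
hrf_regressor <- function(onsets, n_volumes, tr_s, amplitudes = 1, dt = 0.1) {
  if (length(onsets) == 0) return(numeric(n_volumes))
  amplitudes <- rep_len(amplitudes, length(onsets))
  total_s <- n_volumes * tr_s
  grid <- seq(0, total_s + 32, by = dt)
  stick <- numeric(length(grid))
  idx <- pmin(pmax(round(onsets / dt) + 1, 1), length(grid))
  for (k in seq_along(idx)) stick[idx[k]] <- stick[idx[k]] + amplitudes[k]
  # kernel normalized to unit peak: a unit event yields a peak response of
  # 1, so evoked amplitudes are expressed in noise-SD units
  kern <- double_gamma_hrf(seq(0, 32, by = dt))
  kern <- kern / max(kern)
  conv <- convolve(stick, rev(kern), type = "open")[seq_along(grid)]
  sample_t <- (seq_len(n_volumes) - 1) * tr_s
  conv[pmin(round(sample_t / dt) + 1, length(grid))]
}

# Discrete-cosine high-pass basis spanning periods >= cutoff_s (SPM-style).
dct_highpass_basis <- function(n_volumes, tr_s, cutoff_s = 128) {
  total_s <- n_volumes * tr_s
  n_basis <- max(0, floor(2 * total_s / cutoff_s))
  if (n_basis == 0) return(matrix(numeric(0), n_volumes, 0))
  t <- seq_len(n_volumes) - 0.5
  b <- vapply(seq_len(n_basis), function(k) {
    sqrt(2 / n_volumes) * cos(pi * k * t / n_volumes)
  }, numeric(n_volumes))
  colnames(b) <- paste0("dct", seq_len(n_basis))
  b
}
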
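#' Generate a stop-signal/no-go (SNG) task design
#'
#' Builds an ordered trial list for an SNG paradigm: Go trials requiring a
#' left/right response to an arrow, No-Go trials (red arrow from the outset),
#' and Stop-Signal trials (arrow turns red after a variable stop-signal
#' delay). Trial types are randomly interleaved; per-type counts are exact
#' and split as evenly as possible across scanning sessions.
#'
#' @param n_go,n_stop,n_nogo Number of Go, Stop-Signal, and No-Go trials
#'   (defaults 360 / 80 / 40, i.e. 70/20/10 percent).
#' @param n_sessions Number of scanning sessions (runs); default 2.
#' @param iti_s Stimulus-onset asynchrony between consecutive trials in
#'   seconds (default 2.5).
#' @param tr_s Repetition time of the accompanying BOLD acquisition in
#'   seconds (default 2).
#' @param start_s Onset of the first trial within each session (default 4 s).
#' @param seed Integer seed; the design is deterministic given the seed.
#' @return A tibble of class `stopnet_design` with columns `trial`,
#'   `session`, `trial_type` (factor Go/NoGo/Stop), `onset_s`, `arrow_dir`
#'   (left/right). Attributes `tr_s` and `n_volumes_per_session` describe
#'   the matching acquisition grid.
#' @examples
#' d <- generate_task_design(seed = 1)
#' table(d$trial_type)
#' @export
generate_task_design <- function(n_go = 360, n_stop = 80, n_nogo = 40,
                                 n_sessions = 2, iti_s = 2.5, tr_s = 2,
                                 start_s = 4, seed = 1) {
  if (any(c(n_go, n_stop, n_nogo) < 0)) {
    abort("trial counts must be non-negative", class = "stopnet_config_error")
  }
  if (n_sessions < 1) abort("n_sessions must be >= 1", class = "stopnet_config_error")
  stopifnot(iti_s > 0, tr_s > 0)

  # split each type's count as evenly as possible across sessions
  split_count <- function(n) {
    base <- n %/% n_sessions
    extra <- n %% n_sessions
    base + (seq_len(n_sessions) <= extra)
  }
  per_sess <- cbind(Go = split_count(n_go), Stop = split_count(n_stop),
                    NoGo = split_count(n_nogo))

  with_seed(seed, {
    sessions <- lapply(seq_len(n_sessions), function(s) {
      types <- rep(c("Go", "Stop", "NoGo"), times = per_sess[s, ])
      types <- sample(types)
      k <- length(types)
      tibble(
        session = s,
        trial_type = factor(types, levels = c("Go", "NoGo", "Stop")),
        onset_s = start_s + (seq_len(k) - 1) * iti_s,
        arrow_dir = sample(c("left", "right"), k, replace = TRUE)
      )
    })
    out <- bind_rows(sessions)
    out$trial <- seq_len(nrow(out))
    out <- out[, c("trial", "session", "trial_type", "onset_s", "arrow_dir")]
    sess_len <- vapply(sessions, function(x) {
      if (nrow(x) == 0) start_s else max(x$onset_s)
    }, numeric(1))
    n_vol <- ceiling((max(sess_len) + 32) / tr_s)
    structure(out,
      class = c("stopnet_design", class(out)),
      tr_s = tr_s, n_volumes_per_session = n_vol, iti_s = iti_s,
      n_sessions = n_sessions, seed = seed
    )
  })
}

design_tr <- function(design) attr(design, "tr_s") %||% 2
design_n_volumes <- function(design) {
  attr(design, "n_volumes_per_session") %||%
    ceiling((max(design$onset_s) + 32) / design_tr(design))
}
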
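#' Write behavioral trials as a BIDS-style events TSV
#'
#' Columns: onset, duration, trial_type, response, response_time (s), ssd
#' (s), plus session and outcome category. One file per session when
#' `behavior` spans several.
#'
#' @param behavior A `stopnet_behavior` tibble.
#' @param path Output file (session number is infixed for multi-session
#'   input, e.g. `events.tsv` becomes `events_run-1.tsv`).
#' @return Invisibly, the written paths.
#' @export
write_events_tsv <- function(behavior, path) {
  sessions <- sort(unique(behavior$session))
  paths <- vapply(sessions, function(s) {
    b <- behavior[behavior$session == s, ]
    tab <- tibble(
      onset = b$onset_s,
      duration = 0,
      trial_type = as.character(b$trial_type),
      response = b$response,
      response_time = b$rt_ms / 1000,
      ssd = b$ssd_ms / 1000,
      category = b$category,
      session = b$session
    )
    p <- if (length(sessions) > 1) {
      sub("(\\.tsv)?$", sprintf("_run-%d.tsv", s), path)
    } else path
    readr::write_tsv(tab, p, na = "n/a")
    p
  }, character(1))
  invisible(paths)
}

#' Read a BIDS-style events TSV back into a behavior table
#' @param paths One file per session, in session order.
#' @param tr_s,n_volumes_per_session Acquisition grid to attach.
#' @return A `stopnet_behavior`-compatible tibble.
#' @export
read_events_tsv <- function(paths, tr_s = 2, n_volumes_per_session = NULL) {
  tabs <- lapply(seq_along(paths), function(i) {
    t <- readr::read_tsv(paths[i], na = "n/a", show_col_types = FALSE)
    tibble(
      trial = NA_integer_,
      session = if ("session" %in% names(t)) t$session else i,
      trial_type = factor(t$trial_type, levels = c("Go", "NoGo", "Stop")),
      onset_s = t$onset,
      arrow_dir = NA_character_,
      responded = !is.na(t$response_time),
      response = t$response,
      rt_ms = t$response_time * 1000,
      ssd_ms = t$ssd * 1000,
      category = t$category
    )
  })
  out <- bind_rows(tabs)
  out$trial <- seq_len(nrow(out))
  structure(out, class = c("stopnet_behavior", class(out)),
            tr_s = tr_s, n_volumes_per_session = n_volumes_per_session)
}

#' Write realignment parameters as a confounds TSV
#' @param motion Realignment tibble (trans_x..rot_z).
#' @param path Output file.
#' @export
write_confounds_tsv <- function(motion, path) {
  readr::write_tsv(motion[, c("trans_x", "trans_y", "trans_z",
                              "rot_x", "rot_y", "rot_z")], path)
  invisible(path)
}

#' Write a BOLD session as NIfTI with a JSON sidecar
#'
#' Requires the `RNifti` package. The voxel matrix is reshaped onto the
#' ground-truth lattice as a 4-D volume; TR and session metadata go to the
#' sidecar.
#'
#' @param bold A `stopnet_bold` object.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the written NIfTI paths.
#' @export
write_bold_nifti <- function(bold, dir, prefix = "bold") {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("RNifti is required to write NIfTI volumes", class = "stopnet_input_error")
  }
  grid <- bold$truth$grid
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(bold$sessions, function(s) {
    arr <- array(t(s$Y), dim = c(grid, nrow(s$Y)))
    p <- file.path(dir, sprintf("%s_run-%d.nii.gz", prefix, s$session))
    RNifti::writeNifti(RNifti::asNifti(arr, pixdim = c(3, 3, 3, bold$tr_s)), p)
    jsonlite::write_json(
      list(RepetitionTime = bold$tr_s, Session = s$session),
      file.path(dir, sprintf("%s_run-%d.json", prefix, s$session)),
      auto_unbox = TRUE
    )
    p
  }, character(1))
  invisible(paths)
}
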
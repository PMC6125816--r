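#' Build per-session GLM design matrices from behavioral outcomes
#'
#' Event regressors are built per outcome category (not nominal trial type):
#' correctGo, correctNoGo, SuccStop, UnsuccStop as conditions of interest;
#' GoCommission, GoOmission, NoGoCommission, EarlySS, IncorrectSS as
#' conditions of no interest. Events are delta functions at onset convolved
#' with the double-gamma HRF and sampled at the TR. Nuisance columns are the
#' six realignment parameters and a discrete-cosine high-pass basis spanning
#' periods of 128 s and longer. Categories with zero events are omitted and
#' recorded.
#'
#' @param behavior A `stopnet_behavior` tibble.
#' @param motion List of per-session realignment tibbles (or `NULL`).
#' @param tr_s Repetition time (s); defaults to the behavior attribute.
#' @param n_volumes Volumes per session; defaults to the behavior attribute.
#' @param highpass_s High-pass cutoff period in seconds (default 128).
#' @return List of class `stopnet_design_matrix`, one element per session:
#'   `X` (numeric matrix with named columns incl. intercept), `task_cols`,
#'   `psych_cols` (conditions of interest), `confound_cols`,
#'   `omitted_conditions`, `session`, `tr_s`.
#' @export
build_design_matrix <- function(behavior, motion = NULL, tr_s = NULL,
                                n_volumes = NULL, highpass_s = 128) {
  tr_s <- tr_s %||% attr(behavior, "tr_s") %||% 2
  n_volumes <- n_volumes %||% attr(behavior, "n_volumes_per_session")
  if (is.null(n_volumes)) {
    abort("n_volumes must be supplied when behavior carries no attribute",
          class = "stopnet_config_error")
  }
  categories <- c("correctGo", "correctNoGo", "SuccStop", "UnsuccStop",
                  "GoCommission", "GoOmission", "NoGoCommission",
                  "EarlySS", "IncorrectSS")
  sessions <- sort(unique(behavior$session))
  out <- lapply(seq_along(sessions), function(si) {
    s <- sessions[si]
    beh <- behavior[behavior$session == s, ]
    cols <- list()
    omitted <- character(0)
    for (cc in categories) {
      onsets <- beh$onset_s[beh$category == cc]
      if (length(onsets) == 0) {
        omitted <- c(omitted, cc)
      } else {
        cols[[cc]] <- hrf_regressor(onsets, n_volumes, tr_s)
      }
    }
    task_cols <- names(cols)
    X_task <- do.call(cbind, cols)
    X_conf <- NULL
    conf_names <- character(0)
    if (!is.null(motion)) {
      mp <- as.matrix(motion[[si]][, c("trans_x", "trans_y", "trans_z",
                                       "rot_x", "rot_y", "rot_z")])
      if (nrow(mp) != n_volumes) {
        abort("motion rows must equal n_volumes", class = "stopnet_config_error")
      }
      X_conf <- mp
      conf_names <- colnames(mp)
    }
    dct <- dct_highpass_basis(n_volumes, tr_s, highpass_s)
    X <- cbind(X_task, X_conf, dct, intercept = 1)
    colnames(X) <- c(task_cols, conf_names, colnames(dct), "intercept")
    list(X = X, task_cols = task_cols,
         psych_cols = intersect(c("correctGo", "correctNoGo", "SuccStop", "UnsuccStop"),
                                task_cols),
         confound_cols = c(conf_names, colnames(dct)),
         omitted_conditions = omitted, session = s, tr_s = tr_s)
  })
  structure(out, class = "stopnet_design_matrix")
}

#' Ordinary least-squares fit of a component time course on a design matrix
#'
#' @param tc Numeric vector (one session's component time course).
#' @param design_session One element of a [build_design_matrix()] result (or
#'   a plain matrix).
#' @return Named numeric vector of coefficients.
#' @export
component_glm <- function(tc, design_session) {
  X <- if (is.list(design_session)) design_session$X else design_session
  if (length(tc) != nrow(X)) abort("tc and design rows differ", class = "stopnet_input_error")
  q <- qr(X)
  if (q$rank < ncol(X)) {
    dropped <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    abort(paste("design matrix is rank deficient; collinear columns:",
                paste(dropped, collapse = ", ")),
          class = "stopnet_collinearity_error")
  }
  beta <- qr.coef(q, tc)
  setNames(as.numeric(beta), colnames(X))
}

#' Responsivity index: contrast of condition betas averaged over sessions
#'
#' @param betas_by_session List of named coefficient vectors (one per
#'   session, from [component_glm()]).
#' @param contrast Two condition names, difference `first - second`
#'   (default SuccStop - UnsuccStop).
#' @return Scalar responsivity; attribute `n_sessions_used` flags cases
#'   where a session lacked one of the conditions.
#' @export
responsivity_index <- function(betas_by_session,
                               contrast = c("SuccStop", "UnsuccStop")) {
  vals <- vapply(betas_by_session, function(b) {
    if (!all(contrast %in% names(b))) return(NA_real_)
    unname(b[contrast[1]] - b[contrast[2]])
  }, numeric(1))
  ok <- is.finite(vals)
  if (!any(ok)) return(structure(NA_real_, n_sessions_used = 0L))
  structure(mean(vals[ok]), n_sessions_used = sum(ok))
}

#' Subject-by-component responsivity table
#'
#' Fits the component GLM per session for every signal component of every
#' subject and assembles the SuccStop - UnsuccStop responsivity indices.
#'
#' @param subject_tcs_sessions List (subjects) of lists (sessions) of
#'   `[time x components]` matrices.
#' @param design_matrices List (subjects) of [build_design_matrix()]
#'   results.
#' @param contrast Condition pair, see [responsivity_index()].
#' @return Matrix `[subjects x components]`.
#' @export
responsivity_table <- function(subject_tcs_sessions, design_matrices,
                               contrast = c("SuccStop", "UnsuccStop")) {
  n_sub <- length(subject_tcs_sessions)
  stopifnot(length(design_matrices) == n_sub)
  k <- ncol(subject_tcs_sessions[[1]][[1]])
  out <- matrix(NA_real_, n_sub, k)
  for (i in seq_len(n_sub)) {
    dms <- design_matrices[[i]]
    for (ci in seq_len(k)) {
      betas <- lapply(seq_along(dms), function(si) {
        component_glm(subject_tcs_sessions[[i]][[si]][, ci], dms[[si]])
      })
      out[i, ci] <- responsivity_index(betas, contrast)
    }
  }
  colnames(out) <- paste0("IC", seq_len(k))
  out
}
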
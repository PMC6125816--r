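#' Synthesize BOLD-like voxel data from a task design and ground truth
#'
#' Forward model per session: each latent component's time course is the sum
#' of condition onsets convolved with the double-gamma HRF times the
#' component's evoked amplitudes, plus stochastic fluctuations whose
#' cross-component correlation equals `base_coupling` outside stop epochs
#' and `base_coupling +/- coupling_modulation / 2` inside successful /
#' unsuccessful stop epochs (a window of `epoch_window_s` seconds from each
#' Stop-Signal onset). Voxel data are the spatial maps mixed with these time
#' courses, plus motion-derived nuisance and white voxel noise.
#'
#' @param design A `stopnet_design`.
#' @param behavior Matching `stopnet_behavior` (categories drive the evoked
#'   regressors and epoch labels).
#' @param truth A [ground_truth_spec()].
#' @param motion List with one realignment tibble per session (or `NULL`
#'   for no motion nuisance).
#' @param seed Integer seed.
#' @return Object of class `stopnet_bold`: list with `sessions` (each with
#'   `Y` `[time x voxels]`, `tcs_true` `[time x components]`, `epoch_state`),
#'   `truth`, `tr_s`.
#' @export
synthesize_bold <- function(design, behavior, truth, motion = NULL, seed = 1) {
  stopifnot(inherits(truth, "ground_truth_spec"))
  if (nrow(design) != nrow(behavior)) {
    abort("design and behavior have different numbers of trials",
          class = "stopnet_config_error")
  }
  tr <- design_tr(design)
  n_vol <- design_n_volumes(design)
  sessions <- sort(unique(design$session))
  if (!is.null(motion)) {
    if (length(motion) != length(sessions)) {
      abort("motion must have one table per session", class = "stopnet_config_error")
    }
    for (m in motion) {
      if (nrow(m) != n_vol) {
        abort("motion rows must match volumes per session", class = "stopnet_config_error")
      }
    }
  }
  seeds <- derive_seeds(seed, length(sessions) + 1)
  k <- truth$n_components
  v <- ncol(truth$spatial_maps)

  # fixed voxel projection of the motion parameters
  w_motion <- with_seed(seeds[length(seeds)], matrix(rnorm(6 * v, 0, 1 / sqrt(v) * 8), 6, v))

  out_sessions <- lapply(seq_along(sessions), function(si) {
    s <- sessions[si]
    beh <- behavior[behavior$session == s, ]
    tcs <- simulate_component_tcs(beh, truth, n_vol, tr, seed = seeds[si])
    Y <- tcs$tcs %*% truth$spatial_maps
    if (!is.null(motion) && truth$motion_artifact_gain > 0) {
      mp <- as.matrix(motion[[si]][, c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")])
      mp <- apply(mp, 2, function(col) if (sd(col) == 0) col * 0 else as.numeric(scale(col)))
      Y <- Y + truth$motion_artifact_gain * (mp %*% w_motion)
    }
    if (truth$voxel_noise_sd > 0) {
      Y <- Y + with_seed(seeds[si] + 1L,
                         matrix(rnorm(n_vol * v, 0, truth$voxel_noise_sd), n_vol, v))
    }
    list(Y = Y, tcs_true = tcs$tcs, epoch_state = tcs$epoch_state, session = s)
  })

  structure(list(sessions = out_sessions, truth = truth, tr_s = tr,
                 n_volumes_per_session = n_vol),
            class = "stopnet_bold")
}

# Per-session component time courses: HRF-convolved evoked responses plus
# epoch-dependent correlated fluctuations. Internal; also used directly by
# the connectivity power/null simulations.
simulate_component_tcs <- function(behavior, truth, n_vol, tr_s, seed = 1) {
  k <- truth$n_components
  ev <- truth$evoked_amplitudes
  cond_onsets <- list(
    Go = behavior$onset_s[behavior$category %in% c("correctGo", "GoCommission")],
    NoGo = behavior$onset_s[behavior$category %in% c("correctNoGo", "NoGoCommission")],
    SuccStop = behavior$onset_s[behavior$category == "SuccStop"],
    UnsuccStop = behavior$onset_s[behavior$category %in% c("UnsuccStop", "EarlySS", "IncorrectSS")]
  )
  regs <- vapply(names(cond_onsets), function(cn) {
    hrf_regressor(cond_onsets[[cn]], n_vol, tr_s)
  }, numeric(n_vol))
  evoked <- regs %*% t(ev) # [time x k]

  # epoch state: +1 within window after successful stops, -1 after
  # responded stops, clamped when windows overlap
  t_vol <- (seq_len(n_vol) - 1) * tr_s
  state <- numeric(n_vol)
  succ <- cond_onsets$SuccStop
  unsucc <- cond_onsets$UnsuccStop
  w <- truth$epoch_window_s
  for (o in succ) state <- state + (t_vol >= o & t_vol < o + w)
  for (o in unsucc) state <- state - (t_vol >= o & t_vol < o + w)
  state <- pmin(pmax(state, -1), 1)

  chols <- lapply(c(-1, 0, 1), function(s) {
    t(chol(diag(k) + truth$base_coupling + s * truth$coupling_modulation / 2))
  })
  noise <- with_seed(seed, matrix(rnorm(n_vol * k), n_vol, k))
  for (s in c(-1, 0, 1)) {
    idx <- which(state == s)
    if (length(idx)) {
      noise[idx, ] <- noise[idx, , drop = FALSE] %*% t(chols[[s + 2]])
    }
  }
  # AR(1) smoothing toward a low-frequency spectrum; innovation scaling
  # preserves the stationary variance and lag-zero correlations
  phi <- truth$ar_coef %||% 0
  if (phi > 0) {
    noise <- apply(noise, 2, function(e) {
      as.numeric(stats::filter(e * sqrt(1 - phi^2), phi, method = "recursive",
                               init = e[1]))
    })
  }
  list(tcs = evoked + truth$noise_sd * noise, epoch_state = state)
}
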
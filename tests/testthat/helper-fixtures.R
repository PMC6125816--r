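# Shared fixtures and independent oracles used across the test files.
# Everything is generated in code; no stored data.

# small behavior table with hand-set categories/RTs for SSRT oracles
manual_block_behavior <- function(go_rts, p_target_counts, mean_ssd,
                                  n_omit = 0) {
  # p_target_counts: c(n_stop, n_succ, n_early); onsets spaced 2 s
  n_go <- length(go_rts) + n_omit
  n_stop <- p_target_counts[1]
  rows <- list()
  k <- 0
  add <- function(type, category, rt, ssd) {
    k <<- k + 1
    tibble::tibble(trial = k, session = 1, trial_type = factor(type, levels = c("Go", "NoGo", "Stop")),
                   onset_s = 2 * k, arrow_dir = "left",
                   responded = !is.na(rt), response = ifelse(is.na(rt), "none", "left"),
                   rt_ms = rt, ssd_ms = ssd, category = category)
  }
  for (rt in go_rts) rows <- c(rows, list(add("Go", "correctGo", rt, NA)))
  if (n_omit > 0) for (i in seq_len(n_omit)) rows <- c(rows, list(add("Go", "GoOmission", NA, NA)))
  n_succ <- p_target_counts[2]
  n_early <- p_target_counts[3]
  n_unsucc <- n_stop - n_succ - n_early
  for (i in seq_len(n_succ)) rows <- c(rows, list(add("Stop", "SuccStop", NA, mean_ssd)))
  for (i in seq_len(n_unsucc)) rows <- c(rows, list(add("Stop", "UnsuccStop", mean_ssd + 100, mean_ssd)))
  if (n_early > 0) for (i in seq_len(n_early)) rows <- c(rows, list(add("Stop", "EarlySS", mean_ssd - 50, mean_ssd)))
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("stopnet_behavior", class(out)), tr_s = 2,
            n_volumes_per_session = ceiling((max(out$onset_s) + 32) / 2))
}

# brute-force oracle for the integration SSRT of one block
oracle_block_ssrt <- function(go_rts, n_omit, p, mean_ssd) {
  rts <- sort(c(go_rts, rep(max(go_rts), n_omit)))
  n <- max(1, floor(p * length(rts) + 0.5))
  rts[min(n, length(rts))] - mean_ssd
}

# Benjamini-Hochberg step-up oracle, written from the definition
oracle_bh <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  keep_up_to <- 0
  for (i in seq_len(m)) if (p[ord[i]] <= i / m * alpha) keep_up_to <- i
  mask <- logical(m)
  if (keep_up_to > 0) mask[ord[seq_len(keep_up_to)]] <- TRUE
  mask
}

# Monte-Carlo rigid-body displacement oracle: mean RMS displacement of
# points in a solid sphere under the two parameter sets
oracle_displacement <- function(par1, par2, radius, n_pts = 20000) {
  rot <- function(r) {
    Rx <- matrix(c(1, 0, 0, 0, cos(r[1]), sin(r[1]), 0, -sin(r[1]), cos(r[1])), 3, 3)
    Ry <- matrix(c(cos(r[2]), 0, -sin(r[2]), 0, 1, 0, sin(r[2]), 0, cos(r[2])), 3, 3)
    Rz <- matrix(c(cos(r[3]), sin(r[3]), 0, -sin(r[3]), cos(r[3]), 0, 0, 0, 1), 3, 3)
    Rz %*% Ry %*% Rx
  }
  set.seed(1234)
  # uniform points in a solid sphere
  pts <- matrix(rnorm(3 * n_pts), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) * radius * runif(n_pts)^(1 / 3)
  T1 <- rot(par1[4:6]); T2 <- rot(par2[4:6])
  moved1 <- t(T1 %*% t(pts)) + matrix(par1[1:3], n_pts, 3, byrow = TRUE)
  moved2 <- t(T2 %*% t(pts)) + matrix(par2[1:3], n_pts, 3, byrow = TRUE)
  sqrt(mean(rowSums((moved2 - moved1)^2)))
}

# high-SNR ground truth used for decomposition tests: strong component
# fluctuations relative to voxel noise, no motion nuisance
decomposition_truth <- function(...) {
  ground_truth_spec(noise_sd = 2.5, voxel_noise_sd = 0.5,
                    motion_artifact_gain = 0, ...)
}

# concatenated subject matrices for a small high-SNR cohort
decomposition_cohort_data <- function(n_subjects = 4, seed = 2, truth = decomposition_truth()) {
  co <- generate_cohort(n_subjects, seed = seed, truth = truth)
  lapply(seq_len(n_subjects), function(i) {
    s <- simulate_subject_data(co, i)
    do.call(rbind, lapply(s$bold$sessions, `[[`, "Y"))
  })
}

# component time-course pair with configurable coupling, plus everything
# needed for cPPI: behavior, design matrix, psych contrast
cppi_fixture <- function(seed, mod, base = 0.4, n_stop = 300, duration_s = 4,
                         hrf = FALSE) {
  bc <- matrix(0, 5, 5); bc[1, 2] <- bc[2, 1] <- base
  cm <- matrix(0, 5, 5); cm[1, 2] <- cm[2, 1] <- mod
  tr <- ground_truth_spec(base_coupling = bc, coupling_modulation = cm)
  d <- generate_task_design(n_go = 3.5 * n_stop, n_stop = n_stop,
                            n_nogo = n_stop / 2, n_sessions = 1, seed = seed)
  b <- simulate_race_behavior(d, seed = seed + 1)
  n_vol <- attr(d, "n_volumes_per_session")
  dm <- build_design_matrix(b)
  tcs <- stopnet:::simulate_component_tcs(b, tr, n_vol, 2, seed = seed + 10)$tcs
  psych <- build_psych_contrast(b, n_vol, 2, hrf = hrf, duration_s = duration_s)
  list(tcs = tcs, psych = psych, dm = dm[[1]], behavior = b, n_vol = n_vol)
}
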
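#' Generate a synthetic adult life-span cohort with known ground truth
#'
#' Ages are drawn uniformly over `age_range`. Per-subject behavioral and
#' neural parameters deviate from the group-level [ground_truth_spec()] by
#' the configured age slopes times centered age plus subject-level noise.
#' The injected brain-behavior structure links each subject's true mean stop
#' latency (SSRT) to (a) their responsivity deviation (`beta_activity`) and
#' (b) their coupling-modulation deviation (`beta_modulation`), with the
#' modulation link additionally scaled by age when
#' `age_slopes$moderation_per_year` is nonzero -- the age-moderated
#' connectivity-behavior association the analysis pipeline is meant to
#' recover.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param age_range Two-vector of ages in years (default `c(18, 88)`).
#' @param truth Group-level [ground_truth_spec()].
#' @param beta_activity ms of SSRT per unit responsivity deviation
#'   (default -30: more responsive components, faster stopping).
#' @param beta_modulation ms of SSRT per unit modulation deviation at the
#'   center age (default -25).
#' @param subject_sd List of subject-noise SDs: `act` and `mod` (unit
#'   deviations, default 1), `ssrt_ms` residual SSRT noise (default 15),
#'   `go_rt_ms` residual Go-RT noise (default 20).
#' @param seed Master seed; per-subject seeds are derived from it and are
#'   distinct.
#' @return Object of class `stopnet_cohort`: list with `subjects` tibble
#'   (ids, ages, per-subject race parameters and ground-truth deviations,
#'   seeds) and `truth`.
#' @export
generate_cohort <- function(n_subjects, age_range = c(18, 88),
                            truth = ground_truth_spec(),
                            beta_activity = -30, beta_modulation = -25,
                            subject_sd = list(), seed = 1) {
  if (n_subjects < 2) abort("n_subjects must be >= 2", class = "stopnet_config_error")
  stopifnot(length(age_range) == 2, age_range[1] <= age_range[2])
  sdl <- utils::modifyList(list(act = 1, mod = 1, ssrt_ms = 15, go_rt_ms = 20),
                           subject_sd)
  sl <- truth$age_slopes
  center <- mean(age_range)
  seeds <- derive_seeds(seed, 2L)
  subj_seeds <- derive_seeds(seeds[2], n_subjects)

  with_seed(seeds[1], {
    age <- runif(n_subjects, age_range[1], age_range[2])
    ca <- age - center
    act_dev <- rnorm(n_subjects, 0, sdl$act)
    mod_dev <- rnorm(n_subjects, 0, sdl$mod)
    base <- race_params()
    go_rt_mu <- pmax(base$go_rt_mu + sl$go_rt_ms_per_year * ca +
                       rnorm(n_subjects, 0, sdl$go_rt_ms), 150)
    mod_link <- beta_modulation + sl$moderation_per_year * ca
    ssrt_mu <- pmax(base$ssrt_mu + sl$ssrt_ms_per_year * ca +
                      beta_activity * act_dev + mod_link * mod_dev +
                      rnorm(n_subjects, 0, sdl$ssrt_ms), 50)
    mod_scale <- pmin(pmax(1 + 0.25 * mod_dev +
                             sl$coupling_modulation_per_year * ca, 0), 2)
    subjects <- tibble(
      subject_id = sprintf("sub-%03d", seq_len(n_subjects)),
      age_years = age,
      go_rt_mu = go_rt_mu,
      ssrt_mu = ssrt_mu,
      act_dev = act_dev,
      mod_dev = mod_dev,
      mod_scale = mod_scale,
      motion_severity = 0.03,
      # demographic covariates of no interest (no injected effects)
      gender = sample(c("F", "M"), n_subjects, replace = TRUE),
      handedness = pmin(pmax(round(rnorm(n_subjects, 70, 40)), -100), 100),
      education_years = pmin(pmax(round(rnorm(n_subjects, 14, 3)), 8), 22),
      seed = subj_seeds
    )
  })
  structure(list(subjects = subjects, truth = truth,
                 beta_activity = beta_activity, beta_modulation = beta_modulation,
                 age_range = age_range, seed = seed),
            class = "stopnet_cohort")
}

# Subject-specific ground truth: group spec with the subject's responsivity
# and modulation deviations applied.
subject_truth <- function(cohort, i) {
  tr <- cohort$truth
  s <- cohort$subjects[i, ]
  resp_pattern <- tr$evoked_amplitudes[, "SuccStop"] - tr$evoked_amplitudes[, "UnsuccStop"]
  ev <- tr$evoked_amplitudes
  # subject responsivity = (1 + 0.25 * act_dev) * group pattern
  delta <- 0.25 * s$act_dev * resp_pattern / 2
  ev[, "SuccStop"] <- ev[, "SuccStop"] + delta
  ev[, "UnsuccStop"] <- ev[, "UnsuccStop"] - delta
  tr$evoked_amplitudes <- ev
  tr$coupling_modulation <- tr$coupling_modulation * s$mod_scale
  tr
}

#' Simulate one subject's full dataset (design, behavior, motion, BOLD)
#'
#' @param cohort A [generate_cohort()] object.
#' @param i Subject index.
#' @param design Optional shared `stopnet_design`; by default each subject
#'   gets an independently randomized design with the default trial counts.
#' @param with_bold Generate voxel data (set `FALSE` for behavior-only use).
#' @return List with `subject_id`, `age_years`, `design`, `behavior`,
#'   `motion` (per-session list), and `bold` (or `NULL`).
#' @export
simulate_subject_data <- function(cohort, i, design = NULL, with_bold = TRUE) {
  s <- cohort$subjects[i, ]
  seeds <- derive_seeds(s$seed, 4L)
  if (is.null(design)) design <- generate_task_design(seed = seeds[1])
  params <- race_params(go_rt_mu = s$go_rt_mu, ssrt_mu = s$ssrt_mu)
  behavior <- simulate_race_behavior(design, params, seed = seeds[2])
  n_vol <- design_n_volumes(design)
  n_sessions <- length(unique(design$session))
  motion <- lapply(seq_len(n_sessions), function(ss) {
    simulate_motion(n_vol, severity = s$motion_severity, age = s$age_years,
                    age_slope = cohort$truth$age_slopes$motion_severity_per_year,
                    seed = seeds[3] + ss)
  })
  bold <- NULL
  if (with_bold) {
    bold <- synthesize_bold(design, behavior, subject_truth(cohort, i),
                            motion = motion, seed = seeds[4])
  }
  list(subject_id = s$subject_id, age_years = s$age_years, design = design,
       behavior = behavior, motion = motion, bold = bold)
}

#' Desk-scale measured features for the prediction models
#'
#' Produces the subject-by-feature tables the full pipeline would measure
#' from BOLD data, directly from each subject's ground-truth parameters plus
#' measurement noise: per-component responsivity (the subject's evoked
#' SuccStop - UnsuccStop contrast), per-pair spontaneous coupling (the
#' group base coupling, which carries no subject-level behavioral signal),
#' and per-pair coupling modulation (scaled by the subject's modulation
#' deviation). Used for power and calibration studies of the prediction
#' framework at cohort sizes where voxel-level simulation of every subject
#' would dominate runtime.
#'
#' @param cohort A [generate_cohort()] object.
#' @param noise_sd Measurement noise SD added to every feature (default
#'   0.1).
#' @param seed Integer seed.
#' @return List: `activity` `[n x components]`, `spontaneous` and `cppi`
#'   `[n x pairs]`, `y` (true mean stop latency, ms), `age`.
#' @export
simulate_measured_features <- function(cohort, noise_sd = 0.1, seed = 1) {
  tr <- cohort$truth
  k <- tr$n_components
  n <- nrow(cohort$subjects)
  resp_pattern <- tr$evoked_amplitudes[, "SuccStop"] - tr$evoked_amplitudes[, "UnsuccStop"]
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  pair_names <- paste0(pairs[, 1], "-", pairs[, 2])
  with_seed(seed, {
    act <- t(vapply(seq_len(n), function(i) {
      (1 + 0.25 * cohort$subjects$act_dev[i]) * resp_pattern + rnorm(k, 0, noise_sd)
    }, numeric(k)))
    colnames(act) <- paste0("IC", seq_len(k))
    spont <- t(vapply(seq_len(n), function(i) {
      tr$base_coupling[pairs] + rnorm(nrow(pairs), 0, noise_sd)
    }, numeric(nrow(pairs))))
    colnames(spont) <- paste0("spont_", pair_names)
    cppi <- t(vapply(seq_len(n), function(i) {
      cohort$subjects$mod_scale[i] * tr$coupling_modulation[pairs] +
        rnorm(nrow(pairs), 0, noise_sd)
    }, numeric(nrow(pairs))))
    colnames(cppi) <- paste0("cppi_", pair_names)
    list(activity = act, spontaneous = spont, cppi = cppi,
         y = cohort$subjects$ssrt_mu, age = cohort$subjects$age_years)
  })
}
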
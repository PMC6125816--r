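#' Simulate head-motion realignment parameters
#'
#' Head motion is modeled as a six-parameter random walk (three translations
#' in mm, three rotations in radians) whose step scale grows with a severity
#' knob and, optionally, with age -- mirroring the positive motion-age
#' correlation seen in adult life-span cohorts.
#'
#' @param n_volumes Number of volumes (>= 2).
#' @param severity Baseline random-walk step SD, mm per volume for
#'   translations (rotations use `severity / 50` radians). Zero gives an
#'   all-zero trace.
#' @param age Age in years; enters through `age_slope`.
#' @param age_slope Additional step SD per year of age above 18 (default
#'   0.0015 mm/yr, giving a cohort motion-age correlation around 0.5 at the
#'   default severity).
#' @param seed Integer seed.
#' @return Tibble with columns `volume`, `trans_x`, `trans_y`, `trans_z`
#'   (mm), `rot_x`, `rot_y`, `rot_z` (radians).
#' @export
simulate_motion <- function(n_volumes, severity = 0.03, age = 50,
                            age_slope = 0.0015, seed = 1) {
  if (n_volumes < 2) abort("n_volumes must be >= 2", class = "stopnet_config_error")
  step_t <- severity + age_slope * max(age - 18, 0)
  step_t <- max(step_t, 0)
  step_r <- step_t / 50
  with_seed(seed, {
    steps_t <- matrix(rnorm(3 * n_volumes, 0, step_t), ncol = 3)
    steps_r <- matrix(rnorm(3 * n_volumes, 0, step_r), ncol = 3)
    if (step_t == 0) {
      steps_t[] <- 0
      steps_r[] <- 0
    }
    pars <- apply(cbind(steps_t, steps_r), 2, cumsum)
    pars <- sweep(pars, 2, pars[1, ]) # first volume is the reference
    colnames(pars) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
    out <- as_tibble(pars)
    out$volume <- seq_len(n_volumes)
    out[, c("volume", "trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")]
  })
}

rotation_matrix <- function(rx, ry, rz) {
  Rx <- matrix(c(1, 0, 0, 0, cos(rx), sin(rx), 0, -sin(rx), cos(rx)), 3, 3)
  Ry <- matrix(c(cos(ry), 0, -sin(ry), 0, 1, 0, sin(ry), 0, cos(ry)), 3, 3)
  Rz <- matrix(c(cos(rz), sin(rz), 0, -sin(rz), cos(rz), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Root-mean-square volume-to-volume displacement
#'
#' For each consecutive pair of volumes, forms the rigid-body difference
#' transform T2 T1^-1 and evaluates the RMS displacement of points in a
#' solid sphere of radius `radius_mm`:
#' sqrt(radius^2/5 * tr(A'A) + t't), with A the rotation part minus the
#' identity and t the translation part of the difference transform.
#'
#' @param motion Realignment-parameter table as from [simulate_motion()]
#'   (columns trans_x..rot_z, in mm and radians).
#' @param radius_mm Sphere radius approximating the head (default 80 mm).
#' @return Tibble with `volume_pair`, `displacement_mm`; attribute
#'   `mean_displacement_mm` carries the subject summary.
#' @export
rms_displacement <- function(motion, radius_mm = 80) {
  cols <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  if (!all(cols %in% names(motion))) {
    abort("motion table must have columns trans_x..rot_z", class = "stopnet_input_error")
  }
  m <- as.matrix(motion[, cols])
  if (nrow(m) < 2) abort("need >= 2 volumes", class = "stopnet_input_error")
  disp <- vapply(seq_len(nrow(m) - 1), function(i) {
    R1 <- rotation_matrix(m[i, 4], m[i, 5], m[i, 6])
    R2 <- rotation_matrix(m[i + 1, 4], m[i + 1, 5], m[i + 1, 6])
    t1 <- m[i, 1:3]
    t2 <- m[i + 1, 1:3]
    # difference transform mapping volume i coordinates to volume i+1
    A <- R2 %*% t(R1) - diag(3)
    tt <- t2 - R2 %*% t(R1) %*% t1
    sqrt(radius_mm^2 / 5 * sum(A * A) + sum(tt^2))
  }, numeric(1))
  out <- tibble(volume_pair = seq_along(disp), displacement_mm = disp)
  attr(out, "mean_displacement_mm") <- mean(disp)
  out
}

#' Mean RMS displacement of a realignment table
#' @inheritParams rms_displacement
#' @return Scalar mean volume-to-volume displacement in mm.
#' @export
mean_rms_displacement <- function(motion, radius_mm = 80) {
  attr(rms_displacement(motion, radius_mm), "mean_displacement_mm")
}
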
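#' Ground-truth specification for the BOLD forward model
#'
#' Describes the latent structure a synthetic cohort carries: smooth
#' Gaussian-blob spatial components on a small 3-D voxel lattice,
#' condition-evoked response heights per component, context-independent
#' coupling between component fluctuations, coupling differences expressed
#' during successful versus unsuccessful stop epochs, noise levels, and
#' the linear age slopes of behavior and coupling modulation.
#'
#' @param n_components Number of latent spatial components (default 5).
#' @param grid 3-vector of lattice dimensions (default `c(12, 12, 10)`).
#' @param evoked_amplitudes Matrix `[components x 4]` with columns
#'   `Go`, `NoGo`, `SuccStop`, `UnsuccStop`; `NULL` uses a default pattern in
#'   which two components respond more to unsuccessful and two more to
#'   successful stops.
#' @param base_coupling Symmetric zero-diagonal matrix of context-independent
#'   correlations between component fluctuations.
#' @param coupling_modulation Symmetric zero-diagonal matrix of coupling
#'   differences (SuccStop minus UnsuccStop epochs).
#' @param noise_sd SD of the stochastic (coupled) part of each component
#'   time course.
#' @param ar_coef AR(1) coefficient of the stochastic fluctuations (default
#'   0.55 at the 2-s TR), giving the low-frequency-dominated spectrum of
#'   spontaneous BOLD; the innovation scaling keeps the stationary variance
#'   and lag-zero cross-component correlations at their configured values.
#' @param voxel_noise_sd SD of i.i.d. voxel-level noise.
#' @param motion_artifact_gain Gain on motion-derived voxel nuisance.
#' @param epoch_window_s Length of the epoch (seconds) starting at each
#'   Stop-Signal onset during which coupling modulation is expressed
#'   (default 4).
#' @param age_slopes Named list of linear age coefficients:
#'   `go_rt_ms_per_year`, `ssrt_ms_per_year`, `coupling_modulation_per_year`
#'   (relative change of the modulation scale), `moderation_per_year`
#'   (age scaling of the SSRT-modulation link), `motion_severity_per_year`.
#' @param seed Seed for the random blob placement.
#' @return A list of class `ground_truth_spec` with element `spatial_maps`
#'   (`[components x voxels]`, unit L2 norm per row) among the above.
#' @export
ground_truth_spec <- function(n_components = 5, grid = c(12, 12, 10),
                              evoked_amplitudes = NULL,
                              base_coupling = NULL,
                              coupling_modulation = NULL,
                              noise_sd = 1, ar_coef = 0.55,
                              voxel_noise_sd = 1,
                              motion_artifact_gain = 0.5,
                              epoch_window_s = 4,
                              age_slopes = list(), seed = 99) {
  k <- n_components
  stopifnot(k >= 1, length(grid) == 3, all(grid >= 2))

  if (is.null(evoked_amplitudes)) {
    base <- matrix(0, k, 4, dimnames = list(NULL, c("Go", "NoGo", "SuccStop", "UnsuccStop")))
    pattern <- rbind(
      c(1.0, 0.2, 0.6, 1.0),  # motor-like: responds when a response is made
      c(0.3, 0.8, 0.7, 1.2),  # pre-SMA-like: higher on unsuccessful stops
      c(0.2, 0.6, 1.2, 0.7),  # rIFG-like: higher on successful stops
      c(0.4, 0.4, 1.0, 0.6),  # parietal-like
      c(0.8, 0.8, 0.8, 0.8)   # visual-like: condition-indifferent
    )
    for (i in seq_len(k)) base[i, ] <- pattern[((i - 1) %% 5) + 1, ]
    evoked_amplitudes <- base
  }
  evoked_amplitudes <- as.matrix(evoked_amplitudes)
  stopifnot(nrow(evoked_amplitudes) == k, ncol(evoked_amplitudes) == 4)
  colnames(evoked_amplitudes) <- c("Go", "NoGo", "SuccStop", "UnsuccStop")

  sym_default <- function(entries) {
    m <- matrix(0, k, k)
    for (e in entries) if (max(e[1:2]) <= k) {
      m[e[1], e[2]] <- m[e[2], e[1]] <- e[3]
    }
    m
  }
  if (is.null(base_coupling)) {
    base_coupling <- sym_default(list(c(1, 2, 0.4), c(2, 3, 0.3), c(3, 4, 0.25), c(1, 5, 0.15)))
  }
  if (is.null(coupling_modulation)) {
    coupling_modulation <- sym_default(list(c(1, 2, 0.3), c(2, 3, 0.25)))
  }
  base_coupling <- as.matrix(base_coupling)
  coupling_modulation <- as.matrix(coupling_modulation)
  check_sym <- function(m, nm) {
    if (!isTRUE(all.equal(m, t(m))) || any(diag(m) != 0)) {
      abort(paste(nm, "must be symmetric with zero diagonal"),
            class = "stopnet_config_error")
    }
  }
  check_sym(base_coupling, "base_coupling")
  check_sym(coupling_modulation, "coupling_modulation")
  for (s in c(-1, 0, 1)) {
    R <- diag(k) + base_coupling + s * coupling_modulation / 2
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-8) {
      abort("coupling matrices do not yield positive-definite correlation structure",
            class = "stopnet_config_error")
    }
  }

  slopes <- utils::modifyList(list(
    go_rt_ms_per_year = 1.0,
    ssrt_ms_per_year = 0.8,
    coupling_modulation_per_year = -0.008,
    moderation_per_year = 0,
    motion_severity_per_year = 0.0015
  ), age_slopes)

  maps <- gaussian_blob_maps(k, grid, seed = seed)

  structure(list(
    n_components = k, grid = grid, spatial_maps = maps,
    evoked_amplitudes = evoked_amplitudes,
    base_coupling = base_coupling,
    coupling_modulation = coupling_modulation,
    noise_sd = noise_sd, ar_coef = ar_coef, voxel_noise_sd = voxel_noise_sd,
    motion_artifact_gain = motion_artifact_gain,
    epoch_window_s = epoch_window_s,
    age_slopes = slopes, seed = seed
  ), class = "ground_truth_spec")
}

# Smooth, spatially separated Gaussian blobs with unit L2 norm per component.
gaussian_blob_maps <- function(k, grid, fwhm_vox = 2.5, seed = 99) {
  coords <- expand.grid(x = seq_len(grid[1]), y = seq_len(grid[2]), z = seq_len(grid[3]))
  sigma <- fwhm_vox / 2.355
  with_seed(seed, {
    centers <- matrix(NA_real_, k, 3)
    # rejection placement keeps blob centers apart
    min_d <- 0.45 * min(grid)
    for (i in seq_len(k)) {
      for (try in 1:200) {
        c_i <- c(runif(1, 2, grid[1] - 1), runif(1, 2, grid[2] - 1), runif(1, 2, grid[3] - 1))
        if (i == 1 || min(sqrt(rowSums(sweep(centers[seq_len(i - 1), , drop = FALSE], 2, c_i)^2))) > min_d) break
      }
      centers[i, ] <- c_i
    }
    maps <- t(apply(centers, 1, function(cc) {
      d2 <- (coords$x - cc[1])^2 + (coords$y - cc[2])^2 + (coords$z - cc[3])^2
      exp(-d2 / (2 * sigma^2))
    }))
    maps / sqrt(rowSums(maps^2))
  })
}
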
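test_that("spontaneous connectivity is the MLR coefficient with task removed", {
  fx <- cppi_fixture(seed = 40, mod = 0, base = 0)
  X <- fx$dm$X
  n <- nrow(X)
  set.seed(41)
  # identical series: coefficient 1
  tc <- rnorm(n)
  expect_equal(as.numeric(spontaneous_connectivity(tc, tc, fx$dm)), 1, tolerance = 1e-10)
  # correlation only through a shared task regressor already in X -> ~0
  noise_i <- rnorm(n); noise_j <- rnorm(n)
  amp <- 2 / sd(X[, "SuccStop"])
  tc_i <- amp * X[, "SuccStop"] + noise_i
  tc_j <- amp * X[, "SuccStop"] + noise_j
  raw_r <- cor(tc_i, tc_j)
  coefd <- as.numeric(spontaneous_connectivity(tc_i, tc_j, fx$dm))
  expect_gt(raw_r, 0.2)
  expect_lt(abs(coefd), 0.08)
  # independent noise: coefficient within the null band
  expect_lt(abs(as.numeric(spontaneous_connectivity(noise_i, noise_j, fx$dm))),
            3 / sqrt(n))
})

test_that("spontaneous estimates ignore evoked-amplitude changes when task is modeled", {
  vals <- sapply(c(0.5, 1, 2), function(gain) {
    bc <- matrix(0, 5, 5); bc[1, 2] <- bc[2, 1] <- 0.4
    tr <- ground_truth_spec(base_coupling = bc,
                            evoked_amplitudes = gain * ground_truth_spec()$evoked_amplitudes)
    d <- generate_task_design(seed = 42)
    b <- simulate_race_behavior(d, seed = 43)
    nv <- attr(d, "n_volumes_per_session")
    dm <- build_design_matrix(b)
    tcs <- stopnet:::simulate_component_tcs(b[b$session == 1, ], tr, nv, 2, seed = 44)$tcs
    as.numeric(spontaneous_connectivity(tcs[, 1], tcs[, 2], dm[[1]]))
  })
  expect_lt(max(vals) - min(vals), 0.1)
  expect_true(all(abs(vals - 0.4) < 0.12))
})

test_that("psych contrast coding is centered, reversible, and duration-aware", {
  fx <- cppi_fixture(seed = 45, mod = 0, n_stop = 60)
  b <- fx$behavior
  s_hrf <- build_psych_contrast(b, fx$n_vol, 2, hrf = TRUE)
  expect_equal(mean(s_hrf), 0, tolerance = 1e-12)
  s_rev <- build_psych_contrast(b, fx$n_vol, 2, contrast = c("UnsuccStop", "SuccStop"),
                                hrf = TRUE)
  expect_equal(s_rev, -s_hrf, tolerance = 1e-12)
  s_raw <- build_psych_contrast(b, fx$n_vol, 2, hrf = FALSE)
  expect_equal(sort(unique(round(s_raw - min(s_raw)))), 0:2) # stick coding
  b_nogo <- b[b$category != "SuccStop", ]
  expect_error(build_psych_contrast(b_nogo, fx$n_vol, 2), class = "stopnet_input_error")
})

test_that("cPPI is symmetric and invariant to rescaling and nuisance additions", {
  fx <- cppi_fixture(seed = 46, mod = 0.4, n_stop = 100)
  x <- fx$tcs[, 1]; y <- fx$tcs[, 2]
  r_xy <- cppi(x, y, fx$psych, fx$dm)
  r_yx <- cppi(y, x, fx$psych, fx$dm)
  expect_equal(r_xy, r_yx, tolerance = 1e-12)
  # linear rescaling of either series
  expect_equal(cppi(3 * x, y, fx$psych, fx$dm), r_xy, tolerance = 1e-8)
  expect_equal(cppi(x, -2 * y, fx$psych, fx$dm), -r_xy, tolerance = 1e-8)
  # adding a combination of nuisance columns to an interaction term
  # changes nothing once it is residualized against Z
  Z <- cbind(x, y, fx$dm$X)
  I_i <- x * fx$psych
  I_j <- y * fx$psych
  z_add <- Z %*% rnorm(ncol(Z), 0, 0.5)
  r_plain <- cor(stopnet:::residualize(I_i, Z), stopnet:::residualize(I_j, Z))
  r_shift <- cor(stopnet:::residualize(I_i + z_add, Z), stopnet:::residualize(I_j, Z))
  expect_equal(r_shift, r_plain, tolerance = 1e-8)
})

test_that("cPPI detects injected modulation and stays null under constant coupling", {
  alt_p <- sapply(1:25, function(i) {
    fx <- cppi_fixture(seed = 400 + i, mod = 0.5)
    cppi_inference(fx$tcs[, 1], fx$tcs[, 2], fx$psych, fx$dm)$p
  })
  expect_gte(mean(alt_p < 0.05), 0.8)
  nul_p <- sapply(1:60, function(i) {
    fx <- cppi_fixture(seed = 900 + i, mod = 0, base = 0.6)
    cppi_inference(fx$tcs[, 1], fx$tcs[, 2], fx$psych, fx$dm)$p
  })
  expect_lt(mean(nul_p < 0.05), 0.17) # ~alpha over 60 null series
})

test_that("the interaction-term correlation inherits static coupling (why it is not default)", {
  fx <- cppi_fixture(seed = 47, mod = 0, base = 0.6)
  r_int <- cppi(fx$tcs[, 1], fx$tcs[, 2], fx$psych, fx$dm, method = "interaction")
  r_reg <- cppi(fx$tcs[, 1], fx$tcs[, 2], fx$psych, fx$dm)
  expect_gt(r_int, 0.4)      # tracks the spontaneous correlation under the null
  expect_lt(abs(r_reg), 0.1) # default construction does not
})

test_that("spontaneous tracks base coupling and cPPI tracks modulation, not vice versa", {
  # distinct coupling values on every pair so rank correlations are
  # informative (tied true values would cap the attainable Spearman rho)
  pairs0 <- which(upper.tri(matrix(0, 5, 5)), arr.ind = TRUE)
  bc <- matrix(0, 5, 5)
  bv <- seq(0.02, 0.24, length.out = 10)
  cm <- matrix(0, 5, 5)
  mv <- seq(0.02, 0.20, length.out = 10)[c(4, 9, 1, 7, 3, 10, 6, 2, 8, 5)]
  for (i in 1:10) {
    bc[pairs0[i, 1], pairs0[i, 2]] <- bc[pairs0[i, 2], pairs0[i, 1]] <- bv[i]
    cm[pairs0[i, 1], pairs0[i, 2]] <- cm[pairs0[i, 2], pairs0[i, 1]] <- mv[i]
  }
  tr <- ground_truth_spec(base_coupling = bc, coupling_modulation = cm)
  pairs <- which(upper.tri(bc), arr.ind = TRUE)
  est <- replicate(6, {
    seed <- sample.int(1e6, 1)
    d <- generate_task_design(n_go = 1050, n_stop = 300, n_nogo = 150,
                              n_sessions = 1, seed = seed)
    b <- simulate_race_behavior(d, seed = seed + 1)
    nv <- attr(d, "n_volumes_per_session")
    dm <- build_design_matrix(b)
    tcs <- stopnet:::simulate_component_tcs(b, tr, nv, 2, seed = seed + 2)$tcs
    psych <- build_psych_contrast(b, nv, 2, hrf = FALSE, duration_s = 4)
    t(apply(pairs, 1, function(ij) {
      c(spont = as.numeric(spontaneous_connectivity(tcs[, ij[1]], tcs[, ij[2]], dm[[1]])),
        cppi = cppi(tcs[, ij[1]], tcs[, ij[2]], psych, dm[[1]]))
    }))
  })
  est <- apply(est, c(1, 2), mean)
  base_v <- bc[pairs]; mod_v <- cm[pairs]
  expect_gt(cor(est[, "spont"], base_v, method = "spearman"), 0.8)
  expect_gt(cor(est[, "cppi"], mod_v, method = "spearman"), 0.8)
  # cross-insensitivity
  expect_gt(cor.test(est[, "cppi"], base_v, method = "spearman", exact = FALSE)$p.value, 0.05)
  expect_gt(cor.test(est[, "spont"], mod_v, method = "spearman", exact = FALSE)$p.value, 0.05)
})

test_that("group and age tests on connectivity use Fisher z and both FDR levels", {
  set.seed(48)
  n <- 60
  ages <- runif(n, 18, 88)
  conn <- dplyr::bind_rows(lapply(1:n, function(i) {
    tibble::tibble(subject_id = sprintf("s%02d", i),
                   comp_i = c(1, 1, 2), comp_j = c(2, 3, 3), kind = "cppi",
                   value = c(0.4 + rnorm(1, 0, 0.1),        # group effect
                             rnorm(1, 0, 0.1),              # null
                             -0.004 * ages[i] + 0.2 + rnorm(1, 0, 0.05))) # age effect
  }))
  ages_tbl <- tibble::tibble(subject_id = sprintf("s%02d", 1:n), age_years = ages)
  out <- connectivity_group_tests(conn, ages_tbl)
  expect_true(out$group$significant[out$group$connection == "1-2"])
  expect_false(out$group$significant[out$group$connection == "1-3"])
  expect_true(out$age$significant[out$age$measure == "2-3"])
})
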
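# ---- MDL order selection -------------------------------------------------

test_that("MDL selects the generative order for strong sources and caps at rank", {
  set.seed(1)
  hits <- sapply(1:20, function(i) {
    S <- matrix(rnorm(5 * 50), 5, 50)
    A <- matrix(rnorm(1500 * 5), 1500, 5)
    X <- A %*% S + matrix(rnorm(1500 * 50, 0, 0.5), 1500, 50)
    as.integer(select_model_order_mdl(X)) == 5
  })
  expect_gte(mean(hits), 0.9)

  # pure white noise -> k <= 1
  ks <- sapply(1:5, function(i) {
    as.integer(select_model_order_mdl(matrix(rnorm(1500 * 40), 1500, 40)))
  })
  expect_true(all(ks <= 1))

  # rank-deficient data: selected order never exceeds the rank
  low <- matrix(rnorm(200 * 3), 200, 3) %*% matrix(rnorm(3 * 30), 3, 30)
  expect_lte(as.integer(select_model_order_mdl(low)), 3)
})

test_that("growing noise power never pushes MDL above the generative order", {
  set.seed(7)
  S <- matrix(rnorm(5 * 50), 5, 50)
  A <- matrix(rnorm(1200 * 5), 1200, 5)
  ks <- sapply(c(0.3, 0.8, 1.5, 3), function(sd) {
    X <- A %*% S + matrix(rnorm(1200 * 50, 0, sd), 1200, 50)
    as.integer(select_model_order_mdl(X))
  })
  expect_true(all(ks <= 5))
  expect_equal(ks[1], 5)
})

# ---- group ICA -----------------------------------------------------------

truth_fix <- decomposition_truth()
data_fix <- decomposition_cohort_data(n_subjects = 4, seed = 2, truth = truth_fix)
ica_fix <- group_ica(data_fix, k = 5, n_runs = 30, seed = 3)

test_that("group ICA recovers well-separated sources with high stability", {
  m <- match_components(truth_fix$spatial_maps, ica_fix$spatial_maps)
  expect_true(all(m$abs_r > 0.95))
  expect_gt(mean(ica_fix$stability_index), 0.9)
  expect_true(all(ica_fix$stability_index >= 0 & ica_fix$stability_index <= 1))
  # z-scored maps and time courses
  expect_equal(unname(rowMeans(ica_fix$spatial_maps)), rep(0, 5), tolerance = 1e-8)
  expect_equal(unname(apply(ica_fix$spatial_maps, 1, sd)), rep(1, 5), tolerance = 1e-8)
  expect_equal(unname(colMeans(ica_fix$group_tcs)), rep(0, 5), tolerance = 1e-8)
})

test_that("the component matcher agrees with exhaustive permutation search", {
  a <- ica_fix$spatial_maps[1:4, ]
  b <- truth_fix$spatial_maps[sample(1:5, 5), ]
  got <- match_components(a, b)
  # brute-force oracle over all 5!/1! injections
  r <- abs(cor(t(a), t(b)))
  perms <- stopnet:::all_permutations(1:5, 4)
  scores <- vapply(perms, function(p) sum(r[cbind(1:4, p)]), numeric(1))
  expect_equal(sum(got$abs_r), max(scores), tolerance = 1e-12)
})

test_that("group ICA is reproducible from the master seed", {
  ica2 <- group_ica(data_fix, k = 5, n_runs = 10, seed = 99)
  ica3 <- group_ica(data_fix, k = 5, n_runs = 10, seed = 99)
  expect_identical(ica2$spatial_maps, ica3$spatial_maps)
  expect_identical(ica2$stability_index, ica3$stability_index)
})

test_that("back-reconstruction is exact in the noise-free case and robust to noise", {
  set.seed(5)
  maps <- t(apply(matrix(rnorm(3 * 200), 3, 200), 1, function(x) as.numeric(scale(x))))
  tcs <- matrix(rnorm(120 * 3), 120, 3)
  Y <- tcs %*% maps
  fake_ica <- structure(list(spatial_maps = maps, order_k = 3), class = "stopnet_ica")
  rec <- backreconstruct_subject_tcs(fake_ica, Y)
  for (i in 1:3) expect_gt(abs(cor(rec[, i], tcs[, i])), 1 - 1e-10)
  # with noise at SNR ~5 recovery stays high
  Yn <- Y + matrix(rnorm(length(Y), 0, sd(Y) / 5), nrow(Y))
  recn <- backreconstruct_subject_tcs(fake_ica, Yn)
  for (i in 1:3) expect_gt(abs(cor(recn[, i], tcs[, i])), 0.9)
  # an orthogonal nuisance map leaves recovered TCs unchanged
  nuis <- rnorm(200)
  proj <- t(maps) %*% solve(tcrossprod(maps)) %*% (maps %*% nuis)
  nuis <- nuis - as.numeric(proj)
  Yo <- Y + matrix(rnorm(120), 120, 1) %*% t(nuis)
  reco <- backreconstruct_subject_tcs(fake_ica, Yo)
  for (i in 1:3) expect_gt(abs(cor(reco[, i], tcs[, i])), 0.999)
})

test_that("downstream statistics are invariant to component order and sign", {
  # responsivity computed from permuted/flipped maps matches after matching
  flip <- diag(c(-1, 1, -1, 1, 1))
  perm <- c(3, 1, 5, 2, 4)
  maps_t <- (flip %*% ica_fix$spatial_maps)[perm, ]
  sub <- data_fix[[1]]
  tc_a <- stopnet:::backreconstruct_subject_tcs_mat(sub, ica_fix$spatial_maps)
  tc_b <- stopnet:::backreconstruct_subject_tcs_mat(sub, maps_t)
  m <- match_components(ica_fix$spatial_maps, maps_t)
  for (i in 1:5) {
    expect_equal(abs(cor(tc_a[, m$comp_a[i]], tc_b[, m$comp_b[i]])), 1,
                 tolerance = 1e-8)
  }
})

# ---- noise classification ------------------------------------------------

test_that("spectral ratio and template overlap classify noise components", {
  tr_s <- 2
  t <- seq_len(400)
  hi <- sin(2 * pi * 0.2 * t * tr_s)          # 0.2 Hz > 0.1 Hz cutoff
  lo <- hrf_regressor(c(20, 100, 300, 500), 400, tr_s)
  maps <- rbind(rnorm(150), rnorm(150))
  fake <- structure(list(group_tcs = cbind(hi, lo), spatial_maps = maps,
                         order_k = 2, labels = rep(NA, 2)),
                    class = "stopnet_ica")
  cls <- classify_noise_components(fake, tr_s = tr_s)
  expect_equal(cls$label, c("noise", "signal"))
  expect_gt(cls$freq_ratio[1], 0.9)
  expect_lt(cls$freq_ratio[2], 0.9)

  # a component matching a CSF-like reference map best is noise
  refs <- rbind(maps[2, ] + rnorm(150, 0, 0.1), rnorm(150))
  cls2 <- classify_noise_components(fake, tr_s = tr_s,
                                    reference_maps = refs,
                                    reference_labels = c("noise", "signal"))
  expect_equal(cls2$label[2], "noise")
})

# ---- split-half validation ----------------------------------------------

test_that("split-half similarity is near one for duplicated halves and null for homogeneous ones", {
  dup <- c(data_fix, data_fix)
  split <- rep(c("a", "b"), each = 4)
  sh <- split_half_similarity(dup, split, k = 5, n_runs = 8, seed = 11)
  expect_true(all(sh$spatial$r > 0.95))
  # Fisher z applied before averaging/tests
  expect_equal(sh$spatial$z, atanh(pmin(sh$spatial$r, 1 - 1e-12)), tolerance = 1e-6)
  # homogeneous synthetic halves: no significant group difference
  p <- sh$tests$p_value[sh$tests$measure == "spatial"]
  expect_true(is.na(p) || p > 0.05)
  expect_true(all(sh$between_icc$r > 0.8))
  expect_true(all(sh$within_icc$r > 0.8))
})
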
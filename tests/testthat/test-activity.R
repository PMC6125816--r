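design_fix <- generate_task_design(seed = 30)
behavior_fix <- simulate_race_behavior(design_fix, seed = 31)
n_vol_fix <- attr(design_fix, "n_volumes_per_session")
dm_fix <- build_design_matrix(behavior_fix)

test_that("design matrices carry event, motion, and drift columns per session", {
  motion <- lapply(1:2, function(s) simulate_motion(n_vol_fix, seed = s))
  dm <- build_design_matrix(behavior_fix, motion = motion)
  expect_length(dm, 2)
  s1 <- dm[[1]]
  cats_present <- intersect(
    c("correctGo", "correctNoGo", "SuccStop", "UnsuccStop", "GoCommission",
      "GoOmission", "NoGoCommission", "EarlySS", "IncorrectSS"),
    unique(behavior_fix$category[behavior_fix$session == 1]))
  n_dct <- floor(2 * n_vol_fix * 2 / 128)
  expect_equal(ncol(s1$X), length(cats_present) + 6 + n_dct + 1)
  expect_equal(nrow(s1$X), n_vol_fix)
  # a single event, noise-free: column equals the sampled unit-peak HRF
  one <- hrf_regressor(10, 50, 2)
  peak <- max(double_gamma_hrf(seq(0, 32, by = 0.1)))
  expect_equal(one, double_gamma_hrf((0:49) * 2 - 10) / peak, tolerance = 0.02)
})

test_that("conditions with zero events are omitted and recorded", {
  b <- behavior_fix
  b$category[b$category == "UnsuccStop"] <- "SuccStop" # all stops successful
  dm <- build_design_matrix(b)
  expect_false("UnsuccStop" %in% dm[[1]]$task_cols)
  expect_true("UnsuccStop" %in% dm[[1]]$omitted_conditions)
})

test_that("component GLM recovers planted betas and responsivity is their contrast", {
  X <- dm_fix[[1]]$X
  tc <- 2 * X[, "SuccStop"] - 1 * X[, "UnsuccStop"] + 0.5
  beta <- component_glm(tc, dm_fix[[1]])
  expect_equal(unname(beta["SuccStop"]), 2, tolerance = 1e-8)
  expect_equal(unname(beta["UnsuccStop"]), -1, tolerance = 1e-8)
  r <- responsivity_index(list(beta))
  expect_equal(as.numeric(r), 3, tolerance = 1e-8)
  # session averaging and contrast reversal
  b2 <- beta; b2["SuccStop"] <- 0; b2["UnsuccStop"] <- 1
  expect_equal(as.numeric(responsivity_index(list(beta, b2))), (3 + (-1)) / 2)
  expect_equal(as.numeric(responsivity_index(list(beta), c("UnsuccStop", "SuccStop"))), -3,
               tolerance = 1e-8)
  # adding a constant moves only the intercept
  beta_c <- component_glm(tc + 7, dm_fix[[1]])
  expect_equal(unname(beta_c["SuccStop"]), 2, tolerance = 1e-8)
  expect_equal(unname(beta_c["intercept"]), unname(beta["intercept"]) + 7, tolerance = 1e-6)
  # collinear design errors with named columns
  Xbad <- cbind(X, dup = X[, "SuccStop"])
  expect_error(component_glm(tc, Xbad), class = "stopnet_collinearity_error")
})

test_that("GLM residuals are orthogonal to the design and noise betas are null", {
  set.seed(8)
  tc <- rnorm(n_vol_fix)
  beta <- component_glm(tc, dm_fix[[1]])
  fitted <- dm_fix[[1]]$X %*% beta
  expect_lt(max(abs(crossprod(dm_fix[[1]]$X, tc - fitted))), 1e-6)
  # responsivity linear in TC amplitude
  tc2 <- 2 * (dm_fix[[1]]$X[, "SuccStop"] - dm_fix[[1]]$X[, "UnsuccStop"]) + rnorm(n_vol_fix, 0, 0.01)
  b1 <- component_glm(tc2, dm_fix[[1]])
  b3 <- component_glm(3 * tc2, dm_fix[[1]])
  expect_equal(3 * as.numeric(responsivity_index(list(b1))),
               as.numeric(responsivity_index(list(b3))), tolerance = 1e-6)
})

test_that("BH-FDR matches the step-up oracle and controls the null FDP", {
  expect_equal(as.logical(fdr_bh(c(0.001, 0.2, 0.9), 0.05)), c(TRUE, FALSE, FALSE))
  expect_equal(as.logical(fdr_bh(rep(1, 5), 0.05)), rep(FALSE, 5))
  expect_equal(as.logical(fdr_bh(rep(0, 5), 0.05)), rep(TRUE, 5))
  set.seed(10)
  for (i in 1:25) {
    p <- runif(20)^c(rep(1, 15), rep(3, 5))
    expect_equal(as.logical(fdr_bh(p, 0.05)), oracle_bh(p, 0.05))
  }
  # null calibration: expected false-discovery proportion <= alpha
  fdp <- replicate(200, {
    p <- runif(12)
    mean(fdr_bh(p, 0.05))
  })
  expect_lte(mean(fdp), 0.05 + 0.02)
})

test_that("group responsivity tests detect injected effects at the stated FDR", {
  set.seed(11)
  n <- 100
  resp <- cbind(effect = rnorm(n, 1.2, 1), matrix(rnorm(n * 5), n, 5))
  out <- group_responsivity_test(resp, alpha = 0.01)
  expect_true(out$significant[1])
  # single component at p = 0.005 is significant at alpha = 0.01
  x <- rnorm(30)
  x <- x - mean(x) + qt(1 - 0.0025, 29) * sd(x) / sqrt(30) # p = 0.005 exactly
  one <- group_responsivity_test(matrix(x, ncol = 1), alpha = 0.01)
  expect_equal(one$p, 0.005, tolerance = 1e-10)
  expect_true(one$significant)
  # null family: false-discovery proportion near alpha
  set.seed(12)
  fdp <- replicate(100, {
    null <- matrix(rnorm(40 * 8), 40, 8)
    mean(group_responsivity_test(null, alpha = 0.05)$significant)
  })
  expect_lt(mean(fdp), 0.08)
})

test_that("robust age regression recovers slopes and resists outliers", {
  set.seed(13)
  n <- 150
  age <- runif(n, 18, 88)
  val <- -0.02 * age + rnorm(n, 0, 0.3)
  clean <- age_effect_robust(val, age)
  expect_lt(clean$estimate, 0)
  expect_lt(clean$p, 0.01)
  # 5% gross outliers: robust estimate stays near the clean fit, OLS does not
  val_out <- val
  idx <- sample(n, 7)
  val_out[idx] <- val_out[idx] + 30
  rob <- age_effect_robust(val_out, age)
  ols <- coef(lm(age ~ val_out))[2]
  err_rob <- abs(rob$estimate - clean$estimate)
  err_ols <- abs(ols - clean$estimate)
  expect_lt(err_rob, err_ols)
  expect_lt(err_rob, 2 * abs(clean$estimate))
  # null slope: rejection near alpha
  set.seed(14)
  rej <- replicate(150, {
    v <- rnorm(60)
    a <- runif(60, 18, 88)
    age_effect_robust(v, a)$p < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.05)
  # constant covariates are dropped with a warning
  expect_warning(
    age_effect_robust(val, age, covariates = data.frame(const = rep(1, n))),
    "constant"
  )
})

test_that("peri-event averages recover the HRF shape and handle edge cases", {
  tr_s <- 2
  onsets <- seq(20, 500, by = 40)
  tc <- hrf_regressor(onsets, 300, tr_s) * 10
  pe <- peri_event_average(tc, onsets, window_s = 16, tr_s = tr_s)
  hrf_shape <- double_gamma_hrf(pe$time_s)
  expect_gt(cor(pe$mean_response, hrf_shape), 0.95)
  # single event: window equals the raw (baselined) segment
  tc2 <- rnorm(100)
  pe2 <- peri_event_average(tc2, 40, window_s = 8, tr_s = 2)
  expect_equal(pe2$mean_response, tc2[21:25] - tc2[21])
  # zero events: empty, warned
  expect_warning(out <- peri_event_average(tc2, numeric(0), 8, 2), "no events")
  expect_equal(nrow(out), 0)
  # truncated window flagged
  expect_warning(peri_event_average(tc2, 196, window_s = 16, tr_s = 2), "truncated")
})
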
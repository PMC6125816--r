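test_that("shrinkage regression reduces to OLS at gamma 0 and stays finite for p > n", {
  set.seed(50)
  X <- matrix(rnorm(60 * 4), 60, 4)
  y <- rnorm(60)
  f0 <- shrinkage_mlr_fit(X, y, gamma = 0)
  ols <- coef(lm(y ~ X))
  expect_equal(unname(f0$weights), unname(ols[-1]), tolerance = 1e-10)
  expect_equal(f0$intercept, unname(ols[1]), tolerance = 1e-10)
  # p = 200 >> n = 30: finite weights, gamma in (0, 1]
  Xp <- matrix(rnorm(30 * 200), 30, 200)
  fp <- shrinkage_mlr_fit(Xp, rnorm(30))
  expect_true(all(is.finite(fp$weights)))
  expect_gt(fp$gamma, 0)
  expect_error(shrinkage_mlr_fit(X, rep(1, 60)), class = "stopnet_input_error")
})

test_that("the analytic intensity matches a direct-formula oracle and recovery is accurate", {
  set.seed(51)
  R <- 0.3 + 0.7 * diag(5)
  X <- matrix(rnorm(1000 * 5), 1000, 5) %*% chol(R)
  w <- c(2, -1, 0.5, 1, -2)
  y <- as.numeric(X %*% w + rnorm(1000, 0, 0.1))
  f <- shrinkage_mlr_fit(X, y)
  # oracle: direct loops over observations
  Xc <- scale(X, scale = FALSE)
  n <- nrow(Xc); S <- crossprod(Xc) / n; nu <- mean(diag(S))
  d2 <- sum((S - diag(nu, 5))^2)
  b2 <- 0
  for (t in seq_len(n)) b2 <- b2 + sum((tcrossprod(Xc[t, ]) - S)^2)
  gamma_oracle <- min(b2 / n^2, d2) / d2
  expect_equal(f$gamma, gamma_oracle, tolerance = 1e-10)
  # n >> p recovery within 5% in vector norm
  expect_lt(sqrt(sum((f$weights - w)^2)) / sqrt(sum(w^2)), 0.05)
})

test_that("cross-validated scores recover linear signal and stay null without it", {
  set.seed(52)
  X <- matrix(rnorm(100 * 5), 100, 5)
  w <- c(2, -1, 0.5, 1, -2)
  y <- as.numeric(X %*% w + rnorm(100, 0, 0.3))
  pr <- cv_predict_scores(X, y, k = 10, seed = 53)
  expect_gt(pr$observed_r, 0.95)
  expect_equal(length(pr$subject_scores), 100)
  # independent response: r near zero over seeds
  rs <- sapply(1:10, function(i) {
    cv_predict_scores(X, rnorm(100), k = 10, seed = 60 + i)$observed_r
  })
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("held-out scores are untouched by perturbations of held-out responses", {
  set.seed(54)
  X <- matrix(rnorm(60 * 4), 60, 4)
  y <- rnorm(60)
  covs <- data.frame(c1 = rnorm(60), c2 = rnorm(60))
  pr <- cv_predict_scores(X, y, covariates = covs, k = 5, seed = 55)
  f <- pr$fold
  y2 <- y
  y2[f == 3] <- y2[f == 3] + 100 # perturb only fold 3's responses
  pr2 <- cv_predict_scores(X, y2, covariates = covs, k = 5, seed = 55)
  expect_identical(pr$subject_scores[f == 3], pr2$subject_scores[f == 3])
})

test_that("permutation p attains its lower bound for strong signal and ignores column order", {
  set.seed(56)
  X <- matrix(rnorm(50 * 3), 50, 3)
  y <- as.numeric(X %*% c(3, -2, 1) + rnorm(50, 0, 0.1))
  pp <- permutation_pvalue(X, y, n_perm = 99, k = 5, seed = 57)
  expect_equal(pp$p, 1 / 100)
  pp2 <- permutation_pvalue(X[, c(3, 1, 2)], y, n_perm = 99, k = 5, seed = 57)
  expect_equal(pp$p, pp2$p)
  expect_equal(pp$observed_r, pp2$observed_r, tolerance = 1e-10)
  expect_error(permutation_pvalue(X, y, n_perm = 10), class = "stopnet_input_error")
})

test_that("repartition distributions behave like means of the CV statistic", {
  set.seed(58)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- as.numeric(X %*% c(1, 1, -1) + rnorm(40, 0, 1))
  d1 <- repartition_distribution(X, y, n_repart = 40, k = 5, seed = 59)
  d1b <- repartition_distribution(X, y, n_repart = 40, k = 5, seed = 59)
  expect_identical(d1, d1b)
  r_single <- cv_predict_scores(X, y, k = 5, seed = 60)$observed_r
  expect_lt(abs(mean(d1) - r_single), 3 * sd(d1))
  # SD shrinks with n (two-n check)
  set.seed(61)
  Xb <- matrix(rnorm(160 * 3), 160, 3)
  yb <- as.numeric(Xb %*% c(1, 1, -1) + rnorm(160, 0, 1))
  d2 <- repartition_distribution(Xb, yb, n_repart = 40, k = 5, seed = 62)
  expect_lt(sd(d2), sd(d1))
})

test_that("model comparison is antisymmetric and uniform under identical models", {
  set.seed(63)
  nullp <- cbind(rnorm(200, 0, 0.05), rnorm(200, 0, 0.05))
  a <- rnorm(50, 0.3, 0.02); b <- rnorm(50, 0.1, 0.02)
  c1 <- compare_models(a, b, nullp)
  c2 <- compare_models(b, a, nullp[, 2:1])
  expect_equal(c1$mean_diff, -c2$mean_diff)
  expect_lt(c1$p, 0.05)
  # identical models: difference 0, p ~ 1/2 territory
  c3 <- compare_models(a, a, cbind(nullp[, 1], nullp[, 1]))
  expect_equal(c3$mean_diff, 0)
  expect_error(compare_models(a, b[1:10], nullp), class = "stopnet_input_error")
})

test_that("structure coefficients rank generative drivers first", {
  set.seed(64)
  n <- 120
  driver <- rnorm(n)
  X <- cbind(d1 = driver + rnorm(n, 0, 0.2),
             d2 = -driver + rnorm(n, 0, 0.2),
             noise1 = rnorm(n), noise2 = rnorm(n))
  y <- driver * 10 + rnorm(n)
  pr <- cv_predict_scores(X, y, k = 10, seed = 65)
  sc <- structure_coefficients(X, pr)
  expect_setequal(sc$feature[order(-abs(sc$r))][1:2], c("d1", "d2"))
  expect_true(all(sc$significant[1:2]))
  # feature equal to the scores correlates 1; zero-variance flagged
  sc2 <- structure_coefficients(cbind(s = pr$subject_scores, z = rep(1, n)),
                                pr$subject_scores)
  expect_equal(sc2$r[1], 1, tolerance = 1e-12)
  expect_true(sc2$flagged[2])
})

test_that("independence check distinguishes shared from independent drivers", {
  set.seed(66)
  s <- rnorm(80)
  ind <- independence_check(s, rnorm(80))
  expect_gt(ind$p, 0.01)
  shared <- independence_check(s, s + rnorm(80, 0, 0.5))
  expect_lt(shared$p, 1e-5)
  expect_equal(independence_check(s, s)$r, 1, tolerance = 1e-12)
})

test_that("moderation analysis detects interactions only when present", {
  set.seed(67)
  n <- 120
  scores <- rnorm(n)
  age <- runif(n, 18, 88)
  # no interaction injected
  y0 <- 2 * scores + rnorm(n)
  m0 <- moderation_analysis(scores, age, y0)$coefficients
  expect_lt(m0$p[m0$term == "scores"], 0.001)
  rej <- replicate(100, {
    yy <- 2 * scores + rnorm(n)
    m <- moderation_analysis(scores, age, yy)$coefficients
    m$p[m$term == "scores_x_age"] < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.06)
  # interaction injected: power at n = 120
  hits <- replicate(60, {
    sc <- rnorm(n)
    yy <- 2 * sc + 0.08 * sc * (age - mean(age)) + rnorm(n)
    m <- moderation_analysis(sc, age, yy)$coefficients
    m$p[m$term == "scores_x_age"] < 0.05
  })
  expect_gte(mean(hits), 0.8)
  # all-zero response: nothing significant beyond alpha
  m_zero <- moderation_analysis(scores, age, rnorm(n) * 0 + 1e-9 * rnorm(n))$coefficients
  expect_true(mean(m_zero$p < 0.05) <= 0.34)
  expect_error(moderation_analysis(scores, age, y0,
                                   covariates = data.frame(dup = scores - mean(scores))),
               class = "stopnet_collinearity_error")
})
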
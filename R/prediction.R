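# Internal fast engine: residualize covariates (training-fold parameters
# only), fit shrinkage regression on each training set, score the held-out
# fold. Returns held-out scores and the covariate-residualized response.
cv_scores_engine <- function(X, y, C = NULL, folds, gamma = NULL) {
  n <- length(y)
  scores <- numeric(n)
  y_res <- y
  gammas <- numeric(max(folds))
  weights <- vector("list", max(folds))
  for (f in sort(unique(folds))) {
    te <- which(folds == f)
    trn <- which(folds != f)
    if (length(te) < 2) abort("fold smaller than 2", class = "stopnet_input_error")
    Xtr <- X[trn, , drop = FALSE]
    Xte <- X[te, , drop = FALSE]
    ytr <- y[trn]
    yte <- y[te]
    if (!is.null(C)) {
      Ctr <- cbind(1, C[trn, , drop = FALSE])
      Cte <- cbind(1, C[te, , drop = FALSE])
      bc <- qr.coef(qr(Ctr), cbind(ytr, Xtr))
      bc[!is.finite(bc)] <- 0
      ytr <- ytr - as.numeric(Ctr %*% bc[, 1])
      yte <- yte - as.numeric(Cte %*% bc[, 1])
      Xtr <- Xtr - Ctr %*% bc[, -1, drop = FALSE]
      Xte <- Xte - Cte %*% bc[, -1, drop = FALSE]
    }
    fit <- shrinkage_mlr_fit(Xtr, ytr, gamma = gamma)
    scores[te] <- as.numeric(Xte %*% fit$weights + fit$intercept)
    y_res[te] <- yte
    gammas[f] <- fit$gamma
    weights[[f]] <- fit$weights
  }
  list(scores = scores, y_res = y_res, gamma = gammas, weights = weights)
}

make_folds <- function(n, k) sample(rep(seq_len(k), length.out = n))

#' Cross-validated subject scores from shrinkage regression
#'
#' Three-stage procedure: (1) fit the shrinkage-regularized regression on
#' each training set of a k-fold partition, (2) apply the training weights
#' to the held-out fold to obtain subject scores (predicted SSRT), (3)
#' correlate assembled held-out scores with the observed response.
#' Covariates of no interest are residualized out of the response and the
#' features using training-fold parameters only.
#'
#' @param features Matrix or data frame `[subjects x features]`.
#' @param y Response (e.g. SSRT per subject).
#' @param covariates Optional data frame of covariates of no interest.
#' @param k Number of folds (default 10).
#' @param gamma Optional fixed shrinkage intensity (default analytic).
#' @param seed Seed for the fold assignment.
#' @return Object of class `stopnet_prediction`: `subject_scores`,
#'   `observed_r`, `y_used`, `fold`, `gamma` per fold, `weights` per fold.
#' @export
cv_predict_scores <- function(features, y, covariates = NULL, k = 10,
                              gamma = NULL, seed = 1) {
  X <- as.matrix(features)
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (n < 2 * k) abort("need n >= 2k subjects", class = "stopnet_input_error")
  C <- if (!is.null(covariates)) covariate_matrix(covariates) else NULL
  folds <- with_seed(seed, make_folds(n, k))
  eng <- cv_scores_engine(X, y, C, folds, gamma)
  structure(list(
    subject_scores = eng$scores,
    y_used = eng$y_res,
    observed_r = cor(eng$scores, eng$y_res),
    fold = folds, gamma = eng$gamma, weights = eng$weights,
    k = k, n = n, seed = seed
  ), class = "stopnet_prediction")
}

covariate_matrix <- function(covariates) {
  C <- stats::model.matrix(~ . - 1, data = as.data.frame(covariates))
  C[, apply(C, 2, sd) > 0, drop = FALSE]
}

#' Permutation p-value for the cross-validated prediction
#'
#' Permutes the response (covariate rows are permuted jointly with it),
#' reruns the full three-stage cross-validation per permutation with a
#' freshly drawn fold partition, and reports
#' p = (1 + #\{r_perm >= r_obs\}) / (n_perm + 1).
#'
#' @inheritParams cv_predict_scores
#' @param n_perm Number of permutations (>= 99).
#' @param redraw_folds Draw a new partition per permutation (default
#'   `TRUE`).
#' @return List: `p`, `observed_r`, `null_r` (vector of permuted r values).
#' @export
permutation_pvalue <- function(features, y, covariates = NULL, n_perm = 1000,
                               k = 10, gamma = NULL, seed = 1,
                               redraw_folds = TRUE) {
  if (n_perm < 99) abort("n_perm must be >= 99", class = "stopnet_input_error")
  X <- as.matrix(features)
  n <- length(y)
  C <- if (!is.null(covariates)) covariate_matrix(covariates) else NULL
  seeds <- derive_seeds(seed, 2)
  folds0 <- with_seed(seeds[1], make_folds(n, k))
  r_obs <- cor_from_engine(X, y, C, folds0, gamma)
  null_r <- with_seed(seeds[2], {
    vapply(seq_len(n_perm), function(b) {
      perm <- sample(n)
      folds <- if (redraw_folds) make_folds(n, k) else folds0
      cor_from_engine(X, y[perm], if (is.null(C)) NULL else C[perm, , drop = FALSE],
                      folds, gamma)
    }, numeric(1))
  })
  list(p = (1 + sum(null_r >= r_obs)) / (n_perm + 1),
       observed_r = r_obs, null_r = null_r)
}

cor_from_engine <- function(X, y, C, folds, gamma = NULL) {
  eng <- cv_scores_engine(X, y, C, folds, gamma)
  cor(eng$scores, eng$y_res)
}

#' Repartition distribution of cross-validated r values
#'
#' Repeats the k-fold cross-validation with independent random fold
#' partitions and returns the distribution of observed-vs-predicted
#' correlations, used to stabilize model evidence and compare models.
#'
#' @inheritParams cv_predict_scores
#' @param n_repart Number of repartitions (default 1000).
#' @return Numeric vector of r values (length `n_repart`).
#' @export
repartition_distribution <- function(features, y, covariates = NULL,
                                     n_repart = 1000, k = 10, gamma = NULL,
                                     seed = 1) {
  X <- as.matrix(features)
  n <- length(y)
  C <- if (!is.null(covariates)) covariate_matrix(covariates) else NULL
  with_seed(seed, {
    vapply(seq_len(n_repart), function(b) {
      cor_from_engine(X, y, C, make_folds(n, k), gamma)
    }, numeric(1))
  })
}

#' Compare two models by mean repartition evidence against a permuted null
#'
#' The statistic is mean(r_A) - mean(r_B) over repartition distributions
#' obtained from the same response; its null distribution comes from pairs
#' of mean r values computed on jointly permuted responses. The p-value is
#' the one-sided exceedance P(null_diff >= observed_diff), i.e. a test of
#' "A predicts better than B"; the null distribution absorbs the
#' complexity difference between the models (a more complex model has a
#' more negative cross-validated r under permuted responses). Swapping A
#' and B negates the statistic and tests the opposite direction.
#'
#' @param r_dist_a,r_dist_b Repartition r distributions for models A and B.
#' @param null_pairs Two-column matrix of (mean r_A, mean r_B) under
#'   permuted responses.
#' @return Tibble with `mean_diff`, `p`.
#' @export
compare_models <- function(r_dist_a, r_dist_b, null_pairs) {
  null_pairs <- as.matrix(null_pairs)
  if (ncol(null_pairs) != 2) abort("null_pairs needs two columns", class = "stopnet_input_error")
  if (length(r_dist_a) != length(r_dist_b)) {
    abort("repartition distributions must have equal length", class = "stopnet_input_error")
  }
  obs <- mean(r_dist_a) - mean(r_dist_b)
  null_diff <- null_pairs[, 1] - null_pairs[, 2]
  p <- (1 + sum(null_diff >= obs)) / (length(null_diff) + 1)
  tibble(mean_diff = obs, p = p)
}

#' Repartition comparison of feature sets with a shared permutation null
#'
#' Convenience wrapper computing, for each feature set, its repartition
#' distribution on the observed response and the paired null mean-r values
#' under joint permutations of the response, then all pairwise
#' [compare_models()] contrasts.
#'
#' @param feature_sets Named list of feature matrices (same subjects).
#' @inheritParams cv_predict_scores
#' @param n_repart Repartitions for the observed distributions.
#' @param n_perm Permutations for the null.
#' @param n_repart_null Repartitions per permutation (default 20).
#' @return List: `r_dist` (named list), `mean_r` tibble, `comparisons`
#'   tibble (model_a, model_b, mean_diff, p).
#' @export
compare_feature_sets <- function(feature_sets, y, covariates = NULL, k = 10,
                                 n_repart = 100, n_perm = 99,
                                 n_repart_null = 20, gamma = NULL, seed = 1) {
  stopifnot(length(feature_sets) >= 2, !is.null(names(feature_sets)))
  n <- length(y)
  C <- if (!is.null(covariates)) covariate_matrix(covariates) else NULL
  seeds <- derive_seeds(seed, length(feature_sets) + 1)
  r_dist <- lapply(seq_along(feature_sets), function(i) {
    repartition_distribution(feature_sets[[i]], y, covariates,
                             n_repart = n_repart, k = k, gamma = gamma,
                             seed = seeds[i])
  })
  names(r_dist) <- names(feature_sets)

  null_means <- with_seed(seeds[length(seeds)], {
    t(vapply(seq_len(n_perm), function(b) {
      perm <- sample(n)
      yb <- y[perm]
      Cb <- if (is.null(C)) NULL else C[perm, , drop = FALSE]
      vapply(feature_sets, function(Xf) {
        mean(vapply(seq_len(n_repart_null), function(rr) {
          cor_from_engine(as.matrix(Xf), yb, Cb, make_folds(n, k), gamma)
        }, numeric(1)))
      }, numeric(1))
    }, numeric(length(feature_sets))))
  })
  colnames(null_means) <- names(feature_sets)

  combos <- expand.grid(a = names(feature_sets), b = names(feature_sets),
                        stringsAsFactors = FALSE)
  combos <- combos[combos$a != combos$b, ]
  combos <- lapply(seq_len(nrow(combos)), function(i) c(combos$a[i], combos$b[i]))
  comparisons <- bind_rows(lapply(combos, function(ab) {
    cm <- compare_models(r_dist[[ab[1]]], r_dist[[ab[2]]],
                         null_means[, ab, drop = FALSE])
    tibble(model_a = ab[1], model_b = ab[2],
           mean_diff = cm$mean_diff, p = cm$p)
  }))
  list(r_dist = r_dist,
       mean_r = tibble(model = names(r_dist),
                       mean_r = vapply(r_dist, mean, numeric(1))),
       comparisons = comparisons, null_means = null_means)
}

#' Structure coefficients: feature correlations with the subject score
#'
#' @param features Matrix `[subjects x features]`.
#' @param subject_scores Held-out scores from [cv_predict_scores()].
#' @param alpha FDR level for the significance mask (default 0.05).
#' @return Tibble `feature`, `r`, `p`, `q`, `significant`; zero-variance
#'   features yield `NA` and are flagged.
#' @export
structure_coefficients <- function(features, subject_scores, alpha = 0.05) {
  X <- as.matrix(features)
  if (inherits(subject_scores, "stopnet_prediction")) {
    subject_scores <- subject_scores$subject_scores
  }
  stopifnot(nrow(X) == length(subject_scores))
  res <- lapply(seq_len(ncol(X)), function(i) {
    x <- X[, i]
    if (sd(x) == 0) {
      return(tibble(feature = colnames(X)[i] %||% as.character(i),
                    r = NA_real_, p = NA_real_, flagged = TRUE))
    }
    ct <- cor.test(x, subject_scores)
    tibble(feature = colnames(X)[i] %||% as.character(i),
           r = unname(ct$estimate), p = ct$p.value, flagged = FALSE)
  })
  out <- bind_rows(res)
  mask <- fdr_bh(out$p, alpha)
  out$q <- attr(mask, "q")
  out$significant <- as.logical(mask)
  out
}

#' Correlation between two sets of subject scores
#'
#' Used to test whether activity-based and connectivity-based predictions
#' carry independent information about SSRT.
#'
#' @param scores_a,scores_b Subject-score vectors (or `stopnet_prediction`
#'   objects) over the same subjects.
#' @return Tibble `r`, `p`, `n`.
#' @export
independence_check <- function(scores_a, scores_b) {
  if (inherits(scores_a, "stopnet_prediction")) scores_a <- scores_a$subject_scores
  if (inherits(scores_b, "stopnet_prediction")) scores_b <- scores_b$subject_scores
  stopifnot(length(scores_a) == length(scores_b))
  ct <- cor.test(scores_a, scores_b)
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(scores_a))
}
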
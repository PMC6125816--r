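# Symmetric fixed-point ICA (tanh contrast) on pre-whitened data Z [k x n]:
# rows are whitened mixtures with identity covariance over the n samples.
fastica_symm <- function(Z, seed = 1, maxit = 200, tol = 1e-6) {
  k <- nrow(Z)
  n <- ncol(Z)
  W <- with_seed(seed, matrix(rnorm(k * k), k, k))
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), k) %*% t(e$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(maxit)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gprime <- rowMeans(1 - G^2)
    W_new <- (G %*% t(Z)) / n - diag(gprime, k) %*% W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(diag(W_new %*% t(W))) - 1))
    W <- W_new
    if (delta < tol) return(list(W = W, converged = TRUE, iterations = it))
  }
  list(W = W, converged = FALSE, iterations = maxit)
}

# Fix component sign: positive spatial-map skewness, ties broken by the
# sign of the largest-magnitude voxel.
fix_map_sign <- function(map) {
  m <- map - mean(map)
  sk <- mean(m^3)
  s <- sign(sk)
  if (s == 0) s <- sign(map[which.max(abs(map))])
  if (s == 0) s <- 1
  s
}

#' Group spatial ICA with stability clustering
#'
#' Temporally concatenates the subjects' `[time x voxels]` matrices,
#' PCA-reduces to `k` dimensions, and runs symmetric fixed-point ICA
#' `n_runs` times from random initializations. Components from all runs are
#' clustered by average-linkage agglomerative clustering on one minus the
#' absolute spatial correlation; each cluster's centrotype becomes a group
#' component, and its stability index is the mean intra-cluster minus mean
#' extra-cluster similarity. Component signs follow the positive-skewness
#' convention, maps and time courses are z-scored, and components are
#' ordered by decreasing stability.
#'
#' @param data_list List of subject matrices `[time x voxels]`, all sharing
#'   the voxel space.
#' @param k Model order (e.g. from [select_model_order_mdl()]).
#' @param n_runs Number of randomized ICA runs to cluster (default 100).
#' @param seed Master seed.
#' @param maxit,tol Fixed-point iteration controls.
#' @return Object of class `stopnet_ica`: `spatial_maps` `[k x voxels]`
#'   (z-scored), `group_tcs` `[total time x k]` (z-scored), `subject_tcs`
#'   list of per-subject `[time x k]` matrices, `stability_index`,
#'   `order_k`, `n_runs_used`, `labels` (filled by
#'   [classify_noise_components()]).
#' @export
group_ica <- function(data_list, k, n_runs = 100, seed = 1,
                      maxit = 200, tol = 1e-6) {
  stopifnot(length(data_list) >= 1, k >= 1)
  v <- ncol(data_list[[1]])
  if (!all(vapply(data_list, ncol, integer(1)) == v)) {
    abort("all subjects must share the voxel space", class = "stopnet_input_error")
  }
  X <- do.call(rbind, data_list)
  X <- scale(X, center = TRUE, scale = FALSE) # remove voxel means
  sv <- svd(X, nu = k, nv = k)
  if (k > sum(sv$d > sv$d[1] * 1e-9)) {
    abort("k exceeds the rank of the concatenated data", class = "stopnet_input_error")
  }
  Z <- sqrt(v) * t(sv$v[, seq_len(k), drop = FALSE]) # [k x voxels], whitened

  seeds <- derive_seeds(seed, n_runs)
  runs <- lapply(seeds, function(s) fastica_symm(Z, seed = s, maxit = maxit, tol = tol))
  ok <- vapply(runs, `[[`, logical(1), "converged")
  if (!any(ok)) abort("all ICA runs failed to converge", class = "stopnet_ica_error")
  if (!all(ok)) warn(sprintf("%d of %d ICA runs did not converge and were dropped",
                             sum(!ok), n_runs))
  S_all <- do.call(rbind, lapply(runs[ok], function(r) r$W %*% Z)) # [(k*runs) x voxels]

  sim <- abs(cor(t(S_all)))
  cl <- stats::cutree(stats::hclust(stats::as.dist(1 - sim), method = "average"), k = k)

  comp <- lapply(seq_len(k), function(ci) {
    idx <- which(cl == ci)
    intra <- if (length(idx) > 1) {
      s <- sim[idx, idx, drop = FALSE]
      mean(s[upper.tri(s)])
    } else 1
    extra <- if (length(idx) < nrow(sim)) mean(sim[idx, -idx, drop = FALSE]) else 0
    # centrotype: member most similar to the rest of its cluster
    cent <- if (length(idx) > 1) idx[which.max(rowSums(sim[idx, idx, drop = FALSE]))] else idx
    list(stability = intra - extra, map = S_all[cent, ])
  })
  stability <- vapply(comp, `[[`, numeric(1), "stability")
  maps <- do.call(rbind, lapply(comp, `[[`, "map"))
  ord <- order(stability, decreasing = TRUE)
  maps <- maps[ord, , drop = FALSE]
  stability <- stability[ord]

  signs <- apply(maps, 1, fix_map_sign)
  maps <- maps * signs
  maps_z <- t(apply(maps, 1, zscore))

  group_tcs <- spatial_regression_tcs(X, maps_z)
  n_per <- vapply(data_list, nrow, integer(1))
  ends <- cumsum(n_per)
  starts <- c(1, head(ends, -1) + 1)
  subject_tcs <- lapply(seq_along(data_list), function(i) {
    backreconstruct_subject_tcs_mat(data_list[[i]], maps_z)
  })

  structure(list(
    spatial_maps = maps_z, group_tcs = group_tcs, subject_tcs = subject_tcs,
    stability_index = pmin(pmax(stability, 0), 1), order_k = k,
    n_runs_used = sum(ok), labels = rep(NA_character_, k), seed = seed
  ), class = "stopnet_ica")
}

spatial_regression_tcs <- function(Y, maps) {
  # regress voxel data on spatial maps: TC = Y M' (M M')^-1, then z-score
  A <- Y %*% t(maps) %*% solve(maps %*% t(maps))
  apply(A, 2, zscore)
}

backreconstruct_subject_tcs_mat <- function(subject_data, maps) {
  if (ncol(subject_data) != ncol(maps)) {
    abort("subject data and maps disagree on voxel count", class = "stopnet_input_error")
  }
  Yc <- scale(subject_data, center = TRUE, scale = FALSE)
  spatial_regression_tcs(Yc, maps)
}

#' Back-reconstruct subject-specific component time courses
#'
#' Regresses a subject's voxel data onto the group spatial maps (spatial
#' regression) and z-scores the resulting time courses.
#'
#' @param ica A `stopnet_ica` object.
#' @param subject_data Matrix `[time x voxels]`.
#' @return Matrix `[time x components]`, z-scored per component.
#' @export
backreconstruct_subject_tcs <- function(ica, subject_data) {
  stopifnot(inherits(ica, "stopnet_ica"))
  backreconstruct_subject_tcs_mat(subject_data, ica$spatial_maps)
}

#' Match two sets of component maps by absolute spatial correlation
#'
#' Solves the assignment maximizing the summed absolute correlations between
#' rows of `maps_a` and rows of `maps_b` (exhaustively for up to 8
#' components, greedily beyond).
#'
#' @param maps_a,maps_b Matrices `[components x voxels]`.
#' @return Tibble with `comp_a`, `comp_b`, `abs_r`, `r`.
#' @export
match_components <- function(maps_a, maps_b) {
  r <- cor(t(maps_a), t(maps_b))
  a <- abs(r)
  ka <- nrow(a)
  kb <- ncol(a)
  k <- min(ka, kb)
  if (ka <= 8 && ka <= kb) {
    perms <- all_permutations(seq_len(kb), ka)
    best <- perms[[which.max(vapply(perms, function(p) sum(a[cbind(seq_len(ka), p)]), numeric(1)))]]
    assign_b <- best
    assign_a <- seq_len(ka)
  } else {
    # greedy: repeatedly take the largest remaining similarity
    assign_a <- integer(0)
    assign_b <- integer(0)
    aa <- a
    for (i in seq_len(k)) {
      ij <- arrayInd(which.max(aa), dim(aa))
      assign_a <- c(assign_a, ij[1])
      assign_b <- c(assign_b, ij[2])
      aa[ij[1], ] <- -1
      aa[, ij[2]] <- -1
    }
    ord <- order(assign_a)
    assign_a <- assign_a[ord]
    assign_b <- assign_b[ord]
  }
  tibble(comp_a = assign_a, comp_b = assign_b,
         abs_r = a[cbind(assign_a, assign_b)],
         r = r[cbind(assign_a, assign_b)])
}

all_permutations <- function(pool, m) {
  if (m == 0) return(list(integer(0)))
  out <- list()
  for (i in seq_along(pool)) {
    rest <- all_permutations(pool[-i], m - 1)
    out <- c(out, lapply(rest, function(r) c(pool[i], r)))
  }
  out
}
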
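#' Select PCA model order by the minimum description length criterion
#'
#' Classical MDL on sample-covariance eigenvalues for a signal-plus-isotropic
#' noise model: for each candidate order k, the code length is
#' -N (p - k) log(GM/AM of the trailing eigenvalues) + k (2p - k + 1)/2 log N,
#' and the selected order minimizes it. The matrix is transposed if needed so
#' that the larger dimension acts as the sample dimension (N > p); an
#' effective-sample-size factor can shrink N when samples are not
#' independent.
#'
#' @param data Numeric matrix `[time x voxels]` (orientation is resolved
#'   internally).
#' @param k_max Largest order considered (default: rank of the data).
#' @param ess_factor Effective-sample-size correction in (0, 1\]; multiplies
#'   N (default 1).
#' @return Integer order k (>= 0); attribute `mdl` carries the criterion
#'   values for k = 0..k_max.
#' @export
select_model_order_mdl <- function(data, k_max = NULL, ess_factor = 1) {
  X <- as.matrix(data)
  if (nrow(X) < 2 || ncol(X) < 2) {
    abort("need at least a 2 x 2 matrix", class = "stopnet_input_error")
  }
  stopifnot(ess_factor > 0, ess_factor <= 1)
  if (ncol(X) > nrow(X)) X <- t(X)
  N <- max(round(nrow(X) * ess_factor), ncol(X) + 1)
  p <- ncol(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  lam <- eigen(crossprod(Xc) / N, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  rank <- sum(lam > max(lam) * 1e-9)
  kmax <- min(k_max %||% (p - 1), rank, p - 1)
  ks <- 0:kmax
  mdl <- vapply(ks, function(k) {
    l <- lam[(k + 1):p]
    l <- pmax(l, 1e-300)
    gm <- mean(log(l))
    am <- log(mean(l))
    -N * (p - k) * (gm - am) + 0.5 * k * (2 * p - k + 1) * log(N)
  }, numeric(1))
  k <- ks[which.min(mdl)]
  k <- min(k, rank)
  structure(k, mdl = setNames(mdl, ks))
}
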
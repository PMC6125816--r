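#' Shrinkage-regularized multiple linear regression
#'
#' Replaces the sample covariance of the predictors with the
#' well-conditioned convex combination (1 - gamma) S + gamma nu I, where nu
#' is the mean eigenvalue of S and gamma is the analytic optimal shrinkage
#' intensity (the ratio of the estimation-error norm b^2 to the dispersion
#' norm d^2, capped at 1). Weights are Sigma*^-1 s_xy, which stay finite
#' even when predictors outnumber observations; gamma = 0 reproduces
#' ordinary least squares.
#'
#' @param X Predictor matrix `[n x p]`.
#' @param y Response vector.
#' @param gamma Optional fixed shrinkage intensity in \[0, 1\]; `NULL`
#'   (default) uses the analytic estimate.
#' @return Object of class `shrinkage_fit`: `weights`, `intercept`,
#'   `gamma`, `nu`.
#' @export
shrinkage_mlr_fit <- function(X, y, gamma = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 3) abort("need n >= 3", class = "stopnet_input_error")
  if (sd(y) == 0) abort("zero-variance response", class = "stopnet_input_error")
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2, xbar)
  yc <- y - ybar
  S <- crossprod(Xc) / n
  nu <- sum(diag(S)) / p
  if (is.null(gamma)) {
    d2 <- sum((S - diag(nu, p))^2)
    if (d2 < 1e-30) {
      gamma <- 0
    } else {
      # b2 = average squared Frobenius distance of per-observation outer
      # products from S, over n^2 (Ledoit-Wolf-type intensity)
      XC2 <- Xc^2
      sum_x4 <- sum(crossprod(XC2)) # sum_t ||x_t x_t'||_F^2
      b2 <- (sum_x4 / n - sum(S^2)) / n
      b2 <- min(b2, d2)
      gamma <- b2 / d2
    }
  }
  stopifnot(gamma >= 0, gamma <= 1)
  Sigma <- (1 - gamma) * S + gamma * diag(nu, p)
  s_xy <- crossprod(Xc, yc) / n
  w <- tryCatch(solve(Sigma, s_xy),
                error = function(e) MASS::ginv(Sigma) %*% s_xy)
  w <- as.numeric(w)
  structure(list(weights = setNames(w, colnames(X)),
                 intercept = ybar - sum(xbar * w),
                 gamma = gamma, nu = nu),
            class = "shrinkage_fit")
}

#' @export
predict.shrinkage_fit <- function(object, newdata, ...) {
  as.numeric(as.matrix(newdata) %*% object$weights + object$intercept)
}
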
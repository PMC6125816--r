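#' Age-moderation analysis of a brain-behavior association
#'
#' Fits the linear model y ~ scores + age + scores:age (+ covariates of no
#' interest) with subject scores and age mean-centered before the
#' interaction is formed. A significant interaction indicates that the
#' strength of the brain-behavior association changes across the life span.
#'
#' @param subject_scores Held-out subject scores (vector or
#'   `stopnet_prediction`).
#' @param age Ages in years.
#' @param y Behavioral response (e.g. SSRT).
#' @param covariates Optional data frame of covariates of no interest.
#' @return Object of class `stopnet_moderation`; its `coefficients` tibble
#'   has `term`, `estimate`, `t`, `p`, `partial_r` rows for `scores`,
#'   `age`, `scores_x_age`, and any covariates.
#' @export
moderation_analysis <- function(subject_scores, age, y, covariates = NULL) {
  if (inherits(subject_scores, "stopnet_prediction")) {
    subject_scores <- subject_scores$subject_scores
  }
  n <- length(y)
  stopifnot(length(subject_scores) == n, length(age) == n)
  dat <- data.frame(
    y = y,
    scores = subject_scores - mean(subject_scores),
    age = age - mean(age)
  )
  dat$scores_x_age <- dat$scores * dat$age
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  if (n <= ncol(dat) + 2) abort("too few observations", class = "stopnet_input_error")
  fit <- lm(y ~ ., data = dat)
  if (any(is.na(coef(fit)))) {
    abort("collinear moderation design", class = "stopnet_collinearity_error")
  }
  sm <- summary(fit)$coefficients
  df <- fit$df.residual
  terms <- setdiff(rownames(sm), "(Intercept)")
  coefs <- tibble(
    term = terms,
    estimate = unname(sm[terms, "Estimate"]),
    t = unname(sm[terms, "t value"]),
    p = unname(sm[terms, "Pr(>|t|)"]),
    partial_r = unname(sm[terms, "t value"] / sqrt(sm[terms, "t value"]^2 + df))
  )
  structure(list(coefficients = coefs, fit = fit, n = n),
            class = "stopnet_moderation")
}
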
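#' Context-independent (spontaneous) connectivity between two components
#'
#' Multiple linear regression with `tc_i` as the dependent variable and
#' `tc_j` plus all task regressors and confounds as predictors; the
#' connectivity value is the coefficient of `tc_j`. The equivalent partial
#' correlation is attached for interpretability.
#'
#' @param tc_i,tc_j Component time courses (one session).
#' @param design_session One element of [build_design_matrix()] (supplies
#'   task and confound columns).
#' @return Scalar coefficient with attribute `partial_r`.
#' @export
spontaneous_connectivity <- function(tc_i, tc_j, design_session) {
  X <- if (is.list(design_session)) design_session$X else design_session
  if (length(tc_i) != length(tc_j) || length(tc_i) != nrow(X)) {
    abort("series lengths disagree", class = "stopnet_input_error")
  }
  M <- cbind(tc_j = tc_j, X)
  q <- qr(M)
  if (q$rank < ncol(M)) {
    dropped <- colnames(M)[q$pivot[(q$rank + 1):ncol(M)]]
    abort(paste("collinear columns:", paste(dropped, collapse = ", ")),
          class = "stopnet_collinearity_error")
  }
  beta <- qr.coef(q, tc_i)[1]
  ri <- residualize(tc_i, X)
  rj <- residualize(tc_j, X)
  structure(unname(beta), partial_r = suppressWarnings(cor(ri, rj)))
}

residualize <- function(y, Z) {
  fit <- lm.fit(Z, y)
  res <- fit$residuals
  if (any(!is.finite(res))) {
    # ridge fallback for near-singular Z
    ZtZ <- crossprod(Z) + 1e-8 * diag(ncol(Z))
    res <- y - Z %*% solve(ZtZ, crossprod(Z, y))
    warn("near-singular nuisance matrix; ridge residualization used")
  }
  as.numeric(res)
}

#' Psychological contrast series for context-dependent connectivity
#'
#' +1/-1 coded event series for a condition contrast, mean-centered and (by
#' default) convolved with the double-gamma HRF, sampled at the TR.
#'
#' @param behavior_session One session's rows of a `stopnet_behavior`.
#' @param n_volumes,tr_s Acquisition grid.
#' @param contrast Two categories, coded +1 and -1 (default SuccStop,
#'   UnsuccStop).
#' @param hrf Convolve with the HRF (default `TRUE`); `FALSE` leaves the
#'   raw boxcar coding.
#' @param duration_s Event duration for the raw coding (seconds): each event
#'   marks every volume whose acquisition time falls in
#'   `[onset, onset + duration_s)`; `0` (default) marks the first volume at
#'   or after the onset. Ignored when `hrf = TRUE`.
#' @return Numeric series of length `n_volumes`, mean-centered.
#' @export
build_psych_contrast <- function(behavior_session, n_volumes, tr_s,
                                 contrast = c("SuccStop", "UnsuccStop"),
                                 hrf = TRUE, duration_s = 0) {
  on_pos <- behavior_session$onset_s[behavior_session$category == contrast[1]]
  on_neg <- behavior_session$onset_s[behavior_session$category == contrast[2]]
  if (length(on_pos) == 0 || length(on_neg) == 0) {
    abort("both contrast conditions must be present", class = "stopnet_input_error")
  }
  if (hrf) {
    s <- hrf_regressor(on_pos, n_volumes, tr_s) - hrf_regressor(on_neg, n_volumes, tr_s)
  } else {
    s <- numeric(n_volumes)
    t_vol <- (seq_len(n_volumes) - 1) * tr_s
    mark <- function(onsets, sign) {
      for (o in onsets) {
        idx <- if (duration_s > 0) {
          which(t_vol >= o & t_vol < o + duration_s)
        } else {
          which(t_vol >= o)[1]
        }
        idx <- idx[!is.na(idx)]
        s[idx] <<- s[idx] + sign
      }
    }
    mark(on_pos, 1)
    mark(on_neg, -1)
  }
  s - mean(s)
}

#' Context-dependent (psychophysiological-interaction) connectivity
#'
#' Quantifies the change in coupling between two component time courses
#' across the psychological contrast. Two constructions are provided:
#'
#' * `method = "regression"` (default): the symmetrized PPI partial
#'   correlation, \[pcor(psych * tc_i, tc_j | tc_i, Psi, C) +
#'   pcor(psych * tc_j, tc_i | tc_j, Psi, C)\] / 2. Under constant coupling
#'   its expectation is zero, so it isolates the condition-dependent
#'   coupling change from spontaneous correlation.
#' * `method = "interaction"`: the correlation of the two interaction terms
#'   `tc_i * psych` and `tc_j * psych` after residualizing each against
#'   Z = \{tc_i, tc_j, Psi, C\}. This construction inherits the static
#'   coupling between the pair (its null expectation equals the spontaneous
#'   correlation, reweighted by psych^2), which is why it is not the
#'   default; it is retained for comparability with the correlational-PPI
#'   literature.
#'
#' Both are symmetric in (i, j) by construction.
#'
#' @param tc_i,tc_j Component time courses (one session).
#' @param psych Psychological contrast series ([build_psych_contrast()]).
#' @param design_session One element of [build_design_matrix()]; its full
#'   column set (task + confounds + intercept) enters the nuisance set.
#' @param method `"regression"` or `"interaction"`.
#' @return Partial correlation in \[-1, 1\]; `NA` with a warning when a
#'   residual series is degenerate.
#' @export
cppi <- function(tc_i, tc_j, psych, design_session,
                 method = c("regression", "interaction")) {
  method <- match.arg(method)
  X <- if (is.list(design_session)) design_session$X else design_session
  if (length(unique(c(length(tc_i), length(tc_j), length(psych), nrow(X)))) != 1) {
    abort("series lengths disagree", class = "stopnet_input_error")
  }
  if (method == "interaction") {
    Z <- cbind(tc_i = tc_i, tc_j = tc_j, X)
    ii <- residualize(tc_i * psych, Z)
    jj <- residualize(tc_j * psych, Z)
    if (sd(ii) == 0 || sd(jj) == 0) {
      warn("degenerate residual interaction term; cPPI undefined")
      return(NA_real_)
    }
    return(cor(ii, jj))
  }
  r1 <- ppi_direction(tc_i, tc_j, psych, X)
  r2 <- ppi_direction(tc_j, tc_i, psych, X)
  if (is.na(r1) || is.na(r2)) return(NA_real_)
  (r1 + r2) / 2
}

# partial correlation of (psych * seed) with target, given {seed, X}
ppi_direction <- function(seed_tc, target_tc, psych, X) {
  Z <- cbind(seed = seed_tc, X)
  a <- residualize(seed_tc * psych, Z)
  b <- residualize(target_tc, Z)
  if (sd(a) == 0 || sd(b) == 0) {
    warn("degenerate residual interaction term; cPPI undefined")
    return(NA_real_)
  }
  cor(a, b)
}

#' Single-series significance test for context-dependent coupling
#'
#' Directional PPI regression test: fits
#' `tc_i ~ tc_j + psych * tc_j + Psi + C` with AR(1) prewhitening (the
#' lag-one residual autocorrelation is estimated from an initial OLS pass
#' and removed by quasi-differencing, as in standard task-fMRI GLMs) and
#' returns the t-test of the interaction coefficient -- a calibrated
#' per-series test of coupling change. The symmetric [cppi()] value is the
#' quantity carried to group analyses.
#'
#' @inheritParams cppi
#' @return Tibble `estimate`, `t`, `p`, `df`, `ar1` (estimated residual
#'   autocorrelation).
#' @export
cppi_inference <- function(tc_i, tc_j, psych, design_session) {
  X <- if (is.list(design_session)) design_session$X else design_session
  M <- cbind(interaction = tc_j * psych, tc_j = tc_j, X)
  fit0 <- lm.fit(M, tc_i)
  r0 <- fit0$residuals
  rho <- sum(r0[-1] * r0[-length(r0)]) / sum(r0^2)
  rho <- min(max(rho, 0), 0.95)
  n <- length(tc_i)
  yw <- tc_i[-1] - rho * tc_i[-n]
  Mw <- M[-1, , drop = FALSE] - rho * M[-n, , drop = FALSE]
  # quasi-differencing zeroes constant columns; keep the intercept scaled
  const <- which(apply(Mw, 2, function(c) all(abs(c) < 1e-12)))
  Mw[, const] <- 1
  fit <- lm.fit(Mw, yw)
  df <- nrow(Mw) - fit$rank
  res_var <- sum(fit$residuals^2) / df
  XtXinv_11 <- tryCatch(solve(crossprod(Mw))[1, 1],
                        error = function(e) MASS::ginv(crossprod(Mw))[1, 1])
  tval <- fit$coefficients[1] / sqrt(res_var * XtXinv_11)
  tibble(estimate = unname(fit$coefficients[1]), t = unname(tval),
         p = 2 * pt(abs(tval), df, lower.tail = FALSE), df = df, ar1 = rho)
}

#' All-pairs connectivity for one subject, averaged over sessions
#'
#' @param tcs_sessions List (sessions) of `[time x components]` matrices.
#' @param design_matrices A [build_design_matrix()] result for the subject.
#' @param behavior The subject's `stopnet_behavior` (needed for `cppi`).
#' @param kind `"spontaneous"` or `"cppi"`.
#' @param contrast Condition pair for the psychological term.
#' @param hrf Convolve the psychological term (default `TRUE`).
#' @return Long tibble `comp_i`, `comp_j` (i < j), `kind`, `value`.
#' @export
subject_connectivity <- function(tcs_sessions, design_matrices, behavior = NULL,
                                 kind = c("spontaneous", "cppi"),
                                 contrast = c("SuccStop", "UnsuccStop"),
                                 hrf = TRUE) {
  kind <- match.arg(kind)
  k <- ncol(tcs_sessions[[1]])
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  vals <- matrix(NA_real_, nrow(pairs), length(tcs_sessions))
  for (si in seq_along(tcs_sessions)) {
    tcs <- tcs_sessions[[si]]
    dm <- design_matrices[[si]]
    psych <- NULL
    if (kind == "cppi") {
      beh_s <- behavior[behavior$session == dm$session, ]
      psych <- build_psych_contrast(beh_s, nrow(tcs), dm$tr_s, contrast, hrf)
    }
    for (pi in seq_len(nrow(pairs))) {
      i <- pairs[pi, 1]
      j <- pairs[pi, 2]
      vals[pi, si] <- if (kind == "spontaneous") {
        as.numeric(spontaneous_connectivity(tcs[, i], tcs[, j], dm))
      } else {
        cppi(tcs[, i], tcs[, j], psych, dm)
      }
    }
  }
  tibble(comp_i = pairs[, 1], comp_j = pairs[, 2], kind = kind,
         value = rowMeans(vals, na.rm = TRUE))
}

#' Group and age tests over connectivity values
#'
#' Fisher-z transforms the per-subject connectivity values, then runs a
#' one-sample t-test per connection (group effect, FDR at `alpha_group`)
#' and a robust age regression per connection (age effect, FDR at
#' `alpha_age`).
#'
#' @param conn_long Long tibble from [subject_connectivity()] rows bound
#'   over subjects, with a `subject_id` column.
#' @param ages Named vector or tibble mapping subject to age.
#' @param covariates Optional covariate data frame (subject order must
#'   match `ages`).
#' @param alpha_group,alpha_age FDR levels (defaults 0.01 / 0.05).
#' @return List with `group` and `age` tibbles (one row per connection).
#' @export
connectivity_group_tests <- function(conn_long, ages, covariates = NULL,
                                     alpha_group = 0.01, alpha_age = 0.05) {
  conn_long$connection <- paste0(conn_long$comp_i, "-", conn_long$comp_j)
  wide <- tidyr::pivot_wider(conn_long[, c("subject_id", "connection", "value")],
                             names_from = "connection", values_from = "value")
  ids <- wide$subject_id
  m <- as.matrix(wide[, -1, drop = FALSE])
  if (nrow(m) < 3) abort("need >= 3 subjects", class = "stopnet_input_error")
  z <- fisher_z(pmin(pmax(m, -0.999999), 0.999999))
  grp <- group_responsivity_test(z, alpha = alpha_group)
  grp$connection <- colnames(m)[grp$component]
  age_vec <- if (is.data.frame(ages)) ages$age_years[match(ids, ages$subject_id)] else ages[ids]
  age <- age_effect_table(z, age_vec, covariates, alpha = alpha_age)
  list(group = grp, age = age)
}
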
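#' Benjamini-Hochberg false-discovery-rate mask
#'
#' Step-up procedure controlling the expected false-discovery proportion at
#' `alpha` (via [stats::p.adjust()]).
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param alpha FDR level.
#' @return Logical rejection mask; attribute `q` holds the adjusted values.
#' @export
fdr_bh <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]", class = "stopnet_input_error")
  }
  q <- p.adjust(p, method = "BH")
  structure(!is.na(q) & q <= alpha, q = q)
}

#' Group-level one-sample tests of component responsivity
#'
#' Per-component one-sample t-test of the responsivity index against zero,
#' with Benjamini-Hochberg correction at `alpha` (default 0.01, the
#' conventional group-effect level in this pipeline).
#'
#' @param responsivity Matrix `[subjects x components]`.
#' @param alpha FDR level (default 0.01).
#' @return Tibble with `component`, `mean`, `t`, `p`, `q`, `significant`.
#' @export
group_responsivity_test <- function(responsivity, alpha = 0.01) {
  responsivity <- as.matrix(responsivity)
  if (nrow(responsivity) < 3) abort("need >= 3 subjects", class = "stopnet_input_error")
  k <- ncol(responsivity)
  res <- lapply(seq_len(k), function(i) {
    x <- responsivity[, i]
    x <- x[is.finite(x)]
    if (length(x) < 3 || sd(x) == 0) {
      return(tibble(component = i, mean = mean(x), t = NA_real_, p = NA_real_,
                    flagged = TRUE))
    }
    tt <- t.test(x)
    tibble(component = i, mean = unname(tt$estimate), t = unname(tt$statistic),
           p = tt$p.value, flagged = FALSE)
  })
  out <- bind_rows(res)
  mask <- fdr_bh(out$p, alpha)
  out$q <- attr(mask, "q")
  out$significant <- as.logical(mask)
  nm <- colnames(responsivity)
  if (!is.null(nm)) out$label <- nm
  out
}

#' Robust age-effect regression (Huber weights)
#'
#' Fits the orientation used throughout this pipeline: age as the dependent
#' variable, the brain measure plus covariates of no interest as
#' predictors, using iteratively reweighted least squares with Huber's psi
#' (tuning constant 1.345, up to 50 iterations). The p-value for the brain
#' measure uses the t-distribution with n - p degrees of freedom; the
#' equivalent partial correlation is reported for interpretability.
#'
#' @param values Numeric vector (brain measure across subjects).
#' @param age Numeric vector of ages.
#' @param covariates Optional data frame of covariates of no interest.
#' @return One-row tibble: `estimate`, `t`, `p`, `partial_r`, `n`.
#' @export
age_effect_robust <- function(values, age, covariates = NULL) {
  ok <- is.finite(values) & is.finite(age)
  dat <- data.frame(age = age, value = values)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    keep <- vapply(covariates, function(x) length(unique(x[ok])) > 1, logical(1))
    if (!all(keep)) {
      warn(paste("dropping constant covariates:",
                 paste(names(covariates)[!keep], collapse = ", ")))
    }
    covariates <- covariates[, keep, drop = FALSE]
    ok <- ok & complete.cases(covariates)
    dat <- cbind(dat, covariates)
  }
  dat <- dat[ok, , drop = FALSE]
  n <- nrow(dat)
  p_par <- ncol(dat) # predictors + intercept
  if (n <= p_par + 2) abort("too few observations", class = "stopnet_input_error")
  fit <- MASS::rlm(age ~ ., data = dat, psi = MASS::psi.huber, k = 1.345,
                   maxit = 50)
  sm <- summary(fit)$coefficients
  tval <- sm["value", "t value"]
  df <- n - nrow(sm)
  pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  tibble(estimate = sm["value", "Value"], t = tval, p = pval,
         partial_r = tval / sqrt(tval^2 + df), n = n)
}

#' Age effects across components or connections with FDR control
#'
#' @param values_matrix Matrix `[subjects x measures]`.
#' @param age Ages.
#' @param covariates Optional covariate data frame.
#' @param alpha FDR level (default 0.05, the conventional age-effect level).
#' @return Tibble with one row per measure plus `q` and `significant`.
#' @export
age_effect_table <- function(values_matrix, age, covariates = NULL, alpha = 0.05) {
  values_matrix <- as.matrix(values_matrix)
  rows <- lapply(seq_len(ncol(values_matrix)), function(i) {
    r <- tryCatch(age_effect_robust(values_matrix[, i], age, covariates),
                  error = function(e) tibble(estimate = NA_real_, t = NA_real_,
                                             p = NA_real_, partial_r = NA_real_,
                                             n = NA_integer_))
    r$measure <- colnames(values_matrix)[i] %||% as.character(i)
    r
  })
  out <- bind_rows(rows)
  mask <- fdr_bh(out$p, alpha)
  out$q <- attr(mask, "q")
  out$significant <- as.logical(mask)
  out[, c("measure", "estimate", "t", "p", "q", "significant", "partial_r", "n")]
}

#' Event-locked average time course
#'
#' Extracts windows aligned to the nearest volume at each onset, subtracts
#' the value at the onset volume (baseline), and averages across events.
#'
#' @param tc Component time course (one session).
#' @param onsets Event onsets in seconds.
#' @param window_s Window length in seconds (default 16).
#' @param tr_s Repetition time.
#' @return Tibble `time_s`, `mean_response`, `n_events`; zero-row tibble
#'   (with a warning) when there are no events.
#' @export
peri_event_average <- function(tc, onsets, window_s = 16, tr_s = 2) {
  n_win <- floor(window_s / tr_s) + 1
  if (length(onsets) == 0) {
    warn("no events for peri-event average")
    return(tibble(time_s = numeric(0), mean_response = numeric(0), n_events = integer(0)))
  }
  segs <- lapply(onsets, function(o) {
    i0 <- round(o / tr_s) + 1
    idx <- i0:(i0 + n_win - 1)
    if (max(idx) > length(tc)) {
      warn("peri-event window truncated at series end")
      idx <- idx[idx <= length(tc)]
    }
    if (min(idx) < 1 || length(idx) == 0) return(NULL)
    seg <- tc[idx] - tc[idx[1]]
    c(seg, rep(NA_real_, n_win - length(seg)))
  })
  segs <- do.call(rbind, segs[!vapply(segs, is.null, logical(1))])
  tibble(time_s = (seq_len(n_win) - 1) * tr_s,
         mean_response = colMeans(segs, na.rm = TRUE),
         n_events = colSums(!is.na(segs)))
}
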
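#' Premature-response-corrected probability of responding on Stop trials
#'
#' Responses faster than the stop-signal delay (the signal had not yet been
#' shown) are removed from both numerator and denominator:
#' p(respond|signal) = (N_StopSignal - N_SuccStop - N_RT<SSD) /
#' (N_StopSignal - N_RT<SSD).
#'
#' @param n_stopsignal Total Stop-Signal trials.
#' @param n_succstop Successful stops.
#' @param n_rt_lt_ssd Responses faster than the SSD (premature responses).
#' @return Probability in \[0, 1\].
#' @export
p_respond_given_signal <- function(n_stopsignal, n_succstop, n_rt_lt_ssd = 0) {
  denom <- n_stopsignal - n_rt_lt_ssd
  if (denom <= 0) {
    abort("p(respond|signal) undefined: no usable Stop-Signal trials",
          class = "stopnet_undefined_statistic")
  }
  if (n_succstop + n_rt_lt_ssd > n_stopsignal || min(n_stopsignal, n_succstop, n_rt_lt_ssd) < 0) {
    abort("inconsistent Stop-trial counts", class = "stopnet_input_error")
  }
  (n_stopsignal - n_succstop - n_rt_lt_ssd) / denom
}

#' Partition trials into blocks of a fixed number of Stop-Signal trials
#'
#' Consecutive trials (in onset order) are grouped so that each full block
#' contains exactly `stops_per_block` Stop-Signal trials. A trailing
#' remainder of at least `min_remainder` Stop trials forms its own final
#' block; a smaller remainder is absorbed into the preceding block.
#'
#' @param trials Trial tibble with a `trial_type` column.
#' @param stops_per_block Stop trials per block (default 30).
#' @param min_remainder Minimum Stop trials for a standalone final block
#'   (default 15).
#' @return The input with a `block` integer column appended.
#' @export
partition_blocks <- function(trials, stops_per_block = 30, min_remainder = 15) {
  stopifnot(stops_per_block >= 1)
  is_stop <- as.character(trials$trial_type) == "Stop"
  n_stop <- sum(is_stop)
  trials$block <- NA_integer_
  if (n_stop == 0) return(trials[0, ])
  stop_rank <- cumsum(is_stop)
  # block of a trial = block of the next stop trial at or after it
  blk <- (pmin(stop_rank + !is_stop, n_stop) - 1) %/% stops_per_block + 1
  n_full <- n_stop %/% stops_per_block
  remainder <- n_stop %% stops_per_block
  n_blocks <- n_full + (remainder > 0)
  if (remainder > 0 && (remainder < min_remainder || n_full == 0)) {
    if (n_full > 0) {
      blk[blk > n_full] <- n_full
      n_blocks <- n_full
    } else {
      blk[] <- 1
      n_blocks <- 1
    }
  }
  trials$block <- pmin(blk, n_blocks)
  trials
}

#' Block-based integration estimate of the stop-signal reaction time
#'
#' Within each block: Go omissions are assigned the block's maximum Go RT
#' (omission correction), Go RTs are ranked ascending, the critical Go RT is
#' the n-th ranked RT with n = max(1, round(p * N)) (round half up) where p
#' is the block's premature-response-corrected p(respond|signal) and N the
#' number of (corrected) Go RTs, and block SSRT = critical Go RT - mean SSD.
#' The subject's SSRT is the mean over estimable blocks.
#'
#' @param behavior A `stopnet_behavior` tibble (or any trial table with
#'   `trial_type`, `category`, `rt_ms`, `ssd_ms`).
#' @param stops_per_block,min_remainder Block layout, see
#'   [partition_blocks()].
#' @return A list of class `ssrt_estimate`: `ssrt_ms` (subject mean) and
#'   `blocks`, a tibble with per-block `p_respond_signal`,
#'   `critical_go_rt_ms`, `mean_ssd_ms`, `ssrt_ms`, `estimable`.
#' @export
estimate_ssrt_block_integration <- function(behavior, stops_per_block = 30,
                                            min_remainder = 15) {
  trials <- partition_blocks(behavior, stops_per_block, min_remainder)
  if (nrow(trials) == 0 || !any(trials$category %in% c("correctGo"))) {
    abort("SSRT estimation requires Go and Stop trials", class = "stopnet_estimation_error")
  }
  blocks <- lapply(split(trials, trials$block), function(b) {
    stop_idx <- as.character(b$trial_type) == "Stop"
    n_ss <- sum(stop_idx)
    n_early <- sum(b$category == "EarlySS")
    n_succ <- sum(b$category == "SuccStop")
    go_rt <- b$rt_ms[b$category == "correctGo"]
    n_omit <- sum(b$category == "GoOmission")
    p <- tryCatch(p_respond_given_signal(n_ss, n_succ, n_early),
                  stopnet_undefined_statistic = function(e) NA_real_)
    mean_ssd <- mean(b$ssd_ms[stop_idx & b$category != "EarlySS"], na.rm = TRUE)
    if (length(go_rt) == 0 || is.na(p) || p <= 0 || !is.finite(mean_ssd)) {
      return(tibble(block_id = b$block[1], p_respond_signal = p,
                    critical_go_rt_ms = NA_real_, mean_ssd_ms = mean_ssd,
                    ssrt_ms = NA_real_, estimable = FALSE))
    }
    # omission correction: omitted Go trials enter at the block's max Go RT
    go_rt <- c(go_rt, rep(max(go_rt), n_omit))
    go_rt <- sort(go_rt)
    n <- max(1L, min(length(go_rt), round_half_up(p * length(go_rt))))
    crit <- go_rt[n]
    tibble(block_id = b$block[1], p_respond_signal = p,
           critical_go_rt_ms = crit, mean_ssd_ms = mean_ssd,
           ssrt_ms = crit - mean_ssd, estimable = TRUE)
  })
  blocks <- bind_rows(blocks)
  est <- blocks$ssrt_ms[blocks$estimable]
  if (!length(est)) {
    abort("no estimable blocks", class = "stopnet_estimation_error")
  }
  structure(list(ssrt_ms = mean(est), blocks = blocks), class = "ssrt_estimate")
}

#' Per-subject behavioral summary
#'
#' Mean correct-Go RT, Go and No-Go accuracy, p(respond|signal), SSRT by
#' the block-based integration method, and trial-category counts.
#'
#' @param behavior A `stopnet_behavior` tibble.
#' @param ... Passed to [estimate_ssrt_block_integration()].
#' @return One-row tibble with `go_rt_mean_ms`, `go_accuracy`,
#'   `nogo_accuracy`, `p_respond_signal`, `ssrt_ms`, `n_stop`, `n_early_ss`,
#'   `nogo_defined`.
#' @export
summarize_performance <- function(behavior, ...) {
  cat_n <- table(factor(behavior$category,
                        levels = c("correctGo", "GoCommission", "GoOmission",
                                   "correctNoGo", "NoGoCommission",
                                   "SuccStop", "UnsuccStop", "EarlySS", "IncorrectSS")))
  n_go <- sum(cat_n[c("correctGo", "GoCommission", "GoOmission")])
  n_nogo <- sum(cat_n[c("correctNoGo", "NoGoCommission")])
  n_stop <- sum(cat_n[c("SuccStop", "UnsuccStop", "EarlySS", "IncorrectSS")])
  p_rs <- tryCatch(
    p_respond_given_signal(n_stop, cat_n[["SuccStop"]], cat_n[["EarlySS"]]),
    stopnet_undefined_statistic = function(e) NA_real_
  )
  ssrt <- tryCatch(estimate_ssrt_block_integration(behavior, ...)$ssrt_ms,
                   stopnet_estimation_error = function(e) NA_real_)
  tibble(
    go_rt_mean_ms = mean(behavior$rt_ms[behavior$category == "correctGo"]),
    go_accuracy = if (n_go > 0) cat_n[["correctGo"]] / n_go else NA_real_,
    nogo_accuracy = if (n_nogo > 0) cat_n[["correctNoGo"]] / n_nogo else NA_real_,
    nogo_defined = n_nogo > 0,
    p_respond_signal = p_rs,
    ssrt_ms = ssrt,
    n_stop = n_stop,
    n_early_ss = cat_n[["EarlySS"]]
  )
}

#' Apply cohort-level exclusion rules
#'
#' Excludes (a) subjects with more than `max_early_ss` premature-response
#' Stop trials (fewer than 80 - `max_early_ss` usable Stop trials, below
#' the recommended minimum for the block-based integration method) and
#' (b) subjects whose mean head displacement, after regressing displacement
#' on age by OLS, lies `motion_sd_cut` SDs or more above the residual mean.
#'
#' @param summaries Tibble with one row per subject, containing
#'   `n_early_ss`, `mean_displacement_mm`, `age_years` (and any id columns).
#' @param max_early_ss Premature-response tolerance (default 10).
#' @param motion_sd_cut Residual-SD cutoff (default 3.5).
#' @return The input tibble with logical `excluded` and character
#'   `exclusion_reason` columns; attribute `exclusion_log` holds the log.
#' @export
apply_exclusions <- function(summaries, max_early_ss = 10, motion_sd_cut = 3.5) {
  stopifnot(nrow(summaries) >= 3)
  reason <- rep(NA_character_, nrow(summaries))
  too_early <- summaries$n_early_ss > max_early_ss
  reason[too_early] <- "stop-trial minimum"

  fit <- lm(mean_displacement_mm ~ age_years, data = summaries)
  res <- resid(fit)
  s <- sd(res)
  if (is.finite(s) && s > 0) {
    high_motion <- res >= motion_sd_cut * s
    reason[high_motion & is.na(reason)] <- "excessive head motion"
  }
  summaries$excluded <- !is.na(reason)
  summaries$exclusion_reason <- reason
  log <- summaries[summaries$excluded,
                   intersect(c("subject_id", "n_early_ss", "mean_displacement_mm",
                               "age_years", "exclusion_reason"), names(summaries))]
  attr(summaries, "exclusion_log") <- log
  summaries
}

#' Cohort behavioral summary with age trends
#'
#' Runs [summarize_performance()] for each subject of a simulated cohort and
#' reports OLS age slopes of the main behavioral measures.
#'
#' @param behaviors Named list of `stopnet_behavior` tibbles.
#' @param ages Numeric vector of ages (same order).
#' @return List with `subjects` tibble and `age_trends` tibble
#'   (term/slope/p per measure).
#' @export
cohort_behavior_summary <- function(behaviors, ages) {
  stopifnot(length(behaviors) == length(ages))
  subjects <- bind_rows(lapply(behaviors, summarize_performance))
  subjects$age_years <- ages
  if (!is.null(names(behaviors))) subjects$subject_id <- names(behaviors)
  trends <- bind_rows(lapply(c("go_rt_mean_ms", "ssrt_ms", "go_accuracy", "nogo_accuracy"),
    function(v) {
      ok <- is.finite(subjects[[v]])
      if (sum(ok) < 3 || sd(subjects[[v]][ok]) == 0) {
        return(tibble(measure = v, slope_per_year = NA_real_, p_value = NA_real_))
      }
      f <- lm(subjects[[v]][ok] ~ ages[ok])
      sm <- summary(f)$coefficients
      tibble(measure = v, slope_per_year = sm[2, 1], p_value = sm[2, 4])
    }))
  list(subjects = subjects, age_trends = trends)
}
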
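#' Race-model parameters for go and stop finishing times
#'
#' The behavioral generator assumes the independent-race account of stopping:
#' a go process and a stop process race, and a response is produced iff the
#' go process finishes before the stop-signal delay plus the stop finishing
#' time. Go finishing times are ex-Gaussian (normal plus exponential, the
#' standard empirical RT shape); stop finishing times are normal truncated
#' at zero.
#'
#' @param go_rt_mu,go_rt_sigma,go_rt_tau Ex-Gaussian parameters of the Go
#'   finishing-time distribution, in milliseconds (mean RT is
#'   `go_rt_mu + go_rt_tau`).
#' @param ssrt_mu,ssrt_sigma Mean and SD of the stop finishing-time
#'   distribution (ms), truncated at zero.
#' @param go_omission_p Probability of omitting a response on a Go trial.
#' @param go_error_p Probability that a produced response has the wrong
#'   direction.
#' @param trigger_failure_p Probability that the stop process never starts
#'   on a Stop trial.
#' @return A list of class `race_params`.
#' @export
race_params <- function(go_rt_mu = 400, go_rt_sigma = 50, go_rt_tau = 100,
                        ssrt_mu = 200, ssrt_sigma = 30,
                        go_omission_p = 0.02, go_error_p = 0.02,
                        trigger_failure_p = 0) {
  p <- list(
    go_rt_mu = go_rt_mu, go_rt_sigma = go_rt_sigma, go_rt_tau = go_rt_tau,
    ssrt_mu = ssrt_mu, ssrt_sigma = ssrt_sigma,
    go_omission_p = go_omission_p, go_error_p = go_error_p,
    trigger_failure_p = trigger_failure_p
  )
  if (any(c(go_rt_sigma, go_rt_tau, ssrt_sigma) < 0) || go_rt_mu <= 0 || ssrt_mu <= 0) {
    abort("race scale/location parameters must be positive", class = "stopnet_config_error")
  }
  probs <- c(go_omission_p, go_error_p, trigger_failure_p)
  if (any(probs < 0 | probs > 1)) {
    abort("probabilities must lie in [0, 1]", class = "stopnet_config_error")
  }
  structure(p, class = "race_params")
}

#' Staircase configuration for the stop-signal delay tracker
#'
#' One-up/one-down tracking: the stop-signal delay (SSD) increases by
#' `step_ms` after a successful stop and decreases by `step_ms` after a
#' response on a Stop trial, converging on ~50% response cancellation.
#'
#' @param initial_ssd_ms Starting SSD (default 250 ms).
#' @param step_ms Step size (default 50 ms).
#' @param min_ssd_ms,max_ssd_ms Clamping bounds (defaults 0 and 900 ms).
#' @return A list of class `staircase_config`.
#' @export
staircase_config <- function(initial_ssd_ms = 250, step_ms = 50,
                             min_ssd_ms = 0, max_ssd_ms = 900) {
  if (step_ms <= 0) abort("step_ms must be > 0", class = "stopnet_config_error")
  if (!(min_ssd_ms <= initial_ssd_ms && initial_ssd_ms <= max_ssd_ms)) {
    abort("need min_ssd_ms <= initial_ssd_ms <= max_ssd_ms",
          class = "stopnet_config_error")
  }
  structure(list(initial_ssd_ms = initial_ssd_ms, step_ms = step_ms,
                 min_ssd_ms = min_ssd_ms, max_ssd_ms = max_ssd_ms),
            class = "staircase_config")
}

rexgauss <- function(n, mu, sigma, tau) {
  rnorm(n, mu, sigma) + if (tau > 0) rexp(n, 1 / tau) else 0
}

rtruncnorm_pos <- function(n, mu, sigma) {
  x <- rnorm(n, mu, sigma)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mu, sigma)
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Simulate trial-by-trial SNG behavior under the independent race model
#'
#' Walks the design in onset order. Go trials draw an ex-Gaussian finishing
#' time and resolve omission/commission errors by the configured rates. Stop
#' trials draw independent go and stop finishing times; a response occurs iff
#' the go time is below SSD + stop time (always, on trigger failures), and
#' the SSD then moves one staircase step (up after successful stops, down
#' after responses), clamped to its bounds. No-Go trials are treated as Stop
#' trials with SSD fixed at 0. Each trial is assigned the outcome category
#' used by the downstream design matrices.
#'
#' @param design A `stopnet_design` tibble (see [generate_task_design()]).
#' @param params A [race_params()] object.
#' @param staircase A [staircase_config()] object.
#' @param seed Integer seed.
#' @return A tibble of class `stopnet_behavior`: the design columns plus
#'   `responded`, `response` (left/right/none), `rt_ms`, `ssd_ms` (Stop
#'   trials only), `category` in {correctGo, GoCommission, GoOmission,
#'   correctNoGo, NoGoCommission, SuccStop, UnsuccStop, EarlySS,
#'   IncorrectSS}.
#' @export
simulate_race_behavior <- function(design, params = race_params(),
                                   staircase = staircase_config(), seed = 1) {
  if (nrow(design) == 0) abort("design is empty", class = "stopnet_config_error")
  stopifnot(inherits(params, "race_params"), inherits(staircase, "staircase_config"))

  n <- nrow(design)
  with_seed(seed, {
    go_time <- rexgauss(n, params$go_rt_mu, params$go_rt_sigma, params$go_rt_tau)
    go_time <- pmax(go_time, 1)
    stop_time <- rtruncnorm_pos(n, params$ssrt_mu, params$ssrt_sigma)
    trig_fail <- runif(n) < params$trigger_failure_p
    omit <- runif(n) < params$go_omission_p
    wrong <- runif(n) < params$go_error_p

    type <- as.character(design$trial_type)
    responded <- logical(n)
    rt <- rep(NA_real_, n)
    ssd <- rep(NA_real_, n)
    category <- character(n)
    response <- rep("none", n)
    cur_ssd <- staircase$initial_ssd_ms

    for (i in seq_len(n)) {
      if (type[i] == "Go") {
        if (omit[i]) {
          category[i] <- "GoOmission"
        } else {
          responded[i] <- TRUE
          rt[i] <- go_time[i]
          response[i] <- if (wrong[i]) setdiff(c("left", "right"), design$arrow_dir[i]) else design$arrow_dir[i]
          category[i] <- if (wrong[i]) "GoCommission" else "correctGo"
        }
      } else {
        this_ssd <- if (type[i] == "Stop") cur_ssd else 0
        resp <- trig_fail[i] || go_time[i] < this_ssd + stop_time[i]
        if (type[i] == "NoGo") {
          # No-Go: omission of the go process also counts as a correct withhold
          resp <- resp && !omit[i]
          if (resp) {
            responded[i] <- TRUE
            rt[i] <- go_time[i]
            response[i] <- if (wrong[i]) setdiff(c("left", "right"), design$arrow_dir[i]) else design$arrow_dir[i]
            category[i] <- "NoGoCommission"
          } else {
            category[i] <- "correctNoGo"
          }
        } else {
          ssd[i] <- this_ssd
          resp <- resp && !omit[i]
          if (resp) {
            responded[i] <- TRUE
            rt[i] <- go_time[i]
            response[i] <- if (wrong[i]) setdiff(c("left", "right"), design$arrow_dir[i]) else design$arrow_dir[i]
            category[i] <- if (rt[i] < this_ssd) {
              "EarlySS"
            } else if (wrong[i]) {
              "IncorrectSS"
            } else {
              "UnsuccStop"
            }
          } else {
            category[i] <- "SuccStop"
          }
          # 1-up/1-down tracker toward 50% response cancellation
          cur_ssd <- if (resp) cur_ssd - staircase$step_ms else cur_ssd + staircase$step_ms
          cur_ssd <- min(max(cur_ssd, staircase$min_ssd_ms), staircase$max_ssd_ms)
        }
      }
    }

    out <- as_tibble(design)
    out$responded <- responded
    out$response <- response
    out$rt_ms <- rt
    out$ssd_ms <- ssd
    out$category <- category
    structure(out, class = c("stopnet_behavior", class(out)),
              tr_s = design_tr(design),
              n_volumes_per_session = design_n_volumes(design),
              seed = seed)
  })
}
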
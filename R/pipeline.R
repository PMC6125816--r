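default_pipeline_config <- function() {
  list(
    seed = 1,
    out_dir = NULL,
    cohort = list(n_subjects = 20, age_range = c(18, 88)),
    task = list(n_go = 360, n_stop = 80, n_nogo = 40, n_sessions = 2,
                iti_s = 2.5, tr_s = 2),
    truth = list(n_components = 5, grid = c(12, 12, 10)),
    ica = list(order = "auto", n_runs = 20),
    thresholds = list(fdr_group = 0.01, fdr_age = 0.05),
    cv = list(k = 10, n_perm = 199, n_repart = 50, n_repart_null = 10)
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults, rejects unknown keys, and checks value ranges and units
#' (times in seconds, trial parameters in milliseconds are handled by the
#' respective constructors).
#'
#' @param config Named list (possibly empty), e.g. from
#'   [yaml::read_yaml()].
#' @return Normalized config list, or an error enumerating the problems.
#' @export
validate_config <- function(config = list()) {
  defaults <- default_pipeline_config()
  errors <- character(0)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    errors <- c(errors, paste("unknown config keys:", paste(unknown, collapse = ", ")))
  }
  allowed <- lapply(defaults, names)
  allowed$truth <- setdiff(names(formals(ground_truth_spec)), "")
  for (sec in intersect(names(config), names(defaults))) {
    if (is.list(defaults[[sec]])) {
      bad <- setdiff(names(config[[sec]]), allowed[[sec]])
      if (length(bad)) {
        errors <- c(errors, paste0("unknown keys in '", sec, "': ",
                                   paste(bad, collapse = ", ")))
      }
    }
  }
  cfg <- utils::modifyList(defaults, config)
  if (!is.null(cfg$task$iti_s) && cfg$task$iti_s > 60) {
    errors <- c(errors, "task$iti_s > 60: looks like milliseconds; expected seconds")
  }
  if (!is.null(cfg$task$tr_s) && cfg$task$tr_s > 30) {
    errors <- c(errors, "task$tr_s > 30: looks like milliseconds; expected seconds")
  }
  th <- unlist(cfg$thresholds)
  if (any(th <= 0 | th >= 1)) errors <- c(errors, "thresholds must lie in (0, 1)")
  if (cfg$cv$k > cfg$cohort$n_subjects / 2) {
    errors <- c(errors, "cv$k exceeds n_subjects / 2")
  }
  if (length(errors)) {
    abort(paste0("invalid configuration:\n- ", paste(errors, collapse = "\n- ")),
          class = "stopnet_config_error")
  }
  cfg
}

#' Run the full simulate-analyze pipeline
#'
#' Executes, in order: cohort simulation (behavior, motion, BOLD), behavioral
#' summaries and exclusions, group ICA with order selection and noise
#' classification, component responsivity GLMs with group/age statistics,
#' spontaneous and cPPI connectivity with group/age statistics,
#' cross-validated prediction of SSRT from activity (Model 1), spontaneous
#' connectivity (Model 2), cPPI (Model 3), and the joint feature set
#' (Model 4), model comparison, structure coefficients, independence of
#' subject scores, and the age-moderation analyses. All randomness derives
#' from `config$seed`. When `config$out_dir` is set, every stage writes its
#' tables (CSV/TSV/JSON) plus a markdown report and a manifest.
#'
#' @param config A configuration list (validated via [validate_config()]).
#' @return A report bundle (list) with the per-stage results.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  seeds <- derive_seeds(cfg$seed, 10)
  out <- list(config = cfg)
  t0 <- Sys.time()

  # --- stage 1: cohort simulation -------------------------------------
  truth <- do.call(ground_truth_spec, cfg$truth)
  cohort <- generate_cohort(cfg$cohort$n_subjects, cfg$cohort$age_range,
                            truth = truth, seed = seeds[1])
  design <- do.call(generate_task_design, c(cfg$task, list(seed = seeds[2])))
  subj <- lapply(seq_len(cfg$cohort$n_subjects), function(i) {
    simulate_subject_data(cohort, i, design = design)
  })
  out$cohort <- cohort

  # --- stage 2: behavior and exclusions -------------------------------
  beh_sum <- bind_rows(lapply(subj, function(s) summarize_performance(s$behavior)))
  beh_sum$subject_id <- cohort$subjects$subject_id
  beh_sum$age_years <- cohort$subjects$age_years
  beh_sum$mean_displacement_mm <- vapply(subj, function(s) {
    mean(vapply(s$motion, mean_rms_displacement, numeric(1)))
  }, numeric(1))
  beh_sum <- apply_exclusions(beh_sum)
  keep <- which(!beh_sum$excluded)
  if (length(keep) < 2 * cfg$cv$k) {
    warn("few subjects survive exclusions; prediction models may be skipped")
  }
  out$behavior <- beh_sum
  out$exclusion_log <- attr(beh_sum, "exclusion_log")

  # --- stage 3: group ICA ---------------------------------------------
  data_list <- lapply(subj[keep], function(s) {
    do.call(rbind, lapply(s$bold$sessions, `[[`, "Y"))
  })
  order_k <- cfg$ica$order
  if (identical(order_k, "auto")) {
    per_subj <- vapply(data_list, function(d) {
      as.integer(select_model_order_mdl(d))
    }, integer(1))
    order_k <- max(1L, as.integer(round(median(per_subj))))
    out$mdl_orders <- per_subj
  }
  ica <- group_ica(data_list, k = order_k, n_runs = cfg$ica$n_runs, seed = seeds[3])
  cls <- classify_noise_components(ica, tr_s = cfg$task$tr_s)
  ica <- set_component_labels(ica, cls)
  signal <- which(ica$labels == "signal")
  gt_match <- match_components(truth$spatial_maps, ica$spatial_maps)
  out$ica <- ica
  out$noise_classification <- cls
  out$ground_truth_match <- gt_match

  # --- stage 4: activity ----------------------------------------------
  n_vol <- design_n_volumes(design)
  dms <- lapply(subj[keep], function(s) {
    build_design_matrix(s$behavior, motion = s$motion)
  })
  tcs_sessions <- lapply(subj[keep], function(s) {
    lapply(s$bold$sessions, function(sess) {
      backreconstruct_subject_tcs(ica, sess$Y)[, signal, drop = FALSE]
    })
  })
  resp <- responsivity_table(tcs_sessions, dms)
  colnames(resp) <- paste0("IC", signal)
  ages <- cohort$subjects$age_years[keep]
  covs <- data.frame(
    gender = cohort$subjects$gender[keep],
    handedness = cohort$subjects$handedness[keep],
    education_years = cohort$subjects$education_years[keep]
  )
  out$responsivity <- resp
  out$responsivity_group <- group_responsivity_test(resp, cfg$thresholds$fdr_group)
  out$responsivity_age <- age_effect_table(resp, ages, covs, cfg$thresholds$fdr_age)

  # --- stage 5: connectivity ------------------------------------------
  conn <- lapply(c("spontaneous", "cppi"), function(kind) {
    rows <- lapply(seq_along(keep), function(ii) {
      sc <- subject_connectivity(tcs_sessions[[ii]], dms[[ii]],
                                 behavior = subj[[keep[ii]]]$behavior, kind = kind)
      sc$subject_id <- cohort$subjects$subject_id[keep[ii]]
      sc
    })
    bind_rows(rows)
  })
  names(conn) <- c("spontaneous", "cppi")
  age_tbl <- tibble(subject_id = cohort$subjects$subject_id[keep], age_years = ages)
  out$connectivity <- conn
  out$connectivity_tests <- lapply(conn, connectivity_group_tests, ages = age_tbl,
                                   covariates = covs,
                                   alpha_group = cfg$thresholds$fdr_group,
                                   alpha_age = cfg$thresholds$fdr_age)

  # --- stage 6: prediction and moderation -----------------------------
  y <- beh_sum$ssrt_ms[keep]
  pred_covs <- cbind(covs,
                     mean_displacement_mm = beh_sum$mean_displacement_mm[keep],
                     go_rt_mean_ms = beh_sum$go_rt_mean_ms[keep])
  conn_wide <- function(kind) {
    cl <- conn[[kind]]
    cl$connection <- paste0(kind, "_", cl$comp_i, "-", cl$comp_j)
    w <- tidyr::pivot_wider(cl[, c("subject_id", "connection", "value")],
                            names_from = "connection", values_from = "value")
    as.matrix(w[match(cohort$subjects$subject_id[keep], w$subject_id), -1])
  }
  feats <- list(
    model1_activity = resp,
    model2_spontaneous = conn_wide("spontaneous"),
    model3_cppi = conn_wide("cppi")
  )
  feats$model4_joint <- cbind(feats$model1_activity, feats$model3_cppi)

  if (length(y) >= 2 * cfg$cv$k && sd(y) > 0) {
    models <- lapply(seq_along(feats), function(i) {
      pr <- cv_predict_scores(feats[[i]], y, covariates = pred_covs,
                              k = cfg$cv$k, seed = seeds[4] + i)
      pp <- permutation_pvalue(feats[[i]], y, covariates = pred_covs,
                               n_perm = cfg$cv$n_perm, k = cfg$cv$k,
                               seed = seeds[5] + i)
      list(prediction = pr, permutation = pp,
           structure = structure_coefficients(feats[[i]], pr))
    })
    names(models) <- names(feats)
    out$models <- models
    out$model_summary <- bind_rows(lapply(names(models), function(nm) {
      tibble(model = nm,
             observed_r = models[[nm]]$prediction$observed_r,
             permutation_p = models[[nm]]$permutation$p)
    }))
    out$comparison <- compare_feature_sets(
      feats[c("model1_activity", "model3_cppi", "model4_joint")], y,
      covariates = pred_covs, k = cfg$cv$k, n_repart = cfg$cv$n_repart,
      n_perm = cfg$cv$n_perm, n_repart_null = cfg$cv$n_repart_null,
      seed = seeds[6]
    )
    out$independence <- independence_check(models$model1_activity$prediction,
                                           models$model3_cppi$prediction)
    out$moderation <- lapply(models[c("model1_activity", "model3_cppi")],
      function(m) {
        tryCatch(moderation_analysis(m$prediction, ages, y, covariates = covs),
                 stopnet_input_error = function(e) NULL)
      })
  }

  out$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(out, cfg$out_dir)
  structure(out, class = "stopnet_pipeline")
}

write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) readr::write_csv(as_tibble(x), file.path(dir, name))
  w(out$behavior, "behavior.csv")
  jsonlite::write_json(out$exclusion_log %||% list(),
                       file.path(dir, "exclusions.json"), auto_unbox = TRUE)
  w(tibble(component = seq_along(out$ica$stability_index),
           stability = out$ica$stability_index, label = out$ica$labels),
    "ica_components.csv")
  readr::write_csv(as_tibble(as.data.frame(out$responsivity)), file.path(dir, "responsivity.csv"))
  w(out$responsivity_group, "responsivity_group.csv")
  w(out$responsivity_age, "responsivity_age.csv")
  for (kind in names(out$connectivity)) {
    w(out$connectivity[[kind]], paste0("connectivity_", kind, ".csv"))
  }
  if (!is.null(out$model_summary)) {
    w(out$model_summary, "model_summary.csv")
    w(out$comparison$comparisons, "model_comparisons.csv")
    mod <- bind_rows(lapply(names(out$moderation), function(nm) {
      cbind(model = nm, out$moderation[[nm]]$coefficients)
    }))
    w(mod, "moderation.csv")
    jsonlite::write_json(
      lapply(out$models, function(m) list(
        observed_r = m$prediction$observed_r,
        permutation_p = m$permutation$p,
        gamma_per_fold = m$prediction$gamma
      )),
      file.path(dir, "prediction.json"), auto_unbox = TRUE, digits = NA
    )
  }
  jsonlite::write_json(
    list(config = out$config, elapsed_s = out$elapsed_s,
         n_excluded = sum(out$behavior$excluded)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE
  )
  writeLines(render_report(out), file.path(dir, "report.md"))
  invisible(dir)
}

render_report <- function(out) {
  lines <- c(
    "# Pipeline report", "",
    sprintf("Subjects simulated: %d; excluded: %d (%s)",
            nrow(out$behavior), sum(out$behavior$excluded),
            paste(out$exclusion_log$exclusion_reason %||% "none", collapse = "; ")),
    sprintf("ICA order: %d; mean stability %.3f; signal components: %s",
            out$ica$order_k, mean(out$ica$stability_index),
            paste(which(out$ica$labels == "signal"), collapse = ", ")),
    sprintf("Ground-truth map recovery (mean |r|): %.3f",
            mean(out$ground_truth_match$abs_r)), ""
  )
  if (!is.null(out$model_summary)) {
    lines <- c(lines, "## Prediction models", "",
               utils::capture.output(print(as.data.frame(out$model_summary))),
               "", "## Moderation", "",
               unlist(lapply(names(out$moderation), function(nm) {
                 c(paste0("### ", nm),
                   utils::capture.output(print(as.data.frame(out$moderation[[nm]]$coefficients))))
               })))
  }
  lines
}
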
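#' Split-half validation of a group ICA decomposition
#'
#' Reruns the group decomposition within each half of the cohort (e.g. a
#' median split on SSRT), matches each half's components to the full-sample
#' decomposition by absolute spatial correlation, and summarizes similarity
#' as (a) spatial correlations per matched component, (b) between-subject
#' ICC -- the correlation of each component's concatenated subject time
#' courses between the half-decomposition and the full one, and (c)
#' within-subject ICC -- the correlation of each subject's vectorized
#' component-connectivity profile between the two decompositions. All
#' correlations are Fisher-z transformed before averaging and testing; group
#' differences are tested by ANOVA on the transformed spatial similarities
#' (controlling for component), by Kruskal-Wallis for between-subject ICC,
#' and by one-way ANOVA for within-subject ICC.
#'
#' @param data_list List of subject matrices `[time x voxels]`.
#' @param split Factor/vector with two levels assigning subjects to halves.
#' @param k Model order.
#' @param n_runs ICA runs per decomposition (default 20 here; the full
#'   decomposition budget is usually spent once, not per half).
#' @param seed Master seed.
#' @return List of class `stopnet_splithalf`: `spatial` tibble (group,
#'   component, r, z), `between_icc`, `within_icc` tibbles, and `tests`
#'   tibble of p-values.
#' @export
split_half_similarity <- function(data_list, split, k, n_runs = 20, seed = 1) {
  split <- as.factor(split)
  stopifnot(length(split) == length(data_list), nlevels(split) == 2)
  if (min(table(split)) < 2) abort("each split needs >= 2 subjects", class = "stopnet_input_error")
  seeds <- derive_seeds(seed, 3)
  full <- group_ica(data_list, k, n_runs = n_runs, seed = seeds[1])
  halves <- lapply(1:2, function(g) {
    idx <- which(split == levels(split)[g])
    ica <- group_ica(data_list[idx], k, n_runs = n_runs, seed = seeds[1 + g])
    list(idx = idx, ica = ica, match = match_components(full$spatial_maps, ica$spatial_maps))
  })

  spatial <- bind_rows(lapply(1:2, function(g) {
    m <- halves[[g]]$match
    tibble(group = levels(split)[g], component = m$comp_a,
           r = m$abs_r, z = fisher_z(m$abs_r))
  }))

  between <- bind_rows(lapply(1:2, function(g) {
    h <- halves[[g]]
    perm <- h$match$comp_b[order(h$match$comp_a)]
    bind_rows(lapply(seq_len(k), function(ci) {
      full_tc <- unlist(lapply(h$idx, function(i) full$subject_tcs[[i]][, ci]))
      half_tc <- unlist(lapply(seq_along(h$idx), function(j) h$ica$subject_tcs[[j]][, perm[ci]]))
      r <- abs(cor(full_tc, half_tc))
      tibble(group = levels(split)[g], component = ci, r = r, z = fisher_z(r))
    }))
  }))

  within <- bind_rows(lapply(1:2, function(g) {
    h <- halves[[g]]
    perm <- h$match$comp_b[order(h$match$comp_a)]
    bind_rows(lapply(seq_along(h$idx), function(j) {
      fc_full <- cor(full$subject_tcs[[h$idx[j]]])
      fc_half <- cor(h$ica$subject_tcs[[j]][, perm, drop = FALSE])
      r <- cor(fc_full[upper.tri(fc_full)], fc_half[upper.tri(fc_half)])
      tibble(group = levels(split)[g], subject = h$idx[j], r = r, z = fisher_z(r))
    }))
  }))

  p_spatial <- tryCatch({
    f <- aov(z ~ group + factor(component), data = spatial)
    summary(f)[[1]]["group", "Pr(>F)"]
  }, error = function(e) NA_real_)
  p_between <- tryCatch(stats::kruskal.test(z ~ group, data = between)$p.value,
                        error = function(e) NA_real_)
  p_within <- tryCatch({
    f <- aov(z ~ group, data = within)
    summary(f)[[1]]["group", "Pr(>F)"]
  }, error = function(e) NA_real_)

  structure(list(
    spatial = spatial, between_icc = between, within_icc = within,
    tests = tibble(
      measure = c("spatial", "between_icc", "within_icc"),
      p_value = c(p_spatial, p_between, p_within)
    ),
    full = full
  ), class = "stopnet_splithalf")
}
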
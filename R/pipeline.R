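#' Run the full gait-instability analysis
#'
#' Chains the whole workflow on loaded tables: plausibility filtering with
#' whole-day exclusion, per-day run averaging, the minimum-measurement-
#' days dog filter, per-dog linear detrending with the MSE instability
#' score, pathological-side alignment, and the healthy-vs-HD group
#' comparison per feature.
#'
#' @param runs Run table ([read_runs()] or [simulate_cohort()]).
#' @param dogs Dog metadata.
#' @param features Feature catalogue.
#' @param bounds Plausibility bounds ([exclusion_bounds()]).
#' @param min_days Minimum distinct measurement days per dog (default 4).
#' @param alpha Significance level of the group tests (default 0.05).
#' @param reference_side Side convention for healthy dogs
#'   (default `"right"`).
#' @param var_equal Pooled (default) or Welch t-test.
#' @param p_adjust Multiple-testing correction (default `"none"`).
#' @return A list: `exclusions`, `removed_dogs`, `series`, `instability`,
#'   `comparisons`, and `counts` (the preprocessing conservation counts
#'   plus dogs analysed).
#' @export
run_gait_analysis <- function(runs, dogs, features,
                              bounds = exclusion_bounds(), min_days = 4,
                              alpha = 0.05, reference_side = "right",
                              var_equal = TRUE, p_adjust = "none") {
  pre <- preprocess_runs(runs, features, bounds = bounds,
                         min_days = min_days)
  if (nrow(pre$series) == 0) {
    gv_abort("no dog passes the minimum-measurement-days filter: empty cohort",
             "gv_degenerate_error")
  }
  instab <- build_instability_table(pre$series, dogs, features,
                                    reference_side = reference_side)
  comparisons <- compare_all_features(instab, alpha = alpha,
                                      var_equal = var_equal,
                                      p_adjust = p_adjust)
  list(
    exclusions = pre$exclusions,
    removed_dogs = pre$removed_dogs,
    series = pre$series,
    instability = instab,
    comparisons = comparisons,
    counts = c(pre$counts,
               dogs_analysed = dplyr::n_distinct(instab$dog_id))
  )
}
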
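#' Run the full accuracy pipeline on a measurement table
#'
#' Convenience wrapper chaining every analysis stage: per-day reference
#' truth, percent deviations, per-(device, condition) accuracy summaries,
#' accuracy-band classification, error-grid zoning of the condition
#' averages, device-error tallies, reference drift check, and (when a cost
#' config is given) the Group 1-4 ranking.
#'
#' @param records Canonical measurement tibble (from [read_measurements()]
#'   or [simulate_study()]).
#' @param zones Error-grid `zone_polygon_set` (default [parkes_zones()]).
#' @param cost_config Optional cost-tier config for [rank_devices()].
#' @param z Limits-of-agreement multiplier.
#' @param band_thresholds Thresholds for the within-band point fractions.
#' @param drift_threshold_pct Flag threshold for [truth_drift_check()].
#' @return A list of class `gluc_analysis`: `truths`, `deviations`,
#'   `summary`, `bands`, `zone_results`, `tallies`, `drift`, and `ranking`
#'   (`NULL` without a cost config).
#' @export
#' @examples
#' sim <- simulate_study(study_design(days = 2, seed = 3),
#'                       list(device_profile("demo", base_bias_pct = -4,
#'                                           sigma_low_pct = 5, sigma_high_pct = 3)))
#' res <- analyze_study(sim$records)
#' res$summary
analyze_study <- function(records, zones = parkes_zones(), cost_config = NULL,
                          z = 1.96, band_thresholds = c(8, 15, 20),
                          drift_threshold_pct = 5) {
  truths <- build_truth(records)
  deviations <- compute_deviations(records, truths)
  summary <- summarize_accuracy(deviations, z = z)
  bands <- summarize_bands(deviations, thresholds = band_thresholds)
  zone_results <- classify_condition_averages(summary, zones)
  tallies <- tally_errors(records)
  drift <- truth_drift_check(truths, threshold_pct = drift_threshold_pct)
  ranking <- if (!is.null(cost_config)) {
    rank_devices(summary, bands, cost_config,
                 expected_conditions = dplyr::distinct(records, .data$target_hct,
                                                       .data$target_glucose))
  }
  structure(
    list(truths = truths, deviations = deviations, summary = summary,
         bands = bands, zone_results = zone_results, tallies = tallies,
         drift = drift, ranking = ranking),
    class = "gluc_analysis"
  )
}
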
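#' Build per-day, per-condition reference truth
#'
#' For each (day, condition) group the "true value" is the arithmetic mean
#' of that day's reference-analyzer replicates — never pooled across days,
#' because realized hematocrit and glucose differ between donor days even
#' when targets match. Grouping is by the *nominal* targets; realized levels
#' (mean measured hematocrit) are carried along as metadata.
#'
#' Reference replicates are deduplicated on (day, condition, replicate,
#' value): every meter row of a replicate carries the same analyzer value,
#' which must be counted once.
#'
#' @param records Measurement tibble (user-error rows are ignored).
#' @return Tibble with one row per (day_id, target_hct, target_glucose):
#'   `mean_reference` (mg/dL), `n_replicates`, `replicate_values`
#'   (list-column ordered by replicate index), `mean_measured_hct`.
#' @export
build_truth <- function(records) {
  usable <- dplyr::filter(records, !.data$user_error)
  groups <- dplyr::distinct(usable, .data$day_id, .data$target_hct, .data$target_glucose)

  refs <- usable |>
    dplyr::filter(!is.na(.data$reference)) |>
    dplyr::distinct(.data$day_id, .data$target_hct, .data$target_glucose,
                    .data$replicate, .data$reference)

  empty <- dplyr::anti_join(groups, refs,
                            by = c("day_id", "target_hct", "target_glucose"))
  if (nrow(empty) > 0) {
    abort(sprintf(
      "No reference values for group(s): %s",
      paste(sprintf("%s/%s", empty$day_id,
                    condition_label(empty$target_hct, empty$target_glucose)),
            collapse = "; ")
    ))
  }

  hct <- usable |>
    dplyr::group_by(.data$day_id, .data$target_hct, .data$target_glucose) |>
    dplyr::summarise(mean_measured_hct = mean(.data$measured_hct, na.rm = TRUE),
                     .groups = "drop")

  refs |>
    dplyr::arrange(.data$day_id, .data$target_hct, .data$target_glucose, .data$replicate) |>
    dplyr::group_by(.data$day_id, .data$target_hct, .data$target_glucose) |>
    dplyr::summarise(
      mean_reference = mean(.data$reference),
      n_replicates = dplyr::n(),
      replicate_values = list(.data$reference),
      .groups = "drop"
    ) |>
    dplyr::left_join(hct, by = c("day_id", "target_hct", "target_glucose"))
}

#' Percent deviation of each meter reading from its day's truth
#'
#' Attaches to every valid meter reading the signed percent deviation from
#' the mean reference value of its own (day, condition) group:
#' `100 * (meter - truth) / truth`. Readings in mmol/L are converted to
#' mg/dL first. Device-error and user-error records are excluded.
#'
#' @param records Measurement tibble.
#' @param truths Output of [build_truth()]; computed from `records` when
#'   omitted.
#' @return Tibble of deviation points with `meter_value`, `true_value`
#'   (both mg/dL) and `percent_deviation`.
#' @export
compute_deviations <- function(records, truths = NULL) {
  if (is.null(truths)) truths <- build_truth(records)
  valid <- records |>
    dplyr::filter(!.data$user_error, !is.na(.data$reading)) |>
    standardize_units()

  joined <- dplyr::left_join(
    valid,
    dplyr::select(truths, "day_id", "target_hct", "target_glucose", "mean_reference"),
    by = c("day_id", "target_hct", "target_glucose")
  )
  if (anyNA(joined$mean_reference)) {
    miss <- joined[is.na(joined$mean_reference), ]
    abort(sprintf(
      "Reading(s) without a matching reference truth, e.g. %s/%s",
      miss$day_id[1], condition_label(miss$target_hct[1], miss$target_glucose[1])
    ))
  }

  joined |>
    dplyr::transmute(
      device_model = .data$device_model,
      device_unit_id = .data$device_unit_id,
      strip_lot = .data$strip_lot,
      day_id = .data$day_id,
      target_hct = .data$target_hct,
      target_glucose = .data$target_glucose,
      meter_value = .data$reading,
      true_value = .data$mean_reference,
      percent_deviation = 100 * (.data$reading - .data$mean_reference) / .data$mean_reference
    )
}

#' Check reference replicates for within-run glucose drift
#'
#' Glycolysis continues in ex-vivo whole blood, so the reference value could
#' fall across the replicates of a run. Reports, per (day, condition), the
#' least-squares slope of reference value against replicate index and the
#' first-to-last percent change, flagging groups whose absolute change
#' exceeds `threshold_pct` (default 5%, configurable).
#'
#' @param truths Output of [build_truth()].
#' @param threshold_pct Flag threshold on |first-to-last percent change|.
#' @return Tibble with `slope_mgdl_per_replicate`, `first_to_last_pct`,
#'   `flagged`.
#' @export
truth_drift_check <- function(truths, threshold_pct = 5) {
  .assert_scalar_number(threshold_pct, "threshold_pct", min = 0)
  truths |>
    dplyr::mutate(
      slope_mgdl_per_replicate = purrr::map_dbl(.data$replicate_values, function(v) {
        if (length(v) < 2) return(NA_real_)
        idx <- seq_along(v)
        stats::cov(idx, v) / stats::var(idx)
      }),
      first_to_last_pct = purrr::map_dbl(.data$replicate_values, function(v) {
        if (length(v) < 2 || v[1] == 0) return(NA_real_)
        100 * (v[length(v)] - v[1]) / v[1]
      }),
      flagged = !is.na(.data$first_to_last_pct) &
        abs(.data$first_to_last_pct) > threshold_pct
    ) |>
    dplyr::select(-"replicate_values")
}
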
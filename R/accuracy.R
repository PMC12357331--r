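# Headline accuracy statistics: mean percent bias, MARD, SD of percent
# deviation, and 95% limits of agreement at the nominal glucose level.
# All three base statistics operate on the signed percent deviations
# produced by compute_deviations().

.pull_deviations <- function(points) {
  if (is.data.frame(points)) points <- points$percent_deviation
  if (!is.numeric(points)) abort("`points` must be numeric percent deviations or a deviation tibble.")
  points
}

#' Mean percent bias
#'
#' Arithmetic mean of the signed percent deviations of meter readings from
#' the reference average. An empty input yields `NA`, never 0.
#'
#' @param points Numeric vector of signed percent deviations, or a tibble
#'   from [compute_deviations()].
#' @return Percent (signed scalar).
#' @export
#' @examples
#' mean_percent_bias(c(-12, -8, -10)) # -10
mean_percent_bias <- function(points) {
  x <- .pull_deviations(points)
  if (length(x) == 0) return(NA_real_)
  mean(x)
}

#' Mean absolute relative difference (MARD)
#'
#' Mean of the absolute percent deviations — the standard glucometer
#' accuracy metric. Always at least `|mean_percent_bias|`, with equality
#' exactly when all deviations share one sign.
#'
#' @inheritParams mean_percent_bias
#' @return Percent (non-negative scalar); `NA` on empty input.
#' @export
#' @examples
#' mard(c(10, -10)) # 10
mard <- function(points) {
  x <- .pull_deviations(points)
  if (length(x) == 0) return(NA_real_)
  mean(abs(x))
}

#' Standard deviation of percent deviation
#'
#' Sample (n-1) standard deviation of the signed percent deviations; the
#' precision component of the summary. Returns `NA` below two points.
#'
#' @inheritParams mean_percent_bias
#' @return Percent (non-negative scalar); `NA` when n < 2.
#' @export
sd_percent <- function(points) {
  x <- .pull_deviations(points)
  if (length(x) < 2) return(NA_real_)
  sd(x)
}

#' 95% limits of agreement at a nominal glucose level
#'
#' Converts a (bias, SD) pair in percent into the mg/dL interval within
#' which the device is expected to report 95% of its values at the given
#' nominal glucose:
#' `nominal * (1 + (bias -/+ z * sd) / 100)`. The multiplier `z = 1.96` is
#' the usual two-sided normal 95% quantile and is configurable.
#'
#' @param mean_bias Mean percent bias (signed percent).
#' @param sd_pct SD of percent deviation (percent).
#' @param nominal_glucose Nominal glucose level, mg/dL; must be positive.
#' @param z Normal quantile multiplier (default 1.96).
#' @return Named numeric vector `c(loa_low, loa_high)` in mg/dL.
#' @export
#' @examples
#' limits_of_agreement(0, 10, 40) # 32.16, 47.84
limits_of_agreement <- function(mean_bias, sd_pct, nominal_glucose, z = 1.96) {
  .assert_scalar_number(nominal_glucose, "nominal_glucose")
  if (nominal_glucose <= 0) abort("`nominal_glucose` must be positive.")
  if (is.na(mean_bias) || is.na(sd_pct)) {
    return(c(loa_low = NA_real_, loa_high = NA_real_))
  }
  c(
    loa_low = nominal_glucose * (1 + (mean_bias - z * sd_pct) / 100),
    loa_high = nominal_glucose * (1 + (mean_bias + z * sd_pct) / 100)
  )
}

#' Per-device, per-condition accuracy summary
#'
#' Pools the percent deviations of each device model within each condition
#' stratum — across days, meter units and strip lots — and reports n, mean
#' percent bias, MARD, SD of percent deviation, mean meter and mean
#' reference value (mg/dL), and the 95% limits of agreement evaluated at
#' the condition's nominal (target) glucose.
#'
#' @param deviations Tibble from [compute_deviations()].
#' @param z Limits-of-agreement multiplier (default 1.96).
#' @return Tibble with one row per (device_model, target_hct,
#'   target_glucose).
#' @export
summarize_accuracy <- function(deviations, z = 1.96) {
  deviations |>
    dplyr::group_by(.data$device_model, .data$target_hct, .data$target_glucose) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_percent_bias = mean(.data$percent_deviation),
      mard = mean(abs(.data$percent_deviation)),
      sd_percent = dplyr::if_else(dplyr::n() >= 2, sd(.data$percent_deviation), NA_real_),
      mean_meter = mean(.data$meter_value),
      mean_reference = mean(.data$true_value),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      loa_low = .data$target_glucose *
        (1 + (.data$mean_percent_bias - z * .data$sd_percent) / 100),
      loa_high = .data$target_glucose *
        (1 + (.data$mean_percent_bias + z * .data$sd_percent) / 100)
    ) |>
    dplyr::arrange(.data$device_model, .data$target_glucose, .data$target_hct)
}
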
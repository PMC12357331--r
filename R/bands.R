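# Accuracy-band classification against the three published guidelines:
# +/-8% (UNICEF-NEST360 TPP minimal requirement and proposed CLIA limit),
# +/-15% (ISO 15197:2015, percentage limb) and +/-20% (ISO 15197:2003).
# Percentage limits are applied at every glucose level, including below
# 100 mg/dL, to keep devices comparable across strata; the ISO absolute
# mg/dL limb for low glucose is deliberately not implemented (extension
# point via `thresholds`).

.band_levels <- c("green", "orange", "red")

#' Classify mean percent bias into traffic-light accuracy bands
#'
#' `green` when |bias| is within +/-8%, `orange` when between 8% and 15%,
#' `red` beyond 15%. Boundary values belong to the inner (safer) band:
#' "within +/-8%" includes 8 itself. Symmetric in sign.
#'
#' @param mean_bias Numeric vector of mean percent bias values.
#' @param inner,outer Band thresholds in percent (defaults 8 and 15).
#' @return Ordered factor with levels green < orange < red (`NA` in,
#'   `NA` out).
#' @export
#' @examples
#' classify_band(c(-7.9, -10.3, -22))
classify_band <- function(mean_bias, inner = 8, outer = 15) {
  if (!is.numeric(mean_bias)) abort("`mean_bias` must be numeric.")
  a <- abs(mean_bias)
  out <- dplyr::case_when(
    is.na(a) ~ NA_character_,
    a <= inner ~ "green",
    a <= outer ~ "orange",
    TRUE ~ "red"
  )
  factor(out, levels = .band_levels, ordered = TRUE)
}

#' Fraction of points within each accuracy threshold
#'
#' For each threshold `t`, the fraction of deviation points with
#' `|percent_deviation| <= t`. Non-decreasing in the threshold by
#' construction.
#'
#' @inheritParams mean_percent_bias
#' @param thresholds Percent thresholds (default `c(8, 15, 20)`).
#' @return Named numeric vector, one proportion per threshold (`NA`s on
#'   empty input).
#' @export
#' @examples
#' within_band_fractions(c(5, 10, 20)) # 1/3, 2/3, 1
within_band_fractions <- function(points, thresholds = c(8, 15, 20)) {
  x <- .pull_deviations(points)
  if (any(thresholds < 0)) abort("`thresholds` must be non-negative.")
  vals <- if (length(x) == 0) rep(NA_real_, length(thresholds)) else {
    vapply(thresholds, function(t) mean(abs(x) <= t), numeric(1))
  }
  setNames(vals, sprintf("frac_within_%g", thresholds))
}

#' Band classification per device and condition
#'
#' Combines [classify_band()] on the pooled mean percent bias with the
#' within-threshold point fractions, one row per (device, condition).
#'
#' @param deviations Tibble from [compute_deviations()].
#' @param thresholds Thresholds for the point fractions (default
#'   `c(8, 15, 20)`).
#' @param inner,outer Band limits passed to [classify_band()].
#' @return Tibble with `band` and one `frac_within_*` column per threshold.
#' @export
summarize_bands <- function(deviations, thresholds = c(8, 15, 20),
                            inner = 8, outer = 15) {
  deviations |>
    dplyr::group_by(.data$device_model, .data$target_hct, .data$target_glucose) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_percent_bias = mean(.data$percent_deviation),
      fr = list(within_band_fractions(.data$percent_deviation, thresholds)),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("fr") |>
    dplyr::mutate(band = classify_band(.data$mean_percent_bias, inner, outer),
                  .after = "mean_percent_bias") |>
    dplyr::arrange(.data$device_model, .data$target_glucose, .data$target_hct)
}
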
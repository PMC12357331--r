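# Device grouping from accuracy, precision and consumable cost.
#
# The published grouping of bench-tested meters is narrative; the rule here
# is an explicit, documented reconstruction of it, and every report that
# prints a group labels it as such. All thresholds are arguments.

.cost_tiers <- c("meets_TPP", "exceeds_2_3x", "exceeds_20x", "unknown")

#' Rank devices into Groups 1-4
#'
#' Deterministic grouping rule (a documented reconstruction of the
#' published narrative ranking):
#'
#' 1. **Group 4** — any condition banded red (|mean bias| > 15%), or SD of
#'    percent deviation above `low_glucose_sd_max` (default 15%) at the low
#'    glucose level: serious accuracy or precision failure in a condition
#'    that matters for neonates.
#' 2. **Group 3** — otherwise, any condition banded orange, or overall
#'    precision gate failed (`max SD > sd_max`, default 10%): usable with
#'    awareness of the limitation.
#' 3. **Groups 1/2** — all conditions green and precision gate passed;
#'    consumable cost splits them: high-cost tiers (`exceeds_2_3x`,
#'    `exceeds_20x`) form Group 1, devices meeting the cost target (or of
#'    unknown cost) form Group 2.
#'
#' The rule is monotone: improving any bias or SD toward zero can never
#' worsen a device's group, and group assignments do not depend on the
#' order of devices or rows.
#'
#' @param summaries Tibble from [summarize_accuracy()].
#' @param bands Tibble from [summarize_bands()]; recomputed from
#'   `summaries$mean_percent_bias` when omitted (bands only; point
#'   fractions are not needed for ranking).
#' @param cost_config Named character vector or two-column data frame
#'   (`device_model`, `cost_tier`) with tiers among `meets_TPP`,
#'   `exceeds_2_3x`, `exceeds_20x`, `unknown`. Devices absent from the
#'   config get `"unknown"`. Cost tiers are inputs, never computed.
#' @param sd_max Precision gate for Groups 1/2 (max SD over all
#'   conditions, percent).
#' @param low_glucose_sd_max SD threshold at low glucose that forces
#'   Group 4 (percent).
#' @param low_glucose_mgdl Which target glucose counts as "low" (default
#'   40 mg/dL).
#' @param expected_conditions Tibble of conditions every device should
#'   cover (default [default_conditions()]); missing ones are flagged in
#'   the rationale, not penalized.
#' @return Tibble: `device_model`, `group` (ordered factor 1-4),
#'   `cost_tier`, `rationale`.
#' @export
rank_devices <- function(summaries, bands = NULL, cost_config = NULL,
                         sd_max = 10, low_glucose_sd_max = 15,
                         low_glucose_mgdl = 40,
                         expected_conditions = default_conditions()) {
  if (nrow(summaries) == 0) {
    warn("No summaries supplied; nothing to rank.")
    return(tibble::tibble(device_model = character(), group = factor(),
                          cost_tier = character(), rationale = character()))
  }
  if (is.null(bands)) {
    bands <- dplyr::mutate(
      dplyr::select(summaries, "device_model", "target_hct", "target_glucose",
                    "mean_percent_bias"),
      band = classify_band(.data$mean_percent_bias)
    )
  }
  costs <- .normalize_cost_config(cost_config)

  per_dev <- summaries |>
    dplyr::left_join(dplyr::select(bands, "device_model", "target_hct",
                                   "target_glucose", "band"),
                     by = c("device_model", "target_hct", "target_glucose")) |>
    dplyr::group_by(.data$device_model) |>
    dplyr::summarise(
      n_conditions = dplyr::n(),
      any_red = any(.data$band == "red", na.rm = TRUE),
      any_orange = any(.data$band == "orange", na.rm = TRUE),
      max_sd = suppressWarnings(max(.data$sd_percent, na.rm = TRUE)),
      low_sd = suppressWarnings(
        max(.data$sd_percent[.data$target_glucose == low_glucose_mgdl], na.rm = TRUE)
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      max_sd = dplyr::if_else(is.infinite(.data$max_sd), NA_real_, .data$max_sd),
      low_sd = dplyr::if_else(is.infinite(.data$low_sd), NA_real_, .data$low_sd)
    )

  n_expected <- nrow(expected_conditions)

  res <- per_dev |>
    dplyr::left_join(costs, by = "device_model") |>
    dplyr::mutate(cost_tier = dplyr::coalesce(.data$cost_tier, "unknown")) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      group = .assign_group(.data$any_red, .data$any_orange, .data$max_sd,
                            .data$low_sd, .data$cost_tier, sd_max,
                            low_glucose_sd_max),
      rationale = .group_rationale(.data$group, .data$any_red, .data$any_orange,
                                   .data$max_sd, .data$low_sd, .data$cost_tier,
                                   sd_max, low_glucose_sd_max,
                                   .data$n_conditions, n_expected)
    ) |>
    dplyr::ungroup()

  res |>
    dplyr::transmute(
      device_model = .data$device_model,
      group = factor(.data$group, levels = 1:4, ordered = TRUE),
      cost_tier = .data$cost_tier,
      rationale = .data$rationale
    ) |>
    dplyr::arrange(.data$group, .data$device_model)
}

.normalize_cost_config <- function(cost_config) {
  if (is.null(cost_config)) {
    return(tibble::tibble(device_model = character(), cost_tier = character()))
  }
  if (is.character(cost_config) && length(cost_config) == 1 && file.exists(cost_config)) {
    cfg <- yaml::read_yaml(cost_config)
    cost_config <- unlist(cfg$cost_tiers %||% cfg)
  }
  if (is.data.frame(cost_config)) {
    out <- tibble::as_tibble(cost_config[, c("device_model", "cost_tier")])
  } else {
    out <- tibble::tibble(device_model = names(cost_config),
                          cost_tier = unname(cost_config))
  }
  bad <- setdiff(unique(out$cost_tier), .cost_tiers)
  if (length(bad) > 0) {
    abort(sprintf("Unknown cost tier(s): %s (expected %s)",
                  paste(bad, collapse = ", "), paste(.cost_tiers, collapse = ", ")))
  }
  out
}

.assign_group <- function(any_red, any_orange, max_sd, low_sd, cost_tier,
                          sd_max, low_glucose_sd_max) {
  if (any_red || (!is.na(low_sd) && low_sd > low_glucose_sd_max)) return(4L)
  if (any_orange) return(3L)
  if (!is.na(max_sd) && max_sd > sd_max) return(3L)
  if (cost_tier %in% c("exceeds_2_3x", "exceeds_20x")) return(1L)
  2L
}

.group_rationale <- function(group, any_red, any_orange, max_sd, low_sd,
                             cost_tier, sd_max, low_glucose_sd_max,
                             n_conditions, n_expected) {
  why <- switch(as.character(group),
    "4" = if (any_red) "at least one condition with |mean bias| > 15% (red)"
          else sprintf("SD at low glucose %.1f%% exceeds %.0f%%", low_sd, low_glucose_sd_max),
    "3" = if (any_orange) "at least one condition with |mean bias| in (8, 15]% (orange)"
          else sprintf("max SD %.1f%% exceeds precision gate %.0f%%", max_sd, sd_max),
    "2" = sprintf("all conditions green, max SD %.1f%%, cost tier %s", max_sd, cost_tier),
    "1" = sprintf("all conditions green, max SD %.1f%%, high consumable cost (%s)",
                  max_sd, cost_tier)
  )
  if (n_conditions < n_expected) {
    why <- sprintf("%s [only %d/%d conditions observed]", why, n_conditions, n_expected)
  }
  why
}
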
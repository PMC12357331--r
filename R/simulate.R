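# Parametric simulator of the bench study: a panel of blood conditions
# (hematocrit x glucose strata over several donor days), replicate
# reference-analyzer readings, and per-device meter readings generated from
# a known device profile. Because the ground truth is known, the simulator
# drives parameter-recovery and end-to-end null tests of the whole
# pipeline.
#
# Randomness: one seeded base-R generator. simulate_study() seeds once with
# design$seed and draws in documented order (panel glucose jitter, panel
# hematocrit jitter, reference replicates, then per device in the order the
# profiles are given: reading noise then error indicators). The stand-alone
# stage functions seed deterministically from design$seed with fixed
# offsets so each stage is reproducible in isolation.

#' Define a simulated study design
#'
#' Defaults mirror the bench protocol: six hematocrit x glucose strata
#' (18/40/55% x 40/150 mg/dL), five replicates per day per condition, and
#' day-to-day jitter of the realized levels (it is not possible to prepare
#' identical samples on different donor days). Reference replicate scatter
#' defaults to a 1% relative SD, consistent with an analyzer held to a
#' +/-5% linearity specification.
#'
#' @param conditions Tibble of `target_hct`, `target_glucose` rows
#'   (default [default_conditions()]).
#' @param days Number of donor days (default 6).
#' @param replicates_per_day Replicates per day per condition (default 5).
#' @param reference_sigma_pct Relative SD of reference replicates, percent.
#' @param hct_jitter_sd Day-to-day SD of realized hematocrit, percentage
#'   points (default 2).
#' @param glucose_jitter_sd Day-to-day SD of realized glucose, mg/dL
#'   (default 5).
#' @param seed Integer seed governing the whole simulation.
#' @return A `study_design` list.
#' @export
study_design <- function(conditions = default_conditions(), days = 6,
                         replicates_per_day = 5, reference_sigma_pct = 1,
                         hct_jitter_sd = 2, glucose_jitter_sd = 5, seed = 1L) {
  stopifnot(is.data.frame(conditions),
            all(c("target_hct", "target_glucose") %in% names(conditions)))
  .assert_scalar_number(days, "days", min = 1)
  .assert_scalar_number(replicates_per_day, "replicates_per_day", min = 1)
  .assert_scalar_number(reference_sigma_pct, "reference_sigma_pct", min = 0)
  .assert_scalar_number(hct_jitter_sd, "hct_jitter_sd", min = 0)
  .assert_scalar_number(glucose_jitter_sd, "glucose_jitter_sd", min = 0)
  .assert_scalar_number(seed, "seed")
  structure(
    list(
      conditions = dplyr::mutate(tibble::as_tibble(conditions),
                                 dplyr::across(dplyr::everything(), as.numeric)),
      days = as.integer(days),
      replicates_per_day = as.integer(replicates_per_day),
      reference_sigma_pct = reference_sigma_pct,
      hct_jitter_sd = hct_jitter_sd,
      glucose_jitter_sd = glucose_jitter_sd,
      seed = as.integer(seed)
    ),
    class = "study_design"
  )
}

#' Define a simulated device profile
#'
#' The generative model for one meter model:
#' * expected reading = true glucose x
#'   `(1 + (base_bias_pct + hct_coeff_pct_per_hct * (true_hct - 40)) / 100)`
#'   — a constant relative bias plus a linear hematocrit interference
#'   centered on a normal adult hematocrit of 40%;
#' * reading noise is Gaussian on the percent-deviation scale — `sigma_*`
#'   is the SD of the reading's percent deviation from the true glucose —
#'   interpolated linearly in true glucose between `sigma_low_pct`
#'   (anchored at 40 mg/dL) and `sigma_high_pct` (at 150 mg/dL),
#'   reproducing the commonly observed loss of precision at low glucose;
#' * with probability `error_rate` a replicate becomes a device-error
#'   record (error code `"E-1"`, no reading);
#' * readings below `display_floor` become `"lo"` error records, the way
#'   meters report an under-range result;
#' * `reads_mmol = TRUE` devices report `value / 18` with unit `mmol/L`.
#'
#' @param device_model Device name.
#' @param base_bias_pct Signed relative bias, percent.
#' @param hct_coeff_pct_per_hct Bias change per hematocrit point away from
#'   40%, percent per point.
#' @param sigma_low_pct,sigma_high_pct Relative SD (percent) at 40 and
#'   150 mg/dL.
#' @param error_rate Probability a replicate yields a device error.
#' @param reads_mmol Whether the device reports mmol/L.
#' @param display_floor Lowest displayable value, mg/dL, or `NULL`.
#' @param cost_tier Consumable cost tier (config input; see
#'   [rank_devices()]).
#' @return A `device_profile` list.
#' @export
device_profile <- function(device_model, base_bias_pct = 0,
                           hct_coeff_pct_per_hct = 0, sigma_low_pct = 0,
                           sigma_high_pct = 0, error_rate = 0,
                           reads_mmol = FALSE, display_floor = NULL,
                           cost_tier = "unknown") {
  stopifnot(is.character(device_model), length(device_model) == 1)
  .assert_scalar_number(sigma_low_pct, "sigma_low_pct", min = 0)
  .assert_scalar_number(sigma_high_pct, "sigma_high_pct", min = 0)
  .assert_scalar_number(error_rate, "error_rate", min = 0)
  if (error_rate > 1) abort("`error_rate` must be a probability in [0, 1].")
  if (!cost_tier %in% .cost_tiers) {
    abort(sprintf("`cost_tier` must be one of %s.", paste(.cost_tiers, collapse = ", ")))
  }
  structure(
    list(
      device_model = device_model,
      base_bias_pct = base_bias_pct,
      hct_coeff_pct_per_hct = hct_coeff_pct_per_hct,
      sigma_low_pct = sigma_low_pct,
      sigma_high_pct = sigma_high_pct,
      error_rate = error_rate,
      reads_mmol = isTRUE(reads_mmol),
      display_floor = display_floor,
      cost_tier = cost_tier
    ),
    class = "device_profile"
  )
}

# ---- internal, unseeded stage implementations -----------------------------

.sim_panel <- function(design) {
  grid <- tidyr::expand_grid(
    day = seq_len(design$days),
    design$conditions
  )
  n <- nrow(grid)
  true_glucose <- grid$target_glucose + rnorm(n, 0, design$glucose_jitter_sd)
  true_hct <- grid$target_hct + rnorm(n, 0, design$hct_jitter_sd)
  tibble::tibble(
    day_id = sprintf("day%03d", grid$day),
    target_hct = grid$target_hct,
    target_glucose = grid$target_glucose,
    true_glucose = pmax(true_glucose, 10),
    true_hct = pmin(pmax(true_hct, 5), 70)
  )
}

.sim_reference <- function(panel, design) {
  reps <- tidyr::expand_grid(
    panel,
    replicate = seq_len(design$replicates_per_day)
  )
  reps$reference <- reps$true_glucose *
    (1 + rnorm(nrow(reps), 0, design$reference_sigma_pct / 100))
  reps$reference <- pmax(reps$reference, 0)
  dplyr::select(reps, "day_id", "target_hct", "target_glucose", "replicate",
                "true_glucose", "true_hct", "reference")
}

.device_sigma_pct <- function(profile, glucose) {
  slope <- (profile$sigma_high_pct - profile$sigma_low_pct) / (150 - 40)
  pmax(profile$sigma_low_pct + slope * (glucose - 40), 0)
}

.sim_device <- function(panel, reference, profile, design) {
  d <- reference  # one row per (day, condition, replicate)
  bias_pct <- profile$base_bias_pct +
    profile$hct_coeff_pct_per_hct * (d$true_hct - 40)
  sigma <- .device_sigma_pct(profile, d$true_glucose)
  # noise is expressed directly on the percent-deviation scale (relative to
  # the true glucose), so sigma_*_pct is the SD of the percent deviation the
  # pipeline should recover
  dev_pct <- bias_pct + rnorm(nrow(d), 0, sigma)
  reading <- pmax(d$true_glucose * (1 + dev_pct / 100), 0)
  is_err <- runif(nrow(d)) < profile$error_rate
  error_code <- rep(NA_character_, nrow(d))
  error_code[is_err] <- "E-1"
  if (!is.null(profile$display_floor)) {
    lo <- !is_err & reading < profile$display_floor
    error_code[lo] <- "lo"
    is_err <- is_err | lo
  }
  reading[is_err] <- NA_real_
  unit <- rep("mg/dL", nrow(d))
  if (profile$reads_mmol) {
    reading <- reading / 18
    unit[] <- "mmol/L"
  }
  tibble::tibble(
    device_model = profile$device_model,
    device_unit_id = "U1",
    strip_lot = "L1",
    day_id = d$day_id,
    target_hct = d$target_hct,
    target_glucose = d$target_glucose,
    measured_hct = d$true_hct,
    replicate = as.integer(d$replicate),
    reading = reading,
    reading_unit = unit,
    reference = d$reference,
    error_code = error_code,
    user_error = FALSE
  )
}

# ---- exported, seeded stage functions -------------------------------------

#' Simulate the realized condition panel
#'
#' Draws, per (day, condition), the realized true glucose and hematocrit:
#' target plus Gaussian day-to-day jitter, truncated to physiologic bounds
#' (glucose >= 10 mg/dL, hematocrit in \\[5, 70\\]%). Deterministic given
#' `design$seed`.
#'
#' @param design A [study_design()].
#' @return Tibble with `day_id`, targets, `true_glucose`, `true_hct`.
#' @export
simulate_panel <- function(design) {
  set.seed(design$seed)
  .sim_panel(design)
}

#' Simulate reference-analyzer replicates
#'
#' Draws `replicates_per_day` reference readings per (day, condition):
#' Gaussian around the realized true glucose with relative SD
#' `reference_sigma_pct`.
#'
#' @param panel Output of [simulate_panel()].
#' @param design The [study_design()].
#' @return Tibble with one row per (day, condition, replicate).
#' @export
simulate_reference <- function(panel, design) {
  set.seed(design$seed + 1L)
  .sim_reference(panel, design)
}

#' Simulate one device's measurement records
#'
#' Applies the device's generative model (see [device_profile()]) to every
#' reference replicate and returns canonical measurement records ready for
#' [compute_deviations()] et al.
#'
#' @param panel Output of [simulate_panel()] (kept for interface symmetry;
#'   realized levels are carried on `reference`).
#' @param reference Output of [simulate_reference()].
#' @param profile A [device_profile()].
#' @param design The [study_design()].
#' @param seed Seed for this device's draws; defaults to a fixed offset of
#'   `design$seed`.
#' @return Canonical measurement tibble.
#' @export
simulate_device <- function(panel, reference, profile, design,
                            seed = design$seed + 2L) {
  set.seed(seed)
  .sim_device(panel, reference, profile, design)
}

#' Simulate a complete study
#'
#' Seeds once with `design$seed` and draws, in documented order, the
#' condition panel, the reference replicates, and each device's readings
#' (in the order profiles are supplied, one noise vector then one
#' error-indicator vector per device). Rerunning with the same design and
#' profiles is bit-identical.
#'
#' @param design A [study_design()].
#' @param profiles List of [device_profile()]s.
#' @return List with `records` (all devices, canonical columns), `panel`,
#'   `reference`, `design`, `profiles`.
#' @export
#' @examples
#' des <- study_design(days = 2, seed = 7)
#' sim <- simulate_study(des, list(device_profile("null-meter")))
#' head(sim$records)
simulate_study <- function(design, profiles) {
  if (inherits(profiles, "device_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1)
  set.seed(design$seed)
  panel <- .sim_panel(design)
  reference <- .sim_reference(panel, design)
  records <- purrr::map(profiles, function(p) .sim_device(panel, reference, p, design)) |>
    purrr::list_rbind()
  list(records = records, panel = panel, reference = reference,
       design = design, profiles = profiles)
}

# ---- manifest + profile presets -------------------------------------------

#' Write the simulation ground-truth manifest
#'
#' Serializes every generative parameter (design, seed, device profiles) to
#' JSON so a dataset can be regenerated bit-identically and recovery tests
#' know the injected truth.
#'
#' @param profiles List of [device_profile()]s.
#' @param design The [study_design()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_manifest <- function(profiles, design, path) {
  if (inherits(profiles, "device_profile")) profiles <- list(profiles)
  manifest <- list(
    seed = design$seed,
    design = list(
      conditions = design$conditions,
      days = design$days,
      replicates_per_day = design$replicates_per_day,
      reference_sigma_pct = design$reference_sigma_pct,
      hct_jitter_sd = design$hct_jitter_sd,
      glucose_jitter_sd = design$glucose_jitter_sd
    ),
    profiles = purrr::map(profiles, function(p) p[!vapply(p, is.null, logical(1))])
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a simulation manifest back
#'
#' Rejects manifests without a seed: without it the dataset cannot be
#' reproduced and recovery tests are meaningless.
#'
#' @param path Manifest JSON path.
#' @return List with `design` (a `study_design`) and `profiles` (list of
#'   `device_profile`s).
#' @export
read_truth_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  if (is.null(m$seed)) abort("Manifest has no `seed`; refusing to load.")
  design <- study_design(
    conditions = tibble::as_tibble(m$design$conditions),
    days = m$design$days,
    replicates_per_day = m$design$replicates_per_day,
    reference_sigma_pct = m$design$reference_sigma_pct,
    hct_jitter_sd = m$design$hct_jitter_sd,
    glucose_jitter_sd = m$design$glucose_jitter_sd,
    seed = m$seed
  )
  profs <- m$profiles
  if (is.data.frame(profs)) profs <- split(profs, seq_len(nrow(profs)))
  profiles <- purrr::map(profs, function(p) {
    p <- as.list(p)
    device_profile(
      device_model = p$device_model,
      base_bias_pct = p$base_bias_pct %||% 0,
      hct_coeff_pct_per_hct = p$hct_coeff_pct_per_hct %||% 0,
      sigma_low_pct = p$sigma_low_pct %||% 0,
      sigma_high_pct = p$sigma_high_pct %||% 0,
      error_rate = p$error_rate %||% 0,
      reads_mmol = isTRUE(p$reads_mmol),
      display_floor = if (is.null(p$display_floor) || is.na(p$display_floor)) NULL else p$display_floor,
      cost_tier = p$cost_tier %||% "unknown"
    )
  })
  names(profiles) <- NULL
  list(design = design, profiles = profiles)
}

#' Load device profiles from a YAML file
#'
#' @param path YAML file with a top-level `profiles` list whose entries are
#'   [device_profile()] fields; defaults to the shipped preset file.
#' @return List of `device_profile`s.
#' @export
load_device_profiles <- function(path = NULL) {
  path <- path %||% system.file("extdata", "device_profiles_synthetic.yaml",
                                package = "glucobench", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  purrr::map(cfg$profiles, function(p) {
    device_profile(
      device_model = p$device_model,
      base_bias_pct = p$base_bias_pct %||% 0,
      hct_coeff_pct_per_hct = p$hct_coeff_pct_per_hct %||% 0,
      sigma_low_pct = p$sigma_low_pct %||% 0,
      sigma_high_pct = p$sigma_high_pct %||% 0,
      error_rate = p$error_rate %||% 0,
      reads_mmol = isTRUE(p$reads_mmol),
      display_floor = p$display_floor,
      cost_tier = p$cost_tier %||% "unknown"
    )
  })
}

#' Shipped synthetic demo profiles
#'
#' Eleven device profiles whose *qualitative* behavior (sign of bias,
#' hematocrit sensitivity, low-glucose precision, error rates, reporting
#' unit, cost tier) mimics the spread of meters one sees on such a bench
#' panel. These are synthetic demo parameters, **not** measured
#' characteristics of any real product.
#'
#' @return List of `device_profile`s.
#' @export
preset_device_profiles <- function() {
  load_device_profiles()
}
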
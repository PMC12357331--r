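test_that("panel realizes targets exactly when jitter is zero, and is seed-deterministic", {
  des0 <- study_design(days = 3, hct_jitter_sd = 0, glucose_jitter_sd = 0, seed = 71)
  p0 <- simulate_panel(des0)
  expect_equal(p0$true_glucose, p0$target_glucose)
  expect_equal(p0$true_hct, p0$target_hct)

  des <- study_design(days = 5, seed = 72)
  expect_identical(simulate_panel(des), simulate_panel(des))
  expect_false(identical(simulate_panel(des),
                         simulate_panel(study_design(days = 5, seed = 73))))
  # physiologic truncation
  lowg <- study_design(days = 50, glucose_jitter_sd = 40, seed = 74)
  expect_true(all(simulate_panel(lowg)$true_glucose >= 10))
})

test_that("panel jitter SDs are recovered at 100 days", {
  des <- study_design(days = 100, hct_jitter_sd = 2, glucose_jitter_sd = 5, seed = 75)
  p <- simulate_panel(des)
  hct_dev <- p$true_hct - p$target_hct
  glu_dev <- p$true_glucose - p$target_glucose
  expect_lt(abs(sd(hct_dev) - 2) / 2, 0.2)
  expect_lt(abs(sd(glu_dev) - 5) / 5, 0.2)
})

test_that("reference replicates scatter as configured and are unbiased", {
  des <- study_design(days = 60, reference_sigma_pct = 1, seed = 76)
  p <- simulate_panel(des)
  r <- simulate_reference(p, des)
  rel <- r$reference / r$true_glucose - 1
  expect_lt(abs(sd(rel) * 100 - 1), 0.1)
  expect_lt(abs(mean(rel)) * 100, 0.1)

  des0 <- study_design(days = 2, reference_sigma_pct = 0, seed = 77)
  p0 <- simulate_panel(des0)
  r0 <- simulate_reference(p0, des0)
  expect_equal(r0$reference, r0$true_glucose)
})

test_that("a pure-bias device yields exactly its bias when reference noise is zero", {
  des <- study_design(days = 3, reference_sigma_pct = 0, seed = 78)
  sim <- simulate_study(des, list(device_profile("b10", base_bias_pct = -10)))
  dev <- compute_deviations(sim$records)
  expect_equal(dev$percent_deviation, rep(-10, nrow(dev)), tolerance = 1e-12)
})

test_that("device error rates, display floor and mmol reporting behave as modeled", {
  des <- study_design(days = 60, seed = 79)
  profile <- device_profile("erratic", error_rate = 0.033, reads_mmol = TRUE,
                            display_floor = 20, sigma_low_pct = 15, sigma_high_pct = 5)
  sim <- simulate_study(des, list(profile))
  recs <- sim$records
  n <- nrow(recs)
  expect_true(all(xor(is.na(recs$reading), is.na(recs$error_code))))
  expect_true(all(recs$reading_unit == "mmol/L"))
  # error-code rate within 3 binomial SDs of the generative rate (floor adds few)
  n_err <- sum(recs$error_code == "E-1", na.rm = TRUE)
  expect_lt(abs(n_err / n - 0.033), 3 * sqrt(0.033 * 0.967 / n))
  # "lo" floor errors occur at the low-glucose strata of this imprecise meter
  expect_true(any(recs$error_code == "lo" & recs$target_glucose == 40, na.rm = TRUE))
  # converting the mmol readings back gives mg/dL-scale values
  std <- standardize_units(recs)
  expect_equal(std$reading, recs$reading * 18)

  # tally_errors recovers the generative rate
  tal <- tally_errors(recs)
  p_hat <- (tal$n_device_errors - sum(recs$error_code == "lo", na.rm = TRUE)) /
    (tal$n_valid + tal$n_device_errors)
  expect_lt(abs(p_hat - 0.033), 3 * sqrt(0.033 * 0.967 / n))
})

test_that("simulate_study is bit-identical under one seed, and stages draw in order", {
  des <- study_design(days = 4, seed = 80)
  profs <- list(device_profile("a", base_bias_pct = 2, sigma_low_pct = 5,
                               sigma_high_pct = 3),
                device_profile("b", base_bias_pct = -4, sigma_low_pct = 8,
                               sigma_high_pct = 4))
  s1 <- simulate_study(des, profs)
  s2 <- simulate_study(des, profs)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$panel, s2$panel)
})

test_that("the truth manifest round-trips and refuses to load without a seed", {
  des <- study_design(days = 4, seed = 81)
  profs <- list(device_profile("a", base_bias_pct = 2, cost_tier = "meets_TPP"),
                device_profile("b", reads_mmol = TRUE, display_floor = 20,
                               error_rate = 0.05))
  f <- withr::local_tempfile(fileext = ".json")
  write_truth_manifest(profs, des, f)
  back <- read_truth_manifest(f)
  expect_equal(back$design, des)
  expect_equal(back$profiles, profs)
  # dataset regenerated from the manifest is bit-identical
  expect_identical(simulate_study(des, profs)$records,
                   simulate_study(back$design, back$profiles)$records)

  m <- jsonlite::read_json(f)
  m$seed <- NULL
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(m, f2, auto_unbox = TRUE)
  expect_error(read_truth_manifest(f2), "seed")
})

test_that("shipped synthetic profiles load and drive the full pipeline", {
  profs <- preset_device_profiles()
  expect_length(profs, 11)
  expect_true(all(vapply(profs, inherits, logical(1), "device_profile")))
  des <- study_design(days = 2, seed = 82)
  sim <- simulate_study(des, profs)
  res <- analyze_study(sim$records,
                       cost_config = tibble::tibble(
                         device_model = vapply(profs, `[[`, "", "device_model"),
                         cost_tier = vapply(profs, `[[`, "", "cost_tier")))
  expect_equal(sort(unique(res$summary$device_model)),
               sort(vapply(profs, `[[`, "", "device_model")))
  expect_s3_class(res$ranking, "tbl_df")
})

test_that("noise interpolation in glucose matches the two anchors", {
  p <- device_profile("x", sigma_low_pct = 12, sigma_high_pct = 4)
  expect_equal(glucobench:::.device_sigma_pct(p, c(40, 150)), c(12, 4))
  expect_equal(glucobench:::.device_sigma_pct(p, 95), 8)
  # never negative when extrapolating
  expect_gte(glucobench:::.device_sigma_pct(p, 400), 0)
})
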
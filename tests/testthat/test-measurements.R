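test_that("CSV read/write round-trips field-for-field and keeps units untouched", {
  recs <- dplyr::bind_rows(
    make_records("meterA"),
    make_records("meterB-mmol", reading = c(2.1, 2.2, 2.0, 2.3, 2.2),
                 reading_unit = "mmol/L"),
    make_records("meterA", day_id = "d2", user_error = c(TRUE, FALSE, FALSE, FALSE, FALSE))
  )
  f <- withr::local_tempfile(fileext = ".csv")
  write_measurements(recs, f)
  back <- read_measurements(f)
  expect_equal(tibble::as_tibble(back), recs, ignore_attr = TRUE)
  expect_equal(attr(back, "parse_log")$n_rejected, 0)
  # mmol/L rows come back with their original unit and value at read time
  expect_true(all(back$reading_unit[back$device_model == "meterB-mmol"] == "mmol/L"))

  # second write of the re-read table is byte-identical (canonical order)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_measurements(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("row invariant violations are rejected with line numbers, not fatal", {
  recs <- make_records(reading = c(40, 40, 40, 40, 40))
  recs$error_code[2] <- "E-1"           # both reading and error code
  recs$reading[4] <- NA_real_           # neither
  f <- withr::local_tempfile(fileext = ".csv")
  write_measurements(recs, f)
  got <- read_measurements(f)
  expect_equal(nrow(got), 3)
  rej <- attr(got, "rejected")
  expect_equal(rej$line, c(3L, 5L))   # header is line 1
  expect_match(rej$reason[1], "both reading and error_code")
  expect_match(rej$reason[2], "neither reading nor error_code")
})

test_that("missing required columns and unknown units are fatal", {
  recs <- make_records()
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::select(recs, -"reference"), f)
  expect_error(read_measurements(f), "reference")

  recs$reading_unit[3] <- "g/L"
  f2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(recs, f2)
  expect_error(read_measurements(f2), "Unknown reading unit")
})

test_that("schema config remaps foreign column names", {
  recs <- make_records()
  foreign <- dplyr::rename(recs, meter = "device_model", glucose = "reading")
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(foreign, f)
  got <- read_measurements(f, schema_config = list(device_model = "meter",
                                                   reading = "glucose"))
  expect_equal(got$device_model, recs$device_model)
  expect_equal(got$reading, recs$reading)
  expect_error(read_measurements(f, schema_config = list(nonsense = "meter")),
               "Unknown canonical column")
})

test_that("unit conversions follow the x18 and x1.11 formulas and reject negatives", {
  expect_equal(convert_to_mgdl(1.0), 18.0)
  expect_equal(convert_to_mgdl(0), 0)
  expect_equal(convert_to_mgdl(2.2), 39.6)
  expect_error(convert_to_mgdl(-0.1), "non-negative")

  expect_equal(plasma_equivalent(100), 111)
  expect_equal(plasma_equivalent(0), 0)
  expect_equal(plasma_equivalent(40), 44.4)
  expect_error(plasma_equivalent(-1), "non-negative")

  # linearity of the unit conversion
  a <- runif(20, 0, 30); b <- runif(20, 0, 30)
  expect_equal(convert_to_mgdl(a + b), convert_to_mgdl(a) + convert_to_mgdl(b))

  # standardize_units is idempotent and only touches mmol/L rows
  recs <- make_records(reading_unit = c("mmol/L", rep("mg/dL", 4)))
  std <- standardize_units(recs)
  expect_equal(std$reading[1], recs$reading[1] * 18)
  expect_equal(std$reading[-1], recs$reading[-1])
  expect_identical(standardize_units(std), std)
})

test_that("error tallies use the valid+errors denominator and ignore user errors", {
  recs <- dplyr::bind_rows(
    make_tally_records("clean", 10, 0),
    make_tally_records("faulty", 96, 4)
  )
  # user-error rows must be invisible to the tally
  ue <- make_records("faulty", day_id = "d9", reading = rep(NA_real_, 3),
                     error_code = "E-1", replicate = 1:3, user_error = TRUE)
  tal <- tally_errors(dplyr::bind_rows(recs, ue))
  expect_equal(tal$error_rate_pct[tal$device_model == "clean"], 0.0)
  expect_equal(tal$n_valid[tal$device_model == "faulty"], 96)
  expect_equal(tal$n_device_errors[tal$device_model == "faulty"], 4)
  expect_equal(tal$error_rate_pct[tal$device_model == "faulty"], 4.0)

  # order invariance
  shuffled <- recs[sample(nrow(recs)), ]
  expect_equal(tally_errors(shuffled), tally_errors(recs))
})
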
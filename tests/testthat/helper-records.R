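# Builders for canonical measurement tibbles used across tests.

make_records <- function(device_model = "meterX", day_id = "d1",
                         target_hct = 40, target_glucose = 40,
                         replicate = seq_along(reading),
                         reading = c(38, 41, 40, 39, 42),
                         reading_unit = "mg/dL",
                         reference = 40, error_code = NA_character_,
                         user_error = FALSE, measured_hct = target_hct,
                         device_unit_id = "U1", strip_lot = "L1") {
  tibble::tibble(
    device_model = device_model, device_unit_id = device_unit_id,
    strip_lot = strip_lot, day_id = day_id,
    target_hct = target_hct, target_glucose = target_glucose,
    measured_hct = measured_hct, replicate = as.integer(replicate),
    reading = reading, reading_unit = reading_unit, reference = reference,
    error_code = error_code, user_error = user_error
  )
}

# n_valid readings + n_err device-error rows for one device
make_tally_records <- function(device, n_valid, n_err, code = "E-1") {
  make_records(
    device_model = device,
    reading = c(rep(100, n_valid), rep(NA_real_, n_err)),
    error_code = c(rep(NA_character_, n_valid), rep(code, n_err)),
    replicate = seq_len(n_valid + n_err),
    reference = 100, target_glucose = 100
  )
}
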
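#' Read paired glucometer/reference measurements from CSV
#'
#' Reads a long-format measurement table in which every row is one meter
#' reading (or meter error) paired with its reference-analyzer value, day,
#' condition stratum and replicate index. Column names can be remapped with
#' `schema_config` so foreign exports can be ingested without editing the
#' file.
#'
#' Row-level validation enforces the record invariants:
#' * exactly one of `reading` / `error_code` is present,
#' * `reading_unit` is `mg/dL` or `mmol/L` (any other string is fatal),
#' * `replicate` is a positive integer,
#' * `measured_hct` (when present) lies in (0, 100),
#' * numeric glucose values are non-negative.
#'
#' Rows that violate an invariant are rejected (with their file line number)
#' and reported in the parse log; rows flagged `user_error = TRUE` are kept
#' in the returned table so drop decisions stay auditable, but every
#' downstream stage ignores them. Readings are returned in their original
#' unit; conversion to mg/dL happens in [standardize_units()] /
#' [compute_deviations()].
#'
#' @param path Path to a UTF-8 CSV file.
#' @param schema_config Optional column map: a named list (or a YAML/JSON
#'   file containing one, under key `columns`) mapping canonical column
#'   names to the names used in the file, e.g.
#'   `list(device_model = "meter", reading = "glucose_mgdl")`.
#' @param log_path Optional path; when given, the parse log is written there
#'   as JSON.
#' @return A tibble of validated records in canonical column order, with
#'   attributes `parse_log` (list) and `rejected` (tibble of rejected rows
#'   with `line` and `reason`).
#' @seealso [write_measurements()], [tally_errors()]
#' @export
read_measurements <- function(path, schema_config = NULL, log_path = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  colmap <- .load_schema_config(schema_config)

  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  # apply column map: canonical <- file name
  for (canon in names(colmap)) {
    from <- colmap[[canon]]
    if (!from %in% names(raw)) {
      abort(sprintf("Mapped column `%s` (for `%s`) not found in %s", from, canon, path))
    }
    names(raw)[names(raw) == from] <- canon
  }

  missing <- setdiff(.required_cols, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("Missing required column(s): %s", paste(missing, collapse = ", ")))
  }
  # optional columns get defaults
  if (!"device_unit_id" %in% names(raw)) raw$device_unit_id <- "1"
  if (!"strip_lot" %in% names(raw)) raw$strip_lot <- NA_character_
  if (!"measured_hct" %in% names(raw)) raw$measured_hct <- NA_character_
  if (!"error_code" %in% names(raw)) raw$error_code <- NA_character_
  if (!"user_error" %in% names(raw)) raw$user_error <- "FALSE"

  units_seen <- unique(raw$reading_unit[!is.na(raw$reading_unit)])
  bad_units <- setdiff(units_seen, .valid_units)
  if (length(bad_units) > 0) {
    abort(sprintf("Unknown reading unit string(s): %s (expected mg/dL or mmol/L)",
                  paste(bad_units, collapse = ", ")))
  }

  parsed <- tibble::tibble(
    device_model = raw$device_model,
    device_unit_id = raw$device_unit_id,
    strip_lot = raw$strip_lot,
    day_id = raw$day_id,
    target_hct = suppressWarnings(as.numeric(raw$target_hct)),
    target_glucose = suppressWarnings(as.numeric(raw$target_glucose)),
    measured_hct = suppressWarnings(as.numeric(raw$measured_hct)),
    replicate = suppressWarnings(as.integer(raw$replicate)),
    reading = suppressWarnings(as.numeric(raw$reading)),
    reading_unit = raw$reading_unit,
    reference = suppressWarnings(as.numeric(raw$reference)),
    error_code = dplyr::if_else(is.na(raw$error_code) | raw$error_code == "",
                                NA_character_, raw$error_code),
    user_error = toupper(trimws(raw$user_error)) %in% c("TRUE", "T", "1", "YES")
  )

  reason <- .row_violation(parsed)
  keep <- is.na(reason)
  rejected <- tibble::tibble(
    line = which(!keep) + 1L,  # header is line 1
    reason = reason[!keep]
  )
  records <- parsed[keep, .canonical_cols]

  log <- list(
    source = path,
    n_rows = nrow(parsed),
    n_records = nrow(records),
    n_rejected = nrow(rejected),
    n_user_error = sum(records$user_error),
    rejected = rejected
  )
  if (!is.null(log_path)) {
    jsonlite::write_json(log, log_path, auto_unbox = TRUE, digits = NA)
  }
  attr(records, "parse_log") <- log
  attr(records, "rejected") <- rejected
  records
}

# one reason string per row, NA when the row is valid
.row_violation <- function(d) {
  reason <- rep(NA_character_, nrow(d))
  flag <- function(cond, msg) {
    hit <- cond & is.na(reason)
    reason[hit] <<- msg
  }
  has_reading <- !is.na(d$reading)
  has_error <- !is.na(d$error_code)
  flag(has_reading & has_error, "both reading and error_code present")
  flag(!has_reading & !has_error, "neither reading nor error_code present")
  flag(is.na(d$device_model) | d$device_model == "", "missing device_model")
  flag(is.na(d$day_id) | d$day_id == "", "missing day_id")
  flag(is.na(d$target_hct) | d$target_hct <= 0 | d$target_hct >= 100,
       "target_hct not a percent in (0, 100)")
  flag(is.na(d$target_glucose) | d$target_glucose <= 0, "target_glucose not positive")
  flag(is.na(d$replicate) | d$replicate < 1L, "replicate index must be >= 1")
  flag(has_reading & d$reading < 0, "negative reading")
  flag(!is.na(d$reference) & d$reference < 0, "negative reference")
  flag(!is.na(d$measured_hct) & (d$measured_hct <= 0 | d$measured_hct >= 100),
       "measured_hct not a percent in (0, 100)")
  reason
}

.load_schema_config <- function(schema_config) {
  if (is.null(schema_config)) return(list())
  if (is.character(schema_config) && length(schema_config) == 1) {
    cfg <- if (grepl("\\.json$", schema_config, ignore.case = TRUE)) {
      jsonlite::read_json(schema_config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(schema_config)
    }
    schema_config <- cfg$columns %||% cfg
  }
  if (!is.list(schema_config)) abort("`schema_config` must be a named list or a config file path.")
  unknown <- setdiff(names(schema_config), .canonical_cols)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown canonical column(s) in schema config: %s",
                  paste(unknown, collapse = ", ")))
  }
  schema_config
}

#' Write measurements to canonical CSV
#'
#' Writes the canonical column order used by [read_measurements()], so a
#' read/write cycle reproduces the file field-for-field.
#'
#' @param records Measurement tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  missing <- setdiff(.canonical_cols, names(records))
  if (length(missing) > 0) {
    abort(sprintf("Records are missing column(s): %s", paste(missing, collapse = ", ")))
  }
  readr::write_csv(records[, .canonical_cols], path, na = "")
  invisible(path)
}

#' Tally device errors per meter model
#'
#' Counts, per device model, the valid readings and the device-reported
#' errors (error codes such as faulty-strip/cuvette codes or a `lo`
#' under-range display). User-error rows never enter the tally: an operator
#' mistake is repeated or dropped, not held against the instrument. The
#' error rate uses valid + errors as denominator and is rounded to one
#' decimal, matching how such rates are conventionally reported.
#'
#' @param records Measurement tibble.
#' @return Tibble with `device_model`, `n_valid`, `n_device_errors`,
#'   `error_rate_pct` (one decimal; `NA` when a device contributed no
#'   rows at all).
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   device_model = "meterA", device_unit_id = "1", strip_lot = NA,
#'   day_id = "d1", target_hct = 40, target_glucose = 40, measured_hct = 40,
#'   replicate = 1:5, reading = c(38, 41, NA, 40, 39),
#'   reading_unit = "mg/dL", reference = 40,
#'   error_code = c(NA, NA, "E-1", NA, NA), user_error = FALSE
#' )
#' tally_errors(recs)
tally_errors <- function(records) {
  records |>
    dplyr::filter(!.data$user_error) |>
    dplyr::group_by(.data$device_model) |>
    dplyr::summarise(
      n_valid = sum(!is.na(.data$reading)),
      n_device_errors = sum(!is.na(.data$error_code)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      error_rate_pct = dplyr::if_else(
        .data$n_valid + .data$n_device_errors > 0,
        round(100 * .data$n_device_errors / (.data$n_valid + .data$n_device_errors), 1),
        NA_real_
      )
    ) |>
    dplyr::arrange(.data$device_model)
}
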
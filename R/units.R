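#' Convert glucose from mmol/L to mg/dL
#'
#' Meters configured for SI units report mmol/L; all pipeline statistics are
#' computed in mg/dL using the conventional conversion mg/dL = mmol/L x 18.
#'
#' @param value Numeric vector of glucose concentrations in mmol/L; must be
#'   non-negative.
#' @return Numeric vector in mg/dL.
#' @export
#' @examples
#' convert_to_mgdl(2.2) # 39.6
convert_to_mgdl <- function(value) {
  if (!is.numeric(value)) abort("`value` must be numeric.")
  if (any(value < 0, na.rm = TRUE)) {
    abort("Glucose concentrations must be non-negative.")
  }
  value * 18
}

#' Whole-blood to plasma-equivalent glucose
#'
#' Many strip meters measure whole-blood glucose and scale by 1.11 to report
#' a plasma-equivalent value; the factor assumes a normal adult hematocrit.
#' Provided as a standalone utility only — the analysis pipeline never
#' applies it, because meters and the reference analyzer both already report
#' plasma-equivalent values.
#'
#' @param whole_blood_glucose Numeric vector, mg/dL; must be non-negative.
#' @return Plasma-equivalent glucose, mg/dL.
#' @export
#' @examples
#' plasma_equivalent(100) # 111
plasma_equivalent <- function(whole_blood_glucose) {
  if (!is.numeric(whole_blood_glucose)) abort("`whole_blood_glucose` must be numeric.")
  if (any(whole_blood_glucose < 0, na.rm = TRUE)) {
    abort("Glucose concentrations must be non-negative.")
  }
  whole_blood_glucose * 1.11
}

#' Standardize measurement readings to mg/dL
#'
#' Converts every `mmol/L` reading to mg/dL (x 18) and rewrites
#' `reading_unit` accordingly. Reference values are always mg/dL and are not
#' touched. Idempotent.
#'
#' @param records Measurement tibble (see [read_measurements()]).
#' @return The same tibble with all readings in mg/dL.
#' @export
standardize_units <- function(records) {
  bad <- setdiff(unique(records$reading_unit), .valid_units)
  if (length(bad) > 0) {
    abort(sprintf("Unknown reading unit(s): %s", paste(bad, collapse = ", ")))
  }
  is_mmol <- records$reading_unit == "mmol/L"
  records$reading[is_mmol] <- convert_to_mgdl(records$reading[is_mmol])
  records$reading_unit[is_mmol] <- "mg/dL"
  records
}
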
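#' @importFrom rlang %||% .data abort warn
#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils head tail
NULL

# Canonical long-format column order for measurement tables. Kept in one
# place so read/write round-trips are field-for-field identical.
.canonical_cols <- c(
  "device_model", "device_unit_id", "strip_lot", "day_id",
  "target_hct", "target_glucose", "measured_hct", "replicate",
  "reading", "reading_unit", "reference", "error_code", "user_error"
)

.required_cols <- c(
  "device_model", "day_id", "target_hct", "target_glucose",
  "replicate", "reading", "reading_unit", "reference"
)

.valid_units <- c("mg/dL", "mmol/L")

#' Default study conditions
#'
#' The hematocrit x glucose strata of the neonatal-range bench protocol:
#' hematocrit targets of 18, 40 and 55% crossed with glucose targets of
#' 40 and 150 mg/dL.
#'
#' @return A tibble with columns `target_hct` (percent) and
#'   `target_glucose` (mg/dL), one row per condition (six by default).
#' @export
#' @examples
#' default_conditions()
default_conditions <- function() {
  tidyr::expand_grid(target_hct = c(18, 40, 55), target_glucose = c(40, 150))
}

#' Label a condition stratum
#'
#' @param target_hct Hematocrit target, percent.
#' @param target_glucose Glucose target, mg/dL.
#' @return Character vector like `"Hct 18% / 40 mg/dL"`.
#' @export
condition_label <- function(target_hct, target_glucose) {
  sprintf("Hct %g%% / %g mg/dL", target_hct, target_glucose)
}

.assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (x < min) {
    abort(sprintf("`%s` must be >= %g (got %g).", name, min, x))
  }
  invisible(x)
}
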
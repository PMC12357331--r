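Package: glucobench
Title: Stratified Method-Comparison Analysis for Point-of-Care Glucometers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Evaluation pipeline for point-of-care blood-glucose meters
    benchmarked against a laboratory reference analyzer across hematocrit
    and glucose strata. Builds per-day reference truth from replicate
    analyzer readings, computes mean percent bias, mean absolute relative
    difference (MARD), precision and 95% limits of agreement per device and
    condition, classifies results against TPP/CLIA (+/-8%), ISO 15197:2015
    (+/-15%) and ISO 15197:2003 (+/-20%) accuracy bands, performs Parkes
    consensus error-grid zoning, tallies device errors, and ranks devices by
    accuracy, precision and consumable cost. Includes a parametric study
    simulator (device bias, hematocrit sensitivity, glucose-dependent
    precision, error rates) so the whole pipeline is testable with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    mgcv,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
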
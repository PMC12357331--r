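# Figures and the report bundle. Figures follow the conventional layouts
# for this kind of bench comparison: a per-condition deviation chart with
# the +/-8% and +/-15% guideline lines, a MARD panel, and the error grid
# with condition averages.

#' Deviation band chart
#'
#' Percent deviation of every reading against its condition stratum, one
#' facet per device, colored by the device-condition accuracy band, with
#' dashed guideline lines at +/-8% and +/-15%.
#'
#' @param deviations Tibble from [compute_deviations()].
#' @param bands Tibble from [summarize_bands()]; recomputed when omitted.
#' @return A ggplot object.
#' @export
plot_deviation_bands <- function(deviations, bands = NULL) {
  if (is.null(bands)) bands <- summarize_bands(deviations)
  d <- deviations |>
    dplyr::left_join(
      dplyr::select(bands, "device_model", "target_hct", "target_glucose", "band"),
      by = c("device_model", "target_hct", "target_glucose")
    ) |>
    dplyr::mutate(condition = condition_label(.data$target_hct, .data$target_glucose))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$percent_deviation,
                                  colour = .data$band)) +
    ggplot2::geom_hline(yintercept = c(-15, -8, 8, 15), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(green = "#2e7d32", orange = "#ef6c00", red = "#c62828"),
      drop = FALSE
    ) +
    ggplot2::facet_wrap(~device_model) +
    ggplot2::labs(x = NULL, y = "Deviation from reference average (%)",
                  colour = "Mean-bias band") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' MARD panel
#'
#' Mean absolute relative difference per condition, one facet per device.
#'
#' @param summaries Tibble from [summarize_accuracy()].
#' @return A ggplot object.
#' @export
plot_mard <- function(summaries) {
  d <- dplyr::mutate(summaries,
                     condition = condition_label(.data$target_hct, .data$target_glucose))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$mard)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~device_model) +
    ggplot2::labs(x = NULL, y = "MARD (%)") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Error-grid figure
#'
#' Zone boundaries of the grid with the per-condition average points
#' (+/-1 SD vertical bars) overlaid.
#'
#' @param zone_results Tibble from [classify_condition_averages()].
#' @param zones The `zone_polygon_set` used for classification.
#' @param xlim,ylim Plot range, mg/dL (default the full domain).
#' @return A ggplot object.
#' @export
plot_error_grid <- function(zone_results, zones = parkes_zones(),
                            xlim = NULL, ylim = NULL) {
  dom <- zones$domain
  xlim <- xlim %||% dom
  ylim <- ylim %||% dom
  boundaries <- purrr::imap(zones$zones, function(poly, lab) {
    tibble::tibble(zone = lab, x = c(poly[, 1], poly[1, 1]),
                   y = c(poly[, 2], poly[1, 2]))
  }) |>
    purrr::list_rbind() |>
    dplyr::filter(.data$zone != "E")
  ggplot2::ggplot() +
    ggplot2::geom_path(data = boundaries,
                       ggplot2::aes(x = .data$x, y = .data$y, group = .data$zone),
                       colour = "grey55", linewidth = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "black") +
    ggplot2::geom_errorbar(
      data = zone_results,
      ggplot2::aes(x = .data$reference, ymin = .data$meter_sd_low,
                   ymax = .data$meter_sd_high, colour = .data$device_model),
      width = 0
    ) +
    ggplot2::geom_point(
      data = zone_results,
      ggplot2::aes(x = .data$reference, y = .data$meter,
                   colour = .data$device_model,
                   shape = as.character(.data$zone))
    ) +
    ggplot2::coord_cartesian(xlim = xlim, ylim = ylim) +
    ggplot2::labs(x = "Reference glucose (mg/dL)", y = "Meter glucose (mg/dL)",
                  colour = "Device", shape = "Zone") +
    ggplot2::theme_bw()
}

#' Render the report bundle
#'
#' Writes the analysis artifacts of a [analyze_study()] result to a
#' directory: CSV tables (accuracy summary, bands, zone results, error
#' tallies, drift report, ranking when present), PNG figures (deviation
#' band chart, MARD panel, error grid), and a markdown summary. Missing
#' components produce a partial bundle with a notice in the summary rather
#' than an error. Tables are written with full precision so a rerun on the
#' same input is byte-identical.
#'
#' @param results A `gluc_analysis` list (or any list with the same
#'   element names).
#' @param out_dir Output directory (created if needed).
#' @param figures Whether to write PNG figures (default `TRUE`).
#' @return Invisibly, a character vector of written paths.
#' @export
render_report <- function(results, out_dir, figures = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  notices <- character()

  tables <- list(
    accuracy_summary = results$summary,
    bands = results$bands,
    zone_results = results$zone_results,
    error_tallies = results$tallies,
    drift_report = results$drift,
    ranking = results$ranking
  )
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    if (is.null(tab)) {
      notices <- c(notices, sprintf("Component `%s` missing; table skipped.", nm))
      next
    }
    path <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(tab, path)
    written <- c(written, path)
  }

  if (figures) {
    figs <- list()
    if (!is.null(results$deviations)) {
      figs$deviation_bands <- plot_deviation_bands(results$deviations, results$bands)
    }
    if (!is.null(results$summary)) figs$mard <- plot_mard(results$summary)
    if (!is.null(results$zone_results)) {
      figs$error_grid <- plot_error_grid(results$zone_results)
    }
    skipped <- setdiff(c("deviation_bands", "mard", "error_grid"), names(figs))
    if (length(skipped) > 0) {
      notices <- c(notices, sprintf("Figure(s) skipped (missing inputs): %s",
                                    paste(skipped, collapse = ", ")))
    }
    for (nm in names(figs)) {
      path <- file.path(out_dir, paste0(nm, ".png"))
      ok <- tryCatch({
        ggplot2::ggsave(path, figs[[nm]], width = 9, height = 6, dpi = 150)
        TRUE
      }, error = function(e) FALSE)
      if (ok) written <- c(written, path)
      else notices <- c(notices, sprintf("Could not write figure %s (no graphics device?).", nm))
    }
  }

  md <- c(
    "# Glucometer evaluation report",
    "",
    sprintf("Generated by glucobench %s.",
            as.character(utils::packageVersion("glucobench"))),
    ""
  )
  if (!is.null(results$ranking)) {
    md <- c(md, "## Device ranking (Groups 1-4)", "",
            "The grouping rule is a documented reconstruction combining",
            "accuracy bands, precision gates and consumable cost tiers;",
            "see `?rank_devices`.", "",
            sprintf("- Group %s: %s", results$ranking$group,
                    paste0(results$ranking$device_model, " (",
                           results$ranking$rationale, ")")),
            "")
  }
  if (!is.null(results$tallies)) {
    md <- c(md, "## Device errors", "",
            sprintf("- %s: %d valid, %d errors (%s%%)",
                    results$tallies$device_model, results$tallies$n_valid,
                    results$tallies$n_device_errors,
                    ifelse(is.na(results$tallies$error_rate_pct), "NA",
                           format(results$tallies$error_rate_pct))),
            "")
  }
  if (length(notices) > 0) {
    md <- c(md, "## Notices", "", paste0("- ", notices), "")
  }
  md_path <- file.path(out_dir, "summary.md")
  writeLines(md, md_path)
  written <- c(written, md_path)
  invisible(written)
}
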
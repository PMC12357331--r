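# Parkes (consensus) error grid, Type 1 diabetes variant.
#
# The grid grades the clinical consequence of a meter error by locating the
# (reference, meter) pair in risk zones A-E. Zones are stored as NESTED
# cumulative polygons over the [0, 550] mg/dL square: polygon "A" is zone A
# itself, polygon "B" is the region of risk B *or better*, and so on, with
# "E" the whole domain. A point's zone is the first (safest) polygon that
# contains it; points on a shared boundary therefore resolve to the
# lower-risk zone, and every in-domain point receives exactly one label.
#
# The breakpoint coordinates are the published Type-1 consensus values
# (Pfuetzner and colleagues' tabulation of the Parkes grid); they are not
# re-derived here and can be overridden via load_zone_polygons().

.parkes_type1_vertices <- function() {
  list(
    A = matrix(c(
      0, 0,   0, 50,   30, 50,   140, 170,  280, 380,  430, 550,
      550, 550, 550, 450, 385, 300, 170, 145, 50, 30,  50, 0
    ), ncol = 2, byrow = TRUE),
    B = matrix(c(
      0, 0,   0, 60,   30, 60,   50, 80,   70, 110,   260, 550,
      550, 550, 550, 250, 260, 130, 120, 30, 120, 0
    ), ncol = 2, byrow = TRUE),
    C = matrix(c(
      0, 0,   0, 100,  25, 100,  50, 125,  80, 215,   125, 550,
      550, 550, 550, 150, 250, 40, 250, 0
    ), ncol = 2, byrow = TRUE),
    D = matrix(c(
      0, 0,   0, 150,  35, 155,  50, 550,  550, 550,  550, 0
    ), ncol = 2, byrow = TRUE),
    E = matrix(c(
      0, 0,   0, 550,  550, 550, 550, 0
    ), ncol = 2, byrow = TRUE)
  )
}

#' Parkes Type-1 consensus error grid
#'
#' Returns the default zone polygon set: the published consensus
#' breakpoints for Type 1 diabetes, on a `[0, 550]` mg/dL domain
#' (reference on x, meter on y). The identity line lies entirely in
#' zone A.
#'
#' @return A `zone_polygon_set`: list with `grid_name`, `domain`
#'   (`c(0, 550)`), and `zones` — a named list of cumulative polygons
#'   (two-column vertex matrices) for A, B, C, D, E, where polygon K is
#'   the region of risk K or better.
#' @export
#' @examples
#' grid <- parkes_zones()
#' classify_points(c(40, 150), c(40, 280), grid)
parkes_zones <- function() {
  zs <- structure(
    list(
      grid_name = "Parkes consensus error grid (Type 1 diabetes)",
      domain = c(0, 550),
      zones = .parkes_type1_vertices()
    ),
    class = "zone_polygon_set"
  )
  zs
}

#' Load (and validate) an error-grid zone configuration
#'
#' Reads a YAML or JSON zone definition of the form produced in
#' `inst/extdata/parkes_type1_zones.yaml`: `grid_name`, `domain`
#' (two numbers), and `zones`, a list of `{zone: <label>, vertices:
#' [[x, y], ...]}` entries ordered safest-first, each polygon cumulative
#' ("this risk or better"). The loaded set is validated: zone labels must
#' be an initial-ordered subset of A-E ending in a polygon that covers the
#' whole domain, the identity line must classify entirely as zone A, and
#' polygon membership must be nested (monotone) on a coverage lattice.
#'
#' @param path Path to a YAML/JSON zone file; the shipped Parkes Type-1
#'   file when omitted.
#' @param lattice_step Grid step (mg/dL) for the validation lattice.
#' @return A validated `zone_polygon_set`.
#' @export
load_zone_polygons <- function(path = NULL, lattice_step = 10) {
  path <- path %||% system.file("extdata", "parkes_type1_zones.yaml",
                                package = "glucobench", mustWork = TRUE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$zones) || is.null(cfg$domain)) {
    abort("Zone config must supply `domain` and `zones`.")
  }
  zones <- list()
  for (z in cfg$zones) {
    verts <- z$vertices
    if (is.list(verts)) verts <- do.call(rbind, lapply(verts, unlist))
    verts <- matrix(as.numeric(verts), ncol = 2)
    zones[[z$zone]] <- verts
  }
  zs <- structure(
    list(
      grid_name = cfg$grid_name %||% basename(path),
      domain = as.numeric(cfg$domain),
      zones = zones
    ),
    class = "zone_polygon_set"
  )
  validate_zone_set(zs, lattice_step = lattice_step)
  zs
}

#' Validate a zone polygon set
#'
#' Checks the structural invariants of a cumulative zone set: labels are an
#' initial run of A-E in order; the last polygon covers the whole domain
#' (so the zones partition it); membership is nested across zones on a
#' coverage lattice; and the identity line classifies entirely as zone A.
#' Any violation is fatal.
#'
#' @param zones A `zone_polygon_set`.
#' @param lattice_step Lattice step in mg/dL for the coverage check.
#' @return `zones`, invisibly, if valid.
#' @export
validate_zone_set <- function(zones, lattice_step = 10) {
  labels <- names(zones$zones)
  expected <- c("A", "B", "C", "D", "E")
  if (length(labels) < 2 || !identical(labels, expected[seq_along(labels)])) {
    abort(sprintf(
      "Zone labels must be an initial ordered run of A-E; got: %s",
      paste(labels, collapse = ", ")
    ))
  }
  dom <- zones$domain
  g <- seq(dom[1], dom[2], by = lattice_step)
  lat <- tidyr::expand_grid(x = g, y = g)
  member <- vapply(zones$zones,
                   function(p) .point_in_polygon(lat$x, lat$y, p),
                   logical(nrow(lat)))
  if (!all(member[, ncol(member)])) {
    abort("Outermost zone polygon does not cover the domain: zones leave gaps.")
  }
  # nesting: membership in zone k implies membership in all later zones
  for (k in seq_len(ncol(member) - 1)) {
    if (any(member[, k] & !member[, k + 1])) {
      abort(sprintf("Zone polygons are not nested: some points in %s are outside %s.",
                    labels[k], labels[k + 1]))
    }
  }
  ident <- seq(dom[1], dom[2], length.out = 251)
  if (!all(classify_points(ident, ident, zones) == "A")) {
    abort("Identity line is not entirely in zone A.")
  }
  invisible(zones)
}

# Vectorized even-odd point-in-polygon with explicit on-boundary detection;
# boundary points count as inside (combined with safest-first zone order
# this yields the lower-risk tie-break).
.point_in_polygon <- function(px, py, poly, tol = 1e-9) {
  n <- length(px)
  nv <- nrow(poly)
  inside <- rep(FALSE, n)
  on_edge <- rep(FALSE, n)
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    seg_len <- sqrt((xj - xi)^2 + (yj - yi)^2)
    if (seg_len > 0) {
      cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
      on_seg <- abs(cross) / seg_len <= tol &
        px >= pmin(xi, xj) - tol & px <= pmax(xi, xj) + tol &
        py >= pmin(yi, yj) - tol & py <= pmax(yi, yj) + tol
      on_edge <- on_edge | on_seg
      crosses <- ((yi > py) != (yj > py))
      if (any(crosses)) {
        xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
        inside <- xor(inside, crosses & (px < xint))
      }
    }
    j <- i
  }
  inside | on_edge
}

#' Classify (reference, meter) pairs into error-grid zones
#'
#' Assigns each pair the first (safest) cumulative zone polygon containing
#' it; points on a zone boundary therefore resolve to the lower-risk zone.
#' Out-of-domain points are a domain error.
#'
#' @param reference Reference glucose values, mg/dL.
#' @param meter Meter glucose values, mg/dL (same length).
#' @param zones A `zone_polygon_set` (default [parkes_zones()]).
#' @return Ordered factor of zone labels (A < B < C < D < E).
#' @export
#' @examples
#' classify_points(40, 44) # within-10% point at low glucose: zone A
classify_points <- function(reference, meter, zones = parkes_zones()) {
  if (length(reference) != length(meter)) {
    abort("`reference` and `meter` must have the same length.")
  }
  dom <- zones$domain
  bad <- is.na(reference) | is.na(meter) |
    reference < dom[1] | reference > dom[2] | meter < dom[1] | meter > dom[2]
  if (any(bad)) {
    abort(sprintf("%d point(s) outside the grid domain [%g, %g] (or missing).",
                  sum(bad), dom[1], dom[2]))
  }
  labels <- names(zones$zones)
  out <- rep(NA_character_, length(reference))
  remaining <- rep(TRUE, length(reference))
  for (k in seq_along(labels)) {
    if (!any(remaining)) break
    hit <- remaining
    hit[remaining] <- .point_in_polygon(reference[remaining], meter[remaining],
                                        zones$zones[[k]])
    out[hit] <- labels[k]
    remaining <- remaining & !hit
  }
  if (any(is.na(out))) {
    abort("Some points fell outside every zone polygon; invalid zone set.")
  }
  factor(out, levels = c("A", "B", "C", "D", "E"), ordered = TRUE)
}

#' Error-grid zones of per-condition device averages
#'
#' Places each device's per-condition average point — mean reference value
#' on x, mean meter value on y — on the error grid, the way condition-level
#' summaries are conventionally displayed. Also emits the +/-1 SD meter
#' interval (in mg/dL, from the percent SD scaled by the mean reference)
#' for plotting. Meter averages beyond the grid domain are clamped to it
#' with a warning; rows with missing averages are skipped with a warning.
#'
#' @param summaries Tibble from [summarize_accuracy()].
#' @param zones A `zone_polygon_set`.
#' @return Tibble with one row per (device, condition): the plotted point,
#'   its `zone`, and `meter_sd_low` / `meter_sd_high`.
#' @export
classify_condition_averages <- function(summaries, zones = parkes_zones()) {
  need <- c("device_model", "target_hct", "target_glucose",
            "mean_meter", "mean_reference", "sd_percent")
  missing <- setdiff(need, names(summaries))
  if (length(missing) > 0) {
    abort(sprintf("`summaries` is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  ok <- !is.na(summaries$mean_meter) & !is.na(summaries$mean_reference)
  if (any(!ok)) {
    warn(sprintf("Skipping %d summary row(s) with missing averages.", sum(!ok)))
  }
  s <- summaries[ok, ]
  dom <- zones$domain
  clamped <- s$mean_meter < dom[1] | s$mean_meter > dom[2]
  if (any(clamped)) {
    warn(sprintf("Clamped %d meter average(s) to the grid domain [%g, %g].",
                 sum(clamped), dom[1], dom[2]))
  }
  meter <- pmin(pmax(s$mean_meter, dom[1]), dom[2])
  sd_mgdl <- s$mean_reference * s$sd_percent / 100
  tibble::tibble(
    device_model = s$device_model,
    target_hct = s$target_hct,
    target_glucose = s$target_glucose,
    reference = s$mean_reference,
    meter = meter,
    zone = classify_points(s$mean_reference, meter, zones),
    meter_sd_low = meter - sd_mgdl,
    meter_sd_high = meter + sd_mgdl
  )
}
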
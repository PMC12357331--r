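test_that("identity line and near-identity points at low glucose are zone A", {
  g <- parkes_zones()
  id <- seq(0, 550, by = 1)
  expect_true(all(classify_points(id, id, g) == "A"))
  expect_equal(as.character(classify_points(c(40, 40, 40), c(40, 44, 36), g)),
               c("A", "A", "A"))
})

test_that("classification matches the independent point-in-polygon oracle", {
  g <- parkes_zones()
  set.seed(51)
  ref <- runif(2000, 0, 550)
  met <- runif(2000, 0, 550)
  mine <- as.character(classify_points(ref, met, g))
  theirs <- oracle_zone(ref, met, g)
  expect_equal(mine, theirs)
  # frozen spot checks (oracle-verified): large positive error at 150 is B
  expect_equal(as.character(classify_points(150, 280, g)), "B")
  expect_equal(oracle_zone(150, 280, g), "B")
})

test_that("every lattice point gets exactly one zone and membership is nested", {
  g <- parkes_zones()
  lat <- tidyr::expand_grid(x = seq(0, 550, by = 5), y = seq(0, 550, by = 5))
  z <- classify_points(lat$x, lat$y, g)   # errors if any point were unlabeled
  expect_false(anyNA(z))
  member <- vapply(g$zones, function(p) glucobench:::.point_in_polygon(lat$x, lat$y, p),
                   logical(nrow(lat)))
  for (k in 1:4) expect_true(all(!member[, k] | member[, k + 1]))
  # the assigned zone is the first containing polygon
  first <- colnames(member)[apply(member, 1, which.max)]
  expect_equal(as.character(z), first)
})

test_that("zone risk is monotone along vertical rays", {
  g <- parkes_zones()
  set.seed(52)
  for (ref in c(20, 40, 90, 150, 300, 500)) {
    ys <- seq(0, 550, by = 5)
    z <- classify_points(rep(ref, length(ys)), ys, g)
    a_band <- which(z == "A")
    # above the A band, risk never decreases with distance; below, likewise
    above <- z[ys > ys[max(a_band)]]
    below <- rev(z[ys < ys[min(a_band)]])
    expect_true(all(diff(as.integer(above)) >= 0))
    expect_true(all(diff(as.integer(below)) >= 0))
  }
})

test_that("out-of-domain points are a domain error", {
  g <- parkes_zones()
  expect_error(classify_points(600, 100, g), "outside the grid domain")
  expect_error(classify_points(100, -1, g), "outside the grid domain")
  expect_error(classify_points(NA, 100, g), "outside the grid domain")
})

test_that("the shipped YAML config loads, validates, and equals the code default", {
  zs <- load_zone_polygons()
  expect_identical(zs$zones, parkes_zones()$zones)
  expect_identical(zs$domain, c(0, 550))
})

test_that("a config with a zone removed fails validation at load time", {
  cfg <- yaml::read_yaml(system.file("extdata", "parkes_type1_zones.yaml",
                                     package = "glucobench"))
  cfg$zones <- cfg$zones[-5]  # drop E: remaining zones leave gaps
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, f)
  expect_error(load_zone_polygons(f), "gaps|cover")

  cfg2 <- yaml::read_yaml(system.file("extdata", "parkes_type1_zones.yaml",
                                      package = "glucobench"))
  cfg2$zones <- cfg2$zones[c(2, 1, 3, 4, 5)]  # out of order
  f2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg2, f2)
  expect_error(load_zone_polygons(f2), "initial ordered run")
})

test_that("condition averages are zoned; biased-but-moderate devices stay in A", {
  des <- study_design(days = 3, reference_sigma_pct = 0, seed = 53)
  sim <- simulate_study(des, list(
    device_profile("null"),
    device_profile("minus10", base_bias_pct = -10),
    device_profile("plus60", base_bias_pct = 60)
  ))
  res <- analyze_study(sim$records)
  zr <- res$zone_results
  expect_equal(nrow(zr), 18)
  expect_true(all(zr$zone[zr$device_model == "null"] == "A"))
  # a uniform -10% bias stays within zone A at these levels (oracle-checked)
  m10 <- dplyr::filter(zr, device_model == "minus10")
  expect_equal(as.character(m10$zone), oracle_zone(m10$reference, m10$meter))
  expect_true(all(m10$zone == "A"))
  # +60% at the high-glucose conditions leaves zone A (oracle-checked)
  p60 <- dplyr::filter(zr, device_model == "plus60", target_glucose == 150)
  expect_equal(as.character(p60$zone), oracle_zone(p60$reference, p60$meter))
  expect_true(all(p60$zone >= "B"))
})

test_that("meter averages beyond the domain are clamped with a warning", {
  summ <- tibble::tibble(device_model = "x", target_hct = 40, target_glucose = 150,
                         mean_meter = 600, mean_reference = 150, sd_percent = 5)
  expect_warning(zr <- classify_condition_averages(summ), "Clamped")
  expect_equal(zr$meter, 550)
})
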
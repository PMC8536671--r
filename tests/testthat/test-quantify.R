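fake_objects <- function(diam_um, x = NULL, y = NULL, cal = calibration()) {
  n <- length(diam_um)
  area <- pi * (diam_um / 2)^2
  data.frame(
    fov_id = rep("t", n), object_id = seq_len(n),
    pixel_count = as.integer(round(area / cal$pixel_size_um^2)),
    area_um2 = area,
    centroid_x_um = if (is.null(x)) rep(10, n) else x,
    centroid_y_um = if (is.null(y)) rep(10, n) else y,
    equivalent_diameter_um = diam_um,
    touches_left = rep(FALSE, n), touches_right = rep(FALSE, n),
    touches_top = rep(FALSE, n), touches_bottom = rep(FALSE, n),
    depth_um = if (is.null(y)) rep(10, n) else y,
    stringsAsFactors = FALSE
  )
}

test_that("FOV summaries implement the five parameters and zero rules", {
  cal <- calibration()
  empty <- summarize_fov(fake_objects(numeric(0)), cal, "FPS")
  expect_identical(empty$count, 0L)
  expect_equal(empty$area_fraction_pct, 0)
  expect_true(is.na(empty$mean_diameter_um))
  expect_true(is.na(empty$min_diameter_um))
  expect_true(is.na(empty$max_diameter_um))

  two <- summarize_fov(fake_objects(c(6, 10)), cal, "FPS")
  expect_equal(two$mean_diameter_um, 8)
  expect_equal(two$min_diameter_um, 6)
  expect_equal(two$max_diameter_um, 10)

  # objects totalling 2000 um^2 in a 0.2 mm^2 field occupy 1%
  ob <- fake_objects(c(6, 10))
  ob$area_um2 <- c(800, 1200)
  expect_equal(summarize_fov(ob, cal, "FPS")$area_fraction_pct, 1)
})

test_that("HD thickness estimator is area over centre-line length", {
  rect <- cbind(c(0, 200, 200, 0), c(0, 0, 100, 100))
  line <- cbind(c(0, 200), c(50, 50))
  expect_equal(estimate_hd_thickness(rect, line), 100)

  # trapezoid, parallel sides 40 and 60 um deep over a 300 um run:
  # shoelace area = 300 * (40 + 60) / 2 = 15000 um^2
  trap <- cbind(c(0, 300, 300, 0), c(0, 0, 60, 40))
  cl <- cbind(c(0, 300), c(25, 25))
  expect_equal(estimate_hd_thickness(trap, cl), 50)

  degenerate <- cbind(c(0, 100, 200), c(0, 0, 0))
  expect_equal(estimate_hd_thickness(degenerate, line), 0)
  expect_error(estimate_hd_thickness(rect, cbind(c(5, 5), c(1, 1))),
               "zero length")
})

test_that("zone assignment follows the inclusive depth rule", {
  cal <- calibration()
  fps <- zone_partition("FPS", cal)
  ob <- fake_objects(c(8, 8, 8), y = c(99, 101, 100))
  z <- assign_zones(ob, fps)
  expect_identical(z$zone, c("HD", "LD", "HD"))

  sps <- zone_partition("SPS", cal)
  z2 <- assign_zones(fake_objects(8, y = 40.0), sps)
  expect_identical(z2$zone, "HD")

  # neuropil fields have no pial border: everything is LD
  np <- zone_partition("CA4", cal)
  z3 <- assign_zones(fake_objects(c(8, 8), y = c(5, 300)), np)
  expect_identical(z3$zone, c("LD", "LD"))
})

test_that("zone partition conserves area and supports curved borders", {
  cal <- calibration()
  part <- zone_partition("FPS", cal)
  expect_equal(part$hd_area_mm2 + part$ld_area_mm2, cal$fov_area_mm2,
               tolerance = 1e-9)
  expect_error(zone_partition("CA1", cal, hd_depth_um = 40), "neuropil")

  # a sloped border: depth measured to the polyline, not the top edge
  w <- cal$fov_width_px * cal$pixel_size_um
  sloped <- zone_partition("FPS", cal,
                           pial_border = cbind(c(0, w), c(0, 60)))
  z <- assign_zones(fake_objects(8, x = w / 2, y = 40), sloped)
  expect_lt(z$depth_um, 40)
})

test_that("zone summaries compute packing density against zone area", {
  cal <- calibration()
  fps <- zone_partition("FPS", cal)
  ob <- assign_zones(fake_objects(rep(8, 12), y = c(rep(50, 10),
                                                    rep(200, 2))), fps)
  hd <- summarize_zone(ob, fps, "HD")
  expect_identical(hd$count, 10L)
  expect_equal(hd$packing_density_per_mm2, 10 / fps$hd_area_mm2)

  none <- assign_zones(fake_objects(numeric(0)), fps)
  ld <- summarize_zone(none, fps, "LD")
  expect_equal(ld$packing_density_per_mm2, 0)
  expect_true(is.na(ld$mean_diameter_um))

  np <- zone_partition("CA4", cal)
  expect_error(summarize_zone(ob, np, "HD"), "non-positive area")

  # additivity: HD count + LD count equals the FOV count
  expect_identical(hd$count + summarize_zone(ob, fps, "LD")$count,
                   nrow(ob))
})

test_that("HD/LD density ratio is recovered from the generator", {
  cfg <- sim_config(hd_intensity = 300)
  cal <- calibration()
  part <- zone_partition("FPS", cal)
  set.seed(41)
  hd_n <- 0L
  ld_n <- 0L
  for (i in 1:40) {
    sim <- simulate_fov(cfg, cal, "FPS", image = FALSE)
    if (nrow(sim$objects) == 0) next
    ob <- sim$objects
    ob$equivalent_diameter_um <- ob$true_diameter_um
    ob$area_um2 <- pi * (ob$true_diameter_um / 2)^2
    z <- assign_zones(ob, part)
    hd_n <- hd_n + sum(z$zone == "HD")
    ld_n <- ld_n + sum(z$zone == "LD")
  }
  ratio <- (hd_n / part$hd_area_mm2) / (ld_n / part$ld_area_mm2)
  expect_gt(ratio, 10 * 0.6)
  expect_lt(ratio, 10 / 0.6)
})

test_that("compare_zones reports fold changes and t-tests per region", {
  set.seed(52)
  zs <- do.call(rbind, lapply(1:8, function(i) {
    data.frame(section_id = sprintf("S%d", i),
               region = "FPS", zone = c("HD", "LD"),
               packing_density_per_mm2 = c(rnorm(1, 500, 30),
                                           rnorm(1, 50, 10)),
               area_fraction_pct = c(rnorm(1, 4, 0.3),
                                     rnorm(1, 0.4, 0.1)),
               mean_diameter_um = c(9, 9), max_diameter_um = c(15, 13),
               stringsAsFactors = FALSE)
  }))
  # max diameters are constant within both zones: degenerate t flagged
  expect_warning(cz <- compare_zones(zs), "zero pooled")
  dens <- cz[cz$parameter == "packing_density_per_mm2", ]
  expect_equal(dens$fold_change, dens$hd_mean / dens$ld_mean)
  expect_lt(dens$p, 0.001)
  const <- cz[cz$parameter == "mean_diameter_um", ]
  expect_equal(const$p, 1)
})
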
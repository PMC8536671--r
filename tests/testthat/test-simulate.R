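test_that("calibration ties pixel grid to physical area", {
  cal <- calibration()
  expect_equal(cal$fov_area_mm2, 0.2, tolerance = 1e-9)
  expect_equal(cal$pixel_size_um, sqrt(2e5 / 192e4), tolerance = 1e-12)
  cal2 <- calibration(400, 300, 0.5)
  expect_equal(cal2$fov_area_mm2,
               400 * 300 * 0.25 / 1e6, tolerance = 1e-12)
  expect_error(calibration(0, 10), "not TRUE")
})

test_that("sim_config enforces the detectability and diameter contracts", {
  expect_error(sim_config(blob_peak_level = 600), "detectability")
  expect_error(sim_config(diameter_bounds_um = c(2, 30)))
  expect_error(sim_config(diameter_bounds_um = c(3, 40)))
  cfg <- sim_config()
  expect_gt(cfg$blob_peak_level,
            cfg$background_level + 5 * cfg$background_noise_sd)
})

test_that("zero intensity yields an empty field and empty ground truth", {
  cfg <- sim_config(hd_intensity = 0)
  sim <- simulate_fov(cfg, calibration(200L, 150L), "FPS", seed = 7)
  expect_identical(nrow(sim$objects), 0L)
  expect_identical(sim$fov$true_count, 0L)
  expect_equal(sim$fov$true_area_fraction_pct, 0)
  expect_true(all(sim$micrograph$pixels < cfg$blob_peak_level / 2))
})

test_that("identical seed and config give byte-identical images", {
  cfg <- sim_config(hd_intensity = 300)
  cal <- calibration(200L, 150L)
  a <- simulate_fov(cfg, cal, "FPS", seed = 11)
  b <- simulate_fov(cfg, cal, "FPS", seed = 11)
  expect_identical(a$micrograph$pixels, b$micrograph$pixels)
  expect_identical(a$objects, b$objects)
  fa <- tempfile(fileext = ".tif")
  fb <- tempfile(fileext = ".tif")
  write_micrograph(a$micrograph, fa)
  write_micrograph(b$micrograph, fb)
  expect_identical(unname(tools::md5sum(fa)), unname(tools::md5sum(fb)))
})

test_that("HD-band counts follow the Poisson expectation", {
  # 200 count-only FOVs at 500 CoA/mm^2 in a 100 um HD band:
  # expected HD count per field = 500 x 0.05164 mm^2 ~= 25.8
  cfg <- sim_config(hd_intensity = 500)
  cal <- calibration()
  hd_area <- cal$fov_width_px * cal$pixel_size_um * 100 / 1e6
  expected <- 500 * hd_area
  set.seed(101)
  counts <- replicate(200, {
    sim <- simulate_fov(cfg, cal, "FPS", image = FALSE)
    sum(sim$objects$zone == "HD")
  })
  se <- sqrt(expected / 200)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("diameters respect the truncation bounds", {
  cfg <- sim_config(hd_intensity = 500, diameter_bounds_um = c(4, 20))
  sim <- simulate_fov(cfg, calibration(), "FPS", seed = 3, image = FALSE)
  expect_true(all(sim$objects$true_diameter_um >= 4))
  expect_true(all(sim$objects$true_diameter_um <= 20))
})

test_that("hard-core separation is enforced and failure is reported", {
  cfg <- sim_config(hd_intensity = 400, min_separation_um = 15)
  sim <- simulate_fov(cfg, calibration(), "FPS", seed = 5, image = FALSE)
  ob <- sim$objects
  if (nrow(ob) > 1) {
    d <- as.matrix(dist(cbind(ob$centroid_x_um, ob$centroid_y_um)))
    diag(d) <- Inf
    expect_gte(min(d), 15)
  }
  cramped <- sim_config(hd_intensity = 20000, min_separation_um = 60,
                        max_attempts = 10L)
  expect_error(
    simulate_fov(cramped, calibration(), "FPS", seed = 5, image = FALSE),
    "hard-core placement failed.*FPS"
  )
})

test_that("stage targets are interior to bands and decay from the fimbria", {
  expect_true(all(stage_targets(0)$pial == 0))
  t1 <- stage_targets(1)$pial
  expect_gt(t1[["FPS"]], 0)
  expect_lt(t1[["FPS"]], 10)
  expect_true(all(t1[setdiff(names(t1), "FPS")] == 0))
  t2 <- stage_targets(2)$pial
  expect_true(t2[["FPS"]] >= 10 && t2[["FPS"]] < 50)
  for (st in 2:4) {
    tg <- stage_targets(st)$pial
    expect_true(all(tg[["FPS"]] >= tg[setdiff(names(tg), "FPS")]))
    lateral <- tg[c("FPS", "PPS", "SPS", "MPS", "LPS", "CPS")]
    expect_true(all(diff(lateral) <= 0))
  }
  for (st in 3:4) expect_gte(stage_targets(st)$pial[["FPS"]], 50)
  expect_true(stage_targets(4)$deep_wm_phg_fusiform)
  expect_false(stage_targets(3)$deep_wm_phg_fusiform)
})

test_that("simulate_section realises the stage model", {
  cal <- calibration()
  s0 <- simulate_section(sim_config(stage = 0), cal, seed = 21)
  expect_true(all(s0$fovs$true_count == 0))
  expect_identical(s0$section$true_stage, 0L)
  expect_false(s0$section$deep_wm_lv)

  s4 <- simulate_section(sim_config(stage = 4), cal, seed = 22)
  expect_true(s4$section$deep_wm_lv)
  expect_true(s4$section$deep_wm_phg_fusiform)
  # conservation: per-FOV counts sum to the number of object records
  expect_identical(sum(s4$fovs$true_count), nrow(s4$objects))
  # fimbria pial surface dominates every other pial region
  per_region <- tapply(s4$fovs$true_count, s4$fovs$region, sum)
  pial <- per_region[pial_regions()]
  expect_true(all(pial[["FPS"]] >= pial[setdiff(names(pial), "FPS")]))
})

test_that("cohort covariates drive diameters but not densities", {
  cfg <- sim_config(subjects = 12L, fovs_per_region = 2L,
                    age_diameter_slope = 0.08)
  co <- simulate_cohort(cfg, calibration(), seed = 31,
                        stages = rep(2:4, 4))
  expect_identical(nrow(co$sections), 12L)
  expect_setequal(names(co$sections),
                  c("section_id", "true_stage", "deep_wm_lv",
                    "deep_wm_phg_fusiform", "age", "bmi", "sex"))
  # recompute the generating age -> diameter association from ground truth
  mean_d <- vapply(co$sections$section_id, function(sid) {
    mean(co$objects$true_diameter_um[co$objects$section_id == sid])
  }, numeric(1))
  r <- cor(co$sections$age, mean_d, method = "spearman")
  expect_gt(r, 0.5)
})
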
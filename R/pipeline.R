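#' Configure a full analysis run
#'
#' Bundles everything [run_pipeline()] needs: the simulation
#' configuration, the calibration, the detection method, the post hoc gate
#' level and the seed. A configuration can also be loaded from a YAML file
#' whose top-level keys are the arguments of this function (with
#' \code{sim} a mapping of [sim_config()] arguments and
#' \code{calibration} a mapping of [calibration()] arguments).
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed for the whole run.
#' @param sim A [sim_config()].
#' @param calibration A [calibration()].
#' @param detection_method \code{"otsu"} or \code{"fixed"}.
#' @param detection_level Threshold for \code{"fixed"}.
#' @param alpha Levene gate level for post hoc selection.
#' @return List of class \code{coa_run_config}.
#' @export
run_config <- function(out_dir, seed = 1L, sim = sim_config(),
                       calibration = coamap::calibration(),
                       detection_method = "otsu", detection_level = NULL,
                       alpha = 0.05) {
  assert_sim_config(sim)
  assert_calibration(calibration)
  stopifnot(detection_method %in% c("otsu", "fixed"), alpha > 0, alpha < 1)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
         calibration = calibration, detection_method = detection_method,
         detection_level = detection_level, alpha = alpha),
    class = "coa_run_config"
  )
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_config, y$sim %||% list())
  cal <- do.call(calibration, y$calibration %||% list())
  run_config(out_dir = y$out_dir %||% ".",
             seed = y$seed %||% 1L, sim = sim, calibration = cal,
             detection_method = y$detection_method %||% "otsu",
             detection_level = y$detection_level,
             alpha = y$alpha %||% 0.05)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_step <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

## Pool detected objects of one section x region across its FOVs and
## summarise both zones against the pooled zone area.
section_zone_summaries <- function(objects, fovs, calibration, sid,
                                   region, hd_depth_um = NULL) {
  part <- zone_partition(region, calibration, hd_depth_um = hd_depth_um)
  fov_ids <- fovs$fov_id[fovs$section_id == sid & fovs$region == region]
  obj <- objects[objects$fov_id %in% fov_ids, , drop = FALSE]
  obj <- assign_zones(obj, part)
  nf <- length(fov_ids)
  rows <- lapply(c("HD", "LD"), function(z) {
    zs <- summarize_zone(obj, part, z)
    zs$zone_area_mm2 <- zs$zone_area_mm2 * nf
    zs$packing_density_per_mm2 <- zs$count / zs$zone_area_mm2
    zs$area_fraction_pct <- zs$area_fraction_pct / nf
    zs$section_id <- sid
    zs
  })
  do.call(rbind, rows)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes simulate, detect, quantify, stage and stats as one
#' reproducible run: simulates a cohort of sections with rendered
#' micrographs, detects CoA in every field, computes per-FOV and HD/LD
#' zone summaries, classifies stages and ranks the CoA sequence, builds
#' the three correlation grids (ranked sequence, age, BMI) and the HD
#' versus LD comparisons, and writes every table plus a manifest (seed,
#' configuration, row counts, MD5 of each output) to the output
#' directory. Identical configuration and seed give identical outputs.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly; tables are written as CSV under
#'   \code{config$out_dir}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "coa_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  sim <- stage_step("simulate", simulate_cohort(
    config$sim, config$calibration, seed = config$seed, images = TRUE))

  detected <- stage_step("detect", {
    objs <- lapply(sim$micrographs, function(mg) {
      detect(mg, method = config$detection_method,
             level = config$detection_level)
    })
    do.call(rbind, c(objs, list(make.row.names = FALSE)))
  })

  quant <- stage_step("quantify", {
    fov_summaries <- lapply(seq_len(nrow(sim$fovs)), function(i) {
      fid <- sim$fovs$fov_id[i]
      summarize_fov(detected[detected$fov_id == fid, , drop = FALSE],
                    config$calibration, region = sim$fovs$region[i],
                    fov_id = fid, section_id = sim$fovs$section_id[i])
    })
    fov_summaries <- do.call(rbind, c(fov_summaries,
                                      list(make.row.names = FALSE)))
    zone_rows <- list()
    for (sid in sim$sections$section_id) {
      for (region in pial_regions()) {
        zone_rows[[paste(sid, region)]] <- section_zone_summaries(
          detected, sim$fovs, config$calibration, sid, region)
      }
    }
    list(fov_summaries = fov_summaries,
         zone_summaries = do.call(rbind, c(zone_rows,
                                           list(make.row.names = FALSE))))
  })

  stages <- stage_step("stage", {
    profiles <- build_section_profiles(quant$fov_summaries, sim$sections)
    rank_sequence(profiles)
  })

  stats_out <- stage_step("stats", {
    section_params <- summarize_sections(quant$fov_summaries)
    covs <- merge(sim$sections,
                  stages[, c("section_id", "rank")], by = "section_id")
    grids <- rbind(
      build_grid(section_params, covs, "rank"),
      build_grid(section_params, covs, "age"),
      build_grid(section_params, covs, "bmi")
    )
    list(grids = grids, hd_ld = compare_zones(quant$zone_summaries))
  })

  files <- list(
    objects = detected,
    fov_summaries = quant$fov_summaries,
    zone_summaries = quant$zone_summaries,
    stages = stages,
    stats_grid = stats_out$grids,
    hd_ld_tests = stats_out$hd_ld,
    sections = sim$sections
  )
  paths <- character(0)
  for (nm in names(files)) {
    p <- file.path(config$out_dir, paste0(nm, ".csv"))
    write_table_csv(files[[nm]], p)
    paths[nm] <- p
  }
  manifest <- list(
    seed = config$seed,
    alpha = config$alpha,
    detection_method = config$detection_method,
    subjects = config$sim$subjects,
    fovs_per_region = config$sim$fovs_per_region,
    row_counts = lapply(files, nrow),
    md5 = as.list(stats::setNames(tools::md5sum(paths),
                                  basename(paths))),
    r_version = as.character(getRversion())
  )
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Generate a small deterministic fixture corpus
#'
#' Writes one rendered field of view per stage for the fimbria pial
#' surface plus one wall-of-lateral-ventricle field per stage, with exact
#' ground truth and a manifest of MD5 hashes. Fields are rendered at a
#' reduced 400 x 300 px raster (same pixel size as the default
#' calibration) so the corpus stays small; a fixed seed makes it
#' reproducible byte for byte.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @return The manifest (list), invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cal <- calibration(400L, 300L)
  set.seed(seed)
  objects <- list()
  fovs <- list()
  paths <- character(0)
  for (stage in 0:4) {
    tg <- stage_targets(stage)
    px <- cal$pixel_size_um
    w_um <- cal$fov_width_px * px
    h_um <- cal$fov_height_px * px
    for (region in c("FPS", "LV")) {
      cfg <- sim_config(stage = stage)
      if (region == "FPS") {
        depth <- min(cfg$hd_depth_um[["FPS"]], h_um)
        hd_area <- w_um * depth / 1e6
        ld_area <- cal$fov_area_mm2 - hd_area
        # expected count scales with the reduced field area
        cfg$hd_intensity <- tg$pial[["FPS"]] * (cal$fov_area_mm2 / 0.2) /
          (hd_area + cfg$ld_ratio * ld_area)
      } else {
        cfg$hd_intensity <- tg$lv * (cal$fov_area_mm2 / 0.2) /
          (cfg$ld_ratio * cal$fov_area_mm2)
      }
      fid <- sprintf("stage%d_%s", stage, region)
      sim <- simulate_fov(cfg, cal, region, fov_id = fid, image = TRUE)
      p <- file.path(out_dir, paste0(fid, ".tif"))
      write_micrograph(sim$micrograph, p)
      paths <- c(paths, p, paste0(p, ".json"))
      objects[[fid]] <- sim$objects
      fovs[[fid]] <- cbind(sim$fov, data.frame(stage = stage))
    }
  }
  op <- file.path(out_dir, "objects.csv")
  fp <- file.path(out_dir, "fovs.csv")
  write_table_csv(do.call(rbind, c(objects, list(make.row.names = FALSE))),
                  op)
  write_table_csv(do.call(rbind, c(fovs, list(make.row.names = FALSE))),
                  fp)
  paths <- c(paths, op, fp)
  manifest <- list(seed = seed,
                   md5 = as.list(stats::setNames(tools::md5sum(paths),
                                                 basename(paths))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
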
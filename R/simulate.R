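## Truncated lognormal sampler via inverse-CDF; deterministic given the RNG
## stream.
rtrunc_lnorm <- function(n, meanlog, sdlog, bounds) {
  lo <- stats::plnorm(bounds[1], meanlog, sdlog)
  hi <- stats::plnorm(bounds[2], meanlog, sdlog)
  stats::qlnorm(stats::runif(n, lo, hi), meanlog, sdlog)
}

## Sequential hard-core placement: each point is drawn uniformly in its own
## window and rejected while closer than min_sep to any accepted point.
place_hardcore <- function(windows, min_sep, max_attempts, context) {
  n <- nrow(windows)
  xs <- numeric(n)
  ys <- numeric(n)
  if (n == 0L) return(cbind(x = xs, y = ys))
  min_sep2 <- min_sep^2
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in seq_len(max_attempts)) {
      x <- stats::runif(1, windows[i, 1], windows[i, 2])
      y <- stats::runif(1, windows[i, 3], windows[i, 4])
      if (i == 1L) { placed <- TRUE }
      else {
        j <- seq_len(i - 1L)
        placed <- all((xs[j] - x)^2 + (ys[j] - y)^2 >= min_sep2)
      }
      if (placed) { xs[i] <- x; ys[i] <- y; break }
    }
    if (!placed) {
      stop("hard-core placement failed after ", max_attempts,
           " attempts (", context,
           "): intensity too high for min_separation_um = ", min_sep,
           call. = FALSE)
    }
  }
  cbind(x = xs, y = ys)
}

## Pixel indices of a disc: a pixel belongs to the disc iff its centre lies
## within the radius. Returns linear indices into the row-major image matrix
## plus border-touch flags.
rasterize_disc <- function(cx, cy, radius, px, nrow_px, ncol_px) {
  c0 <- max(1L, as.integer(ceiling((cx - radius) / px + 0.5)))
  c1 <- min(ncol_px, as.integer(floor((cx + radius) / px + 0.5)))
  r0 <- max(1L, as.integer(ceiling((cy - radius) / px + 0.5)))
  r1 <- min(nrow_px, as.integer(floor((cy + radius) / px + 0.5)))
  if (c0 > c1 || r0 > r1) {
    return(list(idx = integer(0), rows = integer(0), cols = integer(0)))
  }
  rows <- r0:r1
  cols <- c0:c1
  dy2 <- ((rows - 0.5) * px - cy)^2
  dx2 <- ((cols - 0.5) * px - cx)^2
  inside <- outer(dy2, dx2, "+") <= radius^2
  rr <- rows[row(inside)[inside]]
  cc <- cols[col(inside)[inside]]
  list(idx = rr + (cc - 1L) * nrow_px, rows = rr, cols = cc)
}

empty_objects_df <- function() {
  data.frame(fov_id = character(0), object_id = integer(0),
             centroid_x_um = numeric(0), centroid_y_um = numeric(0),
             true_diameter_um = numeric(0), zone = character(0),
             raster_area_px = numeric(0),
             raster_centroid_x_um = numeric(0),
             raster_centroid_y_um = numeric(0),
             raster_diameter_um = numeric(0),
             clipped = logical(0), in_frame = logical(0),
             stringsAsFactors = FALSE)
}

#' Simulate one calibrated field of view with ground truth
#'
#' Draws a realisation of the subpial CoA point process for one field of
#' view (FOV) and, optionally, renders it as a 16-bit-scale intensity
#' image. For a pial-surface region the pial border is the top image edge;
#' the number of CoA in the high-density (HD) band (depth <=
#' \code{hd_depth_um[region]}) is Poisson with mean \code{hd_intensity} x
#' band area, and the low-density (LD) remainder receives intensity
#' \code{ld_ratio * hd_intensity}. Neuropil regions have no HD band and a
#' uniform LD intensity. Diameters follow the truncated lognormal of the
#' configuration; a hard-core minimum separation is enforced by rejection
#' sampling.
#'
#' @param config A [sim_config()].
#' @param calibration A [calibration()].
#' @param region Region label.
#' @param fov_id Identifier for the FOV.
#' @param seed Optional integer seed; \code{NULL} continues the current RNG
#'   stream.
#' @param image Render the pixel raster (\code{TRUE}) or emit ground truth
#'   only (\code{FALSE}, much faster for count-level studies).
#' @return List with \code{micrograph} (a [micrograph()] or \code{NULL}),
#'   \code{objects} (per-object ground truth: true centre and diameter,
#'   generating zone, and -- when rendered -- the exact raster area,
#'   raster centroid and raster-equivalent diameter of the stamped pixel
#'   set, a \code{clipped} flag for discs cut by any image border, and the
#'   \code{in_frame} flag saying whether the counting frame retains the
#'   object) and \code{fov} (one-row per-FOV summary with true count and
#'   area fraction).
#' @export
simulate_fov <- function(config, calibration, region, fov_id = "fov1",
                         seed = NULL, image = TRUE) {
  assert_sim_config(config)
  assert_calibration(calibration)
  assert_region(region)
  if (!is.null(seed)) set.seed(seed)

  px <- calibration$pixel_size_um
  w_um <- calibration$fov_width_px * px
  h_um <- calibration$fov_height_px * px
  area_mm2 <- calibration$fov_area_mm2
  m <- config$edge_margin_um
  if (2 * m >= min(w_um, h_um)) {
    stop("edge_margin_um too large for the field of view", call. = FALSE)
  }

  pial <- is_pial_region(region)
  hd_depth <- if (pial) min(config$hd_depth_um[[region]], h_um) else 0
  hd_area_mm2 <- w_um * hd_depth / 1e6
  ld_area_mm2 <- area_mm2 - hd_area_mm2

  n_hd <- if (hd_area_mm2 > 0) {
    stats::rpois(1, config$hd_intensity * hd_area_mm2)
  } else 0L
  n_ld <- stats::rpois(1, config$ld_ratio * config$hd_intensity *
                          ld_area_mm2)
  zone <- c(rep("HD", n_hd), rep("LD", n_ld))
  n <- n_hd + n_ld

  if (n > 0) {
    ld_top <- if (pial) max(hd_depth, m) else m
    win <- cbind(
      xmin = rep(m, n), xmax = rep(w_um - m, n),
      ymin = ifelse(zone == "HD", m, ld_top),
      ymax = ifelse(zone == "HD", min(hd_depth, h_um - m), h_um - m)
    )
    pos <- place_hardcore(win, config$min_separation_um,
                          config$max_attempts,
                          sprintf("region %s, hd_intensity %g", region,
                                  config$hd_intensity))
    diam <- rtrunc_lnorm(n, config$diameter_meanlog, config$diameter_sdlog,
                         config$diameter_bounds_um)
    objects <- data.frame(
      fov_id = fov_id, object_id = seq_len(n),
      centroid_x_um = pos[, "x"], centroid_y_um = pos[, "y"],
      true_diameter_um = diam, zone = zone,
      raster_area_px = NA_real_,
      raster_centroid_x_um = NA_real_, raster_centroid_y_um = NA_real_,
      raster_diameter_um = NA_real_,
      clipped = NA, in_frame = TRUE,
      stringsAsFactors = FALSE
    )
  } else {
    objects <- empty_objects_df()
  }

  mg <- NULL
  union_px <- 0
  if (image) {
    nr <- calibration$fov_height_px
    nc <- calibration$fov_width_px
    fg <- matrix(FALSE, nr, nc)
    if (n > 0) {
      for (i in seq_len(n)) {
        ras <- rasterize_disc(objects$centroid_x_um[i],
                              objects$centroid_y_um[i],
                              objects$true_diameter_um[i] / 2, px, nr, nc)
        fg[ras$idx] <- TRUE
        objects$raster_area_px[i] <- length(ras$idx)
        objects$raster_centroid_x_um[i] <- mean((ras$cols - 0.5) * px)
        objects$raster_centroid_y_um[i] <- mean((ras$rows - 0.5) * px)
        touches_left <- any(ras$cols == 1L)
        touches_bottom <- any(ras$rows == nr)
        eq_diam <- 2 * sqrt(length(ras$idx) * px^2 / pi)
        objects$raster_diameter_um[i] <- eq_diam
        objects$clipped[i] <- touches_left || touches_bottom ||
          any(ras$cols == nc) || any(ras$rows == 1L)
        objects$in_frame[i] <- !touches_left && !touches_bottom &&
          eq_diam >= 3
      }
    }
    union_px <- sum(fg)
    pix <- matrix(config$background_level, nr, nc)
    pix[fg] <- config$blob_peak_level
    pix <- pix + stats::rnorm(nr * nc, 0, config$background_noise_sd)
    pix <- pmin(pmax(pix, 0), 65535)
    mg <- micrograph(pix, calibration, fov_id = fov_id, region = region)
    area_frac <- 100 * union_px * px^2 / (area_mm2 * 1e6)
  } else {
    area_frac <- if (n > 0) {
      100 * sum(pi * (objects$true_diameter_um / 2)^2) / (area_mm2 * 1e6)
    } else 0
  }

  fov <- data.frame(fov_id = fov_id, region = region, true_count = n,
                    true_area_fraction_pct = area_frac,
                    stringsAsFactors = FALSE)
  list(micrograph = mg, objects = objects, fov = fov)
}

#' Simulate a whole-section sampling of fields of view
#'
#' Generates \code{fovs_per_region} fields of view for each of the 14
#' sampling regions of one brain section, with regional HD-band intensities
#' set by the staged spatial model (see [stage_targets()]): densities peak
#' at the fimbria pial surface and decay along the pial border in both
#' directions, wall-of-lateral-ventricle fields become involved at stage 3,
#' and parahippocampal/fusiform deep-white-matter spread is flagged at
#' stage 4. Neuropil regions other than \code{LV} are left empty.
#'
#' @inheritParams simulate_fov
#' @param section_id Identifier for the section.
#' @param images Render pixel rasters for every FOV (slow) or ground truth
#'   only.
#' @return List with \code{micrographs} (named list, present when
#'   \code{images = TRUE}), \code{objects} and \code{fovs} (row-bound
#'   ground truth across all FOVs) and \code{section} (one-row table:
#'   \code{section_id}, \code{true_stage}, \code{deep_wm_lv},
#'   \code{deep_wm_phg_fusiform}).
#' @export
simulate_section <- function(config, calibration = calibration(),
                             section_id = "S1", seed = NULL,
                             images = FALSE) {
  assert_sim_config(config)
  assert_calibration(calibration)
  if (!is.null(seed)) set.seed(seed)

  tg <- stage_targets(config$stage)

  # Stage targets are expected counts per standard 0.2 mm^2 field; convert
  # to spatial intensities against the standard geometry so that smaller
  # rasters scale their expected counts with area.
  std <- calibration()
  std_w <- std$fov_width_px * std$pixel_size_um
  std_h <- std$fov_height_px * std$pixel_size_um
  region_intensity <- function(region) {
    if (is_pial_region(region)) {
      depth <- min(config$hd_depth_um[[region]], std_h)
      hd_area <- std_w * depth / 1e6
      ld_area <- std$fov_area_mm2 - hd_area
      tg$pial[[region]] / (hd_area + config$ld_ratio * ld_area)
    } else if (region == "LV") {
      tg$lv / (config$ld_ratio * std$fov_area_mm2)
    } else 0
  }

  objects <- list()
  fovs <- list()
  micrographs <- list()
  for (region in all_regions()) {
    cfg <- config
    cfg$hd_intensity <- region_intensity(region)
    for (k in seq_len(config$fovs_per_region)) {
      fid <- sprintf("%s_%s_f%d", section_id, region, k)
      sim <- simulate_fov(cfg, calibration, region, fov_id = fid,
                          image = images)
      objects[[fid]] <- sim$objects
      fovs[[fid]] <- sim$fov
      if (images) micrographs[[fid]] <- sim$micrograph
    }
  }
  objects <- do.call(rbind, c(objects, list(make.row.names = FALSE)))
  fovs <- do.call(rbind, c(fovs, list(make.row.names = FALSE)))
  fovs$section_id <- section_id
  if (nrow(objects) > 0) objects$section_id <- section_id
  else objects$section_id <- character(0)

  lv_count <- sum(fovs$true_count[fovs$region == "LV"])
  section <- data.frame(section_id = section_id,
                        true_stage = config$stage,
                        deep_wm_lv = lv_count > 0,
                        deep_wm_phg_fusiform = tg$deep_wm_phg_fusiform,
                        stringsAsFactors = FALSE)
  out <- list(objects = objects, fovs = fovs, section = section)
  if (images) out$micrographs <- micrographs
  out
}

#' Simulate a cohort of sections with subject covariates
#'
#' Draws a cohort of subjects (one section each) with ages and BMI uniform
#' over their configured ranges, balanced sex, and stages assigned
#' independently of age (the spatiotemporal sequence is modelled as
#' age-independent). Each subject's median CoA diameter is shifted by
#' \code{age_diameter_slope * (age - midpoint of age_range)}, emulating the
#' growth of CoA with natural ageing; no covariate affects densities.
#'
#' @inheritParams simulate_section
#' @param stages Optional integer vector of stages (length
#'   \code{config$subjects}); default cycles through 0-4 in a random order.
#' @return List with \code{objects}, \code{fovs}, \code{sections} (per
#'   section: true stage, deep-white-matter flags, age, BMI, sex) and,
#'   when \code{images = TRUE}, \code{micrographs}.
#' @export
simulate_cohort <- function(config, calibration = calibration(),
                            seed = NULL, images = FALSE, stages = NULL) {
  assert_sim_config(config)
  if (config$subjects < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- config$subjects

  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  bmi <- stats::runif(n, config$bmi_range[1], config$bmi_range[2])
  sex <- sample(rep_len(c("F", "M"), n))
  if (is.null(stages)) {
    stages <- sample(rep_len(0:4, n))
  }
  stopifnot(length(stages) == n, all(stages %in% 0:4))

  mid <- mean(config$age_range)
  base_median <- exp(config$diameter_meanlog)
  lo <- config$diameter_bounds_um[1]
  hi <- config$diameter_bounds_um[2]

  objects <- list()
  fovs <- list()
  sections <- list()
  micrographs <- list()
  for (i in seq_len(n)) {
    sid <- sprintf("S%02d", i)
    cfg <- config
    cfg$stage <- as.integer(stages[i])
    med_i <- base_median + config$age_diameter_slope * (age[i] - mid)
    med_i <- min(max(med_i, lo + 0.2), hi - 0.2)
    cfg$diameter_meanlog <- log(med_i)
    sim <- simulate_section(cfg, calibration, section_id = sid,
                            images = images)
    objects[[sid]] <- sim$objects
    fovs[[sid]] <- sim$fovs
    sec <- sim$section
    sec$age <- age[i]
    sec$bmi <- bmi[i]
    sec$sex <- sex[i]
    sections[[sid]] <- sec
    if (images) micrographs <- c(micrographs, sim$micrographs)
  }
  out <- list(
    objects = do.call(rbind, c(objects, list(make.row.names = FALSE))),
    fovs = do.call(rbind, c(fovs, list(make.row.names = FALSE))),
    sections = do.call(rbind, c(sections, list(make.row.names = FALSE)))
  )
  if (images) out$micrographs <- micrographs
  out
}
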
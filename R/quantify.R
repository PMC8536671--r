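#' Summarise detected objects of one field of view
#'
#' Computes the five per-FOV parameters: (1) CoA count; (2) CoA area
#' fraction, the percentage of the field occupied by CoA; (3) mean
#' equivalent diameter; (4) minimum diameter, the diameter of the smallest
#' CoA in the field; (5) maximum diameter, the diameter of the largest. A
#' field without CoA records 0 for count and area fraction -- those zeros
#' enter downstream density analyses -- while the three diameters are
#' recorded as missing (\code{NA}) and are excluded from diameter analyses.
#'
#' @param objects Data frame of retained objects (see [detect()]), all from
#'   one field of view.
#' @param calibration A [calibration()].
#' @param region Region label.
#' @param fov_id,section_id Identifiers copied into the output.
#' @return One-row data frame: \code{fov_id}, \code{section_id},
#'   \code{region}, \code{count}, \code{area_fraction_pct},
#'   \code{mean_diameter_um}, \code{min_diameter_um},
#'   \code{max_diameter_um}.
#' @export
summarize_fov <- function(objects, calibration, region,
                          fov_id = if (nrow(objects)) objects$fov_id[1] else "fov",
                          section_id = NA_character_) {
  assert_calibration(calibration)
  n <- nrow(objects)
  d <- objects$equivalent_diameter_um
  data.frame(
    fov_id = fov_id, section_id = section_id, region = region,
    count = n,
    area_fraction_pct = if (n) {
      100 * sum(objects$area_um2) / (calibration$fov_area_mm2 * 1e6)
    } else 0,
    mean_diameter_um = if (n) mean(d) else NA_real_,
    min_diameter_um = if (n) min(d) else NA_real_,
    max_diameter_um = if (n) max(d) else NA_real_,
    stringsAsFactors = FALSE
  )
}

## Shoelace area of a simple polygon given as a 2-column (x, y) matrix.
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

polyline_length <- function(line) {
  sum(sqrt(diff(line[, 1])^2 + diff(line[, 2])^2))
}

## Minimum distance from points (px, py) to a polyline.
dist_to_polyline <- function(px, py, line) {
  best <- rep(Inf, length(px))
  for (s in seq_len(nrow(line) - 1)) {
    ax <- line[s, 1]; ay <- line[s, 2]
    bx <- line[s + 1, 1]; by <- line[s + 1, 2]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx^2 + dy^2
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(pmax(((px - ax) * dx + (py - ay) * dy) / len2, 0), 1)
    d <- sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
    best <- pmin(best, d)
  }
  best
}

#' High-density / low-density zone partition of a field of view
#'
#' Describes how a subpial field is split into the high-density (HD) band
#' -- from the pial border down to a fixed region-specific depth -- and the
#' low-density (LD) remainder. By default the pial border is the straight
#' top edge of the field; a curved border may be supplied as a polyline in
#' micrometre coordinates, in which case depth is distance to that
#' polyline. Neuropil regions have no pial border and no HD zone.
#'
#' @param region Region label.
#' @param calibration A [calibration()].
#' @param hd_depth_um HD-zone depth (um); default from
#'   [hd_depth_defaults()] for pial regions.
#' @param pial_border Optional 2-column (x, y) polyline (um); default the
#'   top edge.
#' @return An object of class \code{coa_zone_partition} with the border,
#'   the HD depth, HD/LD polygons (axis-aligned rectangles in the default
#'   geometry) and their areas in mm^2.
#' @export
zone_partition <- function(region, calibration = calibration(),
                           hd_depth_um = NULL, pial_border = NULL) {
  assert_region(region)
  assert_calibration(calibration)
  w <- calibration$fov_width_px * calibration$pixel_size_um
  h <- calibration$fov_height_px * calibration$pixel_size_um
  fov_poly <- cbind(c(0, w, w, 0), c(0, 0, h, h))
  pial <- is_pial_region(region)
  if (is.null(hd_depth_um)) {
    hd_depth_um <- if (pial) hd_depth_defaults()[[region]] else 0
  }
  if (!pial && hd_depth_um > 0) {
    stop("neuropil regions have no HD zone; hd_depth_um must be 0",
         call. = FALSE)
  }
  hd_depth_um <- min(hd_depth_um, h)
  if (is.null(pial_border)) {
    pial_border <- cbind(c(0, w), c(0, 0))
  }
  hd_polygon <- if (hd_depth_um > 0) {
    cbind(c(0, w, w, 0), c(0, 0, hd_depth_um, hd_depth_um))
  } else NULL
  ld_polygon <- if (hd_depth_um < h) {
    cbind(c(0, w, w, 0), c(hd_depth_um, hd_depth_um, h, h))
  } else NULL
  structure(
    list(region = region, calibration = calibration,
         hd_depth_um = hd_depth_um, pial_border = pial_border,
         hd_polygon = hd_polygon, ld_polygon = ld_polygon,
         hd_area_mm2 = w * hd_depth_um / 1e6,
         ld_area_mm2 = w * (h - hd_depth_um) / 1e6,
         fov_polygon = fov_poly),
    class = "coa_zone_partition"
  )
}

#' Estimate the thickness of a high-density band
#'
#' The depth of an HD zone traced as a polygon along the pial surface is
#' estimated as the enclosed area divided by the length of a centre line
#' drawn along the middle of the zone, parallel to the pial border. For a
#' constant-depth band this recovers the depth exactly.
#'
#' @param hd_polygon 2-column (x, y) matrix of polygon vertices (um).
#' @param centre_line 2-column (x, y) polyline (um) of positive length.
#' @return Estimated thickness in micrometres.
#' @export
estimate_hd_thickness <- function(hd_polygon, centre_line) {
  stopifnot(is.matrix(hd_polygon), ncol(hd_polygon) == 2,
            nrow(hd_polygon) >= 3,
            is.matrix(centre_line), ncol(centre_line) == 2,
            nrow(centre_line) >= 2)
  len <- polyline_length(centre_line)
  if (len <= 0) stop("centre line has zero length", call. = FALSE)
  polygon_area(hd_polygon) / len
}

#' Assign detected objects to the HD or LD zone
#'
#' Zone membership is decided by the object centroid: depth is the
#' distance from the centroid to the pial border, and an object is HD iff
#' its depth is at most the partition's HD depth (the boundary itself is
#' HD). In neuropil fields every object is LD, consistent with the HD zone
#' being defined only beneath the pia.
#'
#' @param objects Data frame of objects with centroid columns.
#' @param partition A [zone_partition()].
#' @return \code{objects} with \code{depth_um} recomputed against the
#'   partition's border and a \code{zone} column (\code{"HD"} /
#'   \code{"LD"}).
#' @export
assign_zones <- function(objects, partition) {
  stopifnot(inherits(partition, "coa_zone_partition"))
  if (nrow(objects) == 0) {
    objects$zone <- character(0)
    return(objects)
  }
  depth <- dist_to_polyline(objects$centroid_x_um, objects$centroid_y_um,
                            partition$pial_border)
  objects$depth_um <- depth
  objects$zone <- ifelse(partition$hd_depth_um > 0 &
                           depth <= partition$hd_depth_um, "HD", "LD")
  objects
}

#' Summarise one zone of a field of view
#'
#' Packing density (count per mm^2 of the zone), area fraction and diameter
#' statistics computed over the objects assigned to the zone, against the
#' zone's own area. Diameters are missing when the zone holds no objects.
#'
#' @param objects Data frame with a \code{zone} column (see
#'   [assign_zones()]).
#' @param partition A [zone_partition()].
#' @param zone \code{"HD"} or \code{"LD"}.
#' @return One-row data frame: \code{region}, \code{zone}, \code{count},
#'   \code{zone_area_mm2}, \code{packing_density_per_mm2},
#'   \code{area_fraction_pct}, \code{mean_diameter_um},
#'   \code{max_diameter_um}.
#' @export
summarize_zone <- function(objects, partition, zone = c("HD", "LD")) {
  stopifnot(inherits(partition, "coa_zone_partition"))
  zone <- match.arg(zone)
  zarea <- if (zone == "HD") partition$hd_area_mm2 else partition$ld_area_mm2
  if (zarea <= 0) {
    stop("zone ", zone, " of region ", partition$region,
         " has non-positive area", call. = FALSE)
  }
  sel <- objects[objects$zone == zone, , drop = FALSE]
  n <- nrow(sel)
  d <- sel$equivalent_diameter_um
  data.frame(
    region = partition$region, zone = zone, count = n,
    zone_area_mm2 = zarea,
    packing_density_per_mm2 = n / zarea,
    area_fraction_pct = if (n) 100 * sum(sel$area_um2) / (zarea * 1e6)
                        else 0,
    mean_diameter_um = if (n) mean(d) else NA_real_,
    max_diameter_um = if (n) max(d) else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Compare HD and LD zones across sections
#'
#' For each region and parameter, runs an unpaired two-tailed t-test of the
#' per-section HD values against the per-section LD values and reports the
#' HD/LD fold change of the means (missing when the LD mean is zero),
#' mirroring the high-density versus low-density burden comparison.
#'
#' @param zone_summaries Data frame of per-section zone summaries: columns
#'   \code{section_id}, \code{region}, \code{zone} and the parameter
#'   columns of [summarize_zone()].
#' @param parameters Which parameter columns to compare.
#' @return Data frame with one row per region x parameter: group means,
#'   fold change, t statistic, df and p value.
#' @export
compare_zones <- function(zone_summaries,
                          parameters = c("packing_density_per_mm2",
                                         "area_fraction_pct",
                                         "mean_diameter_um",
                                         "max_diameter_um")) {
  out <- list()
  for (region in intersect(pial_regions(),
                           unique(zone_summaries$region))) {
    reg <- zone_summaries[zone_summaries$region == region, , drop = FALSE]
    for (param in parameters) {
      hd <- reg[[param]][reg$zone == "HD"]
      ld <- reg[[param]][reg$zone == "LD"]
      hd <- hd[!is.na(hd)]
      ld <- ld[!is.na(ld)]
      tt <- if (length(hd) >= 2 && length(ld) >= 2) {
        t_test_unpaired(hd, ld)
      } else {
        list(statistic = NA_real_, df = NA_real_, p_raw = NA_real_)
      }
      fold <- if (length(ld) && mean(ld) > 0) mean(hd) / mean(ld)
              else NA_real_
      out[[paste(region, param)]] <- data.frame(
        region = region, parameter = param,
        hd_mean = if (length(hd)) mean(hd) else NA_real_,
        ld_mean = if (length(ld)) mean(ld) else NA_real_,
        fold_change = fold,
        t = tt$statistic, df = tt$df, p = tt$p_raw,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
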
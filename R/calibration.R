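#' Spatial calibration of a field of view
#'
#' Binds the pixel grid of a field of view (FOV) to physical units. The
#' default reproduces the acquisition geometry assumed throughout the
#' package: 1600 x 1200 pixels covering 0.2 mm^2, i.e. a pixel side of
#' sqrt(200000 / 1920000) ~= 0.32275 um.
#'
#' @param fov_width_px,fov_height_px Image size in pixels.
#' @param pixel_size_um Physical length of one pixel side, in micrometres.
#' @return An object of class \code{coa_calibration}: a list with
#'   \code{pixel_size_um}, \code{fov_width_px}, \code{fov_height_px} and the
#'   derived \code{fov_area_mm2}.
#' @examples
#' cal <- calibration()
#' cal$fov_area_mm2  # 0.2
#' @export
calibration <- function(fov_width_px = 1600L, fov_height_px = 1200L,
                        pixel_size_um = sqrt(2e5 / (1600 * 1200))) {
  fov_width_px <- as.integer(fov_width_px)
  fov_height_px <- as.integer(fov_height_px)
  stopifnot(fov_width_px > 0L, fov_height_px > 0L,
            is.finite(pixel_size_um), pixel_size_um > 0)
  structure(
    list(
      pixel_size_um = pixel_size_um,
      fov_width_px = fov_width_px,
      fov_height_px = fov_height_px,
      fov_area_mm2 = fov_width_px * fov_height_px * pixel_size_um^2 / 1e6
    ),
    class = "coa_calibration"
  )
}

#' @export
print.coa_calibration <- function(x, ...) {
  cat(sprintf("<coa_calibration> %d x %d px, %.5f um/px, %.4f mm2\n",
              x$fov_width_px, x$fov_height_px, x$pixel_size_um,
              x$fov_area_mm2))
  invisible(x)
}

assert_calibration <- function(x) {
  if (!inherits(x, "coa_calibration")) {
    stop("expected a 'coa_calibration' object", call. = FALSE)
  }
  x
}

#' Construct a micrograph object
#'
#' A micrograph is a calibrated single-channel intensity image of one field
#' of view, together with its region label.
#'
#' @param pixels Numeric matrix of non-negative intensities; rows are image
#'   rows (y, increasing downward), columns are image columns (x, increasing
#'   rightward).
#' @param calibration A [calibration()] whose pixel dimensions match
#'   \code{pixels}.
#' @param fov_id Identifier string.
#' @param region Region label (see [pial_regions()]), or \code{NA} if
#'   unknown.
#' @return An object of class \code{coa_micrograph}.
#' @export
micrograph <- function(pixels, calibration, fov_id = "fov",
                       region = NA_character_) {
  assert_calibration(calibration)
  stopifnot(is.matrix(pixels), all(is.finite(pixels)), all(pixels >= 0))
  if (nrow(pixels) != calibration$fov_height_px ||
      ncol(pixels) != calibration$fov_width_px) {
    stop("pixel matrix is ", nrow(pixels), " x ", ncol(pixels),
         " but calibration declares ", calibration$fov_height_px, " x ",
         calibration$fov_width_px, call. = FALSE)
  }
  if (!is.na(region)) assert_region(region)
  structure(
    list(pixels = pixels, calibration = calibration, fov_id = fov_id,
         region = region),
    class = "coa_micrograph"
  )
}

#' @export
print.coa_micrograph <- function(x, ...) {
  cat(sprintf("<coa_micrograph> %s [%s], %d x %d px, range [%g, %g]\n",
              x$fov_id, ifelse(is.na(x$region), "?", x$region),
              ncol(x$pixels), nrow(x$pixels), min(x$pixels), max(x$pixels)))
  invisible(x)
}
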
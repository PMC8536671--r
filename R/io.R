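#' Write and read calibrated micrographs
#'
#' Micrographs are stored as single-channel 16-bit TIFFs with a JSON
#' sidecar (same path plus \code{.json}) recording the calibration, FOV id
#' and region label, so physical units survive the round trip.
#'
#' @param mg A [micrograph()].
#' @param path Output TIFF path.
#' @return \code{write_micrograph} returns \code{path} invisibly;
#'   \code{read_micrograph} returns a [micrograph()].
#' @export
write_micrograph <- function(mg, path) {
  stopifnot(inherits(mg, "coa_micrograph"))
  tiff::writeTIFF(mg$pixels / 65535, path, bits.per.sample = 16,
                  compression = "none")
  sidecar <- list(
    fov_id = mg$fov_id, region = mg$region,
    pixel_size_um = mg$calibration$pixel_size_um,
    fov_width_px = mg$calibration$fov_width_px,
    fov_height_px = mg$calibration$fov_height_px
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_micrograph
#' @export
read_micrograph <- function(path) {
  pix <- tiff::readTIFF(path) * 65535
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cal <- calibration(sc$fov_width_px, sc$fov_height_px, sc$pixel_size_um)
  region <- if (is.null(sc$region) || is.na(sc$region)) NA_character_
            else sc$region
  micrograph(pix, cal, fov_id = sc$fov_id, region = region)
}

write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
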
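#' Region labels of the hippocampal sampling scheme
#'
#' Fields of view are sampled at seven sites along the hippocampal pial
#' border and in seven neuropil regions. Pial-surface labels, ordered
#' anatomically from the alveus through the fimbria to the collateral
#' sulcus:
#' \itemize{
#'   \item \code{APS} alveus pial surface
#'   \item \code{FPS} fimbria pial surface
#'   \item \code{PPS} prosubiculum pial surface
#'   \item \code{SPS} subiculum pial surface
#'   \item \code{MPS} medial entorhinal cortex pial surface
#'   \item \code{LPS} lateral entorhinal cortex pial surface
#'   \item \code{CPS} collateral sulcus pial surface
#' }
#' Neuropil labels: \code{LV} (wall of lateral ventricle), \code{fimbria},
#' \code{CA4}, \code{CA3}, \code{CA2}, \code{CA1}, \code{subiculum}.
#'
#' @return Character vector of region labels.
#' @export
pial_regions <- function() {
  c("APS", "FPS", "PPS", "SPS", "MPS", "LPS", "CPS")
}

#' @rdname pial_regions
#' @export
neuropil_regions <- function() {
  c("LV", "fimbria", "CA4", "CA3", "CA2", "CA1", "subiculum")
}

#' @rdname pial_regions
#' @export
all_regions <- function() {
  c(pial_regions(), neuropil_regions())
}

is_pial_region <- function(region) region %in% pial_regions()

assert_region <- function(region) {
  if (length(region) != 1L || !region %in% all_regions()) {
    stop("unknown region label: ", paste(region, collapse = ", "),
         " (expected one of ", paste(all_regions(), collapse = ", "), ")",
         call. = FALSE)
  }
  region
}

#' Default high-density-zone analysis depths
#'
#' Fixed subpial depths delimiting the high-density (HD) zone in each
#' pial-surface region: 100 um at the fimbria, 70 um at the prosubiculum
#' and 40 um at the remaining five pial surfaces.
#'
#' @return Named numeric vector of depths in micrometres, one per
#'   pial-surface region.
#' @export
hd_depth_defaults <- function() {
  c(APS = 40, FPS = 100, PPS = 70, SPS = 40, MPS = 40, LPS = 40, CPS = 40)
}
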
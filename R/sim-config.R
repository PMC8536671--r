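#' Configuration of the synthetic-micrograph generator
#'
#' Collects every tunable of the simulator: the spatial intensity of CoA in
#' the subpial high-density (HD) band, the HD/LD intensity ratio, the
#' truncated-lognormal diameter distribution, rendering levels, the
#' hard-core minimum separation, and the cohort covariate model.
#'
#' Defaults emulate the acquisition and biology the analysis assumes: CoA
#' diameters lognormal with median 9 um (observed mean diameters cluster
#' near 9.1 um), truncated to 3-30 um (mature CoA can reach 30 um; 3 um is
#' the analysis detection floor); bright discs at ~10x the background so the
#' peak exceeds the background by far more than 5 noise SDs; a 10 um
#' hard-core separation so discs rarely touch.
#'
#' @param stage Section stage 0-4 used by [simulate_section()].
#' @param hd_depth_um Named vector of HD-band depths per pial region (um);
#'   see [hd_depth_defaults()].
#' @param hd_intensity Expected CoA per mm^2 of HD band (single FOV
#'   simulations); [simulate_section()] overrides this per region from the
#'   stage model.
#' @param ld_ratio LD/HD intensity ratio, in (0, 1).
#' @param diameter_meanlog,diameter_sdlog Lognormal parameters of the CoA
#'   diameter distribution, on the log-micrometre scale.
#' @param diameter_bounds_um Length-2 truncation bounds (um).
#' @param background_level,background_noise_sd,blob_peak_level Rendering
#'   intensities on the 16-bit scale: constant autofluorescence background,
#'   Gaussian noise SD, and the disc level.
#' @param min_separation_um Hard-core minimum centre-to-centre distance
#'   (um) between simulated CoA.
#' @param edge_margin_um Inset of the centroid sampling window from every
#'   image border (um); 0 lets discs straddle borders.
#' @param max_attempts Rejection-sampling attempts per object before the
#'   generator gives up.
#' @param subjects Number of subjects in [simulate_cohort()].
#' @param fovs_per_region Fields of view captured per region per section.
#' @param age_range,bmi_range Uniform covariate ranges for the cohort.
#' @param age_diameter_slope Shift of the median CoA diameter per year of
#'   age (um/year), applied around the midpoint of \code{age_range}.
#' @return An object of class \code{coa_sim_config} (a validated list).
#' @export
sim_config <- function(stage = 0L,
                       hd_depth_um = hd_depth_defaults(),
                       hd_intensity = 500,
                       ld_ratio = 0.1,
                       diameter_meanlog = log(9),
                       diameter_sdlog = 0.25,
                       diameter_bounds_um = c(3, 30),
                       background_level = 500,
                       background_noise_sd = 50,
                       blob_peak_level = 5000,
                       min_separation_um = 10,
                       edge_margin_um = 0,
                       max_attempts = 500L,
                       subjects = 30L,
                       fovs_per_region = 3L,
                       age_range = c(42, 89),
                       bmi_range = c(20, 42),
                       age_diameter_slope = 0.05) {
  stopifnot(stage %in% 0:4,
            is.numeric(hd_depth_um), all(hd_depth_um > 0),
            all(pial_regions() %in% names(hd_depth_um)),
            hd_intensity >= 0,
            ld_ratio > 0, ld_ratio < 1,
            is.finite(diameter_meanlog), diameter_sdlog > 0,
            length(diameter_bounds_um) == 2L,
            diameter_bounds_um[1] < diameter_bounds_um[2],
            diameter_bounds_um[1] >= 3, diameter_bounds_um[2] <= 30,
            background_level >= 0, background_noise_sd >= 0,
            min_separation_um >= 0, edge_margin_um >= 0,
            max_attempts >= 1L, subjects >= 1L, fovs_per_region >= 1L,
            age_range[1] < age_range[2], bmi_range[1] < bmi_range[2])
  if (blob_peak_level <= background_level + 5 * background_noise_sd) {
    stop("blob_peak_level must exceed background_level + 5 * ",
         "background_noise_sd (detectability contract)", call. = FALSE)
  }
  structure(
    list(stage = as.integer(stage), hd_depth_um = hd_depth_um,
         hd_intensity = hd_intensity, ld_ratio = ld_ratio,
         diameter_meanlog = diameter_meanlog,
         diameter_sdlog = diameter_sdlog,
         diameter_bounds_um = diameter_bounds_um,
         background_level = background_level,
         background_noise_sd = background_noise_sd,
         blob_peak_level = blob_peak_level,
         min_separation_um = min_separation_um,
         edge_margin_um = edge_margin_um,
         max_attempts = as.integer(max_attempts),
         subjects = as.integer(subjects),
         fovs_per_region = as.integer(fovs_per_region),
         age_range = age_range, bmi_range = bmi_range,
         age_diameter_slope = age_diameter_slope),
    class = "coa_sim_config"
  )
}

assert_sim_config <- function(x) {
  if (!inherits(x, "coa_sim_config")) {
    stop("expected a 'coa_sim_config' object (see sim_config())",
         call. = FALSE)
  }
  x
}

#' Expected per-FOV CoA counts by region for each stage
#'
#' The staged spatial model of CoA deposition: densities peak at the
#' fimbria pial surface (FPS) and decay monotonically along the pial border
#' in both directions (towards the alveus on one side and towards the
#' collateral sulcus on the other). Expected per-FOV counts are placed
#' strictly inside the stage bands -- stage 1: fimbria in (0, 10); stage 2:
#' fimbria, prosubiculum and subiculum pial surfaces in (10, 50); stages
#' 3-4: fimbria in (50, 500) with continuous pial spread. \code{LV} is the
#' expected count in wall-of-lateral-ventricle fields (deep white matter
#' involvement) and \code{deep_wm_phg_fusiform} flags parahippocampal /
#' fusiform deep-white-matter spread, present only at stage 4.
#'
#' @param stage Integer 0-4.
#' @return List with \code{pial} (named expected per-FOV counts for the 7
#'   pial regions), \code{lv} (expected count in LV fields) and
#'   \code{deep_wm_phg_fusiform} (logical).
#' @export
stage_targets <- function(stage) {
  stopifnot(length(stage) == 1L, stage %in% 0:4)
  zero <- stats::setNames(numeric(7), pial_regions())
  pial <- switch(as.character(stage),
    "0" = zero,
    "1" = replace(zero, "FPS", 5),
    "2" = replace(zero, c("FPS", "PPS", "SPS"), c(30, 22, 15)),
    "3" = stats::setNames(c(30, 80, 50, 35, 25, 15, 8), pial_regions()),
    "4" = stats::setNames(c(50, 150, 90, 60, 40, 25, 12), pial_regions())
  )
  list(pial = pial,
       lv = c(0, 0, 0, 25, 40)[stage + 1L],
       deep_wm_phg_fusiform = stage == 4L)
}
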
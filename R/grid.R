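#' Section-level regional parameter summaries
#'
#' Collapses per-FOV summaries to one value per section x region for each
#' of the five CoA parameters. Counts and area fractions average over all
#' fields, zeros included; the three diameter parameters average only over
#' fields that contained CoA (empty fields contribute no diameter), and a
#' region whose fields were all empty is missing -- the source of the
#' varying per-cell n in the correlation grids.
#'
#' @param fov_summaries Data frame of [summarize_fov()] rows with a
#'   \code{section_id} column.
#' @param regions Regions to summarise (default the 7 pial surfaces).
#' @return Data frame: \code{section_id}, \code{region}, \code{count},
#'   \code{area_fraction_pct}, \code{mean_diameter_um},
#'   \code{min_diameter_um}, \code{max_diameter_um}.
#' @export
summarize_sections <- function(fov_summaries, regions = pial_regions()) {
  ids <- unique(fov_summaries$section_id)
  mean_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  rows <- list()
  for (sid in ids) {
    fs <- fov_summaries[fov_summaries$section_id == sid, , drop = FALSE]
    for (r in regions) {
      fr <- fs[fs$region == r, , drop = FALSE]
      if (nrow(fr) == 0) next
      rows[[paste(sid, r)]] <- data.frame(
        section_id = sid, region = r,
        count = mean(fr$count),
        area_fraction_pct = mean(fr$area_fraction_pct),
        mean_diameter_um = mean_na(fr$mean_diameter_um),
        min_diameter_um = mean_na(fr$min_diameter_um),
        max_diameter_um = mean_na(fr$max_diameter_um),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

coa_parameters <- function() {
  c("count", "area_fraction_pct", "mean_diameter_um", "min_diameter_um",
    "max_diameter_um")
}

#' Correlation grid of a covariate against regional CoA parameters
#'
#' For every pial-surface region and every CoA parameter, correlates the
#' section-level regional values with a per-section covariate (ranked CoA
#' sequence, age, or BMI) by Spearman's rho, then applies the
#' Benjamini-Hochberg adjustment across all cells of the grid as one
#' family. Missing parameter values are deleted pairwise, so n varies by
#' cell; cells with fewer than 3 complete pairs stay missing and shrink
#' the family.
#'
#' @param section_params Data frame from [summarize_sections()].
#' @param covariates Data frame with \code{section_id} and the covariate
#'   column.
#' @param covariate Name of the covariate column.
#' @param regions,parameters Grid axes; defaults are the 7 pial regions
#'   and the 5 CoA parameters.
#' @return Long data frame with one row per cell: \code{covariate},
#'   \code{region}, \code{parameter}, \code{r}, \code{p_raw},
#'   \code{p_adjusted}, \code{n}, \code{significant} (adjusted p < 0.05).
#' @export
build_grid <- function(section_params, covariates, covariate,
                       regions = pial_regions(),
                       parameters = coa_parameters()) {
  stopifnot(covariate %in% names(covariates),
            "section_id" %in% names(covariates))
  rows <- list()
  for (r in regions) {
    reg <- section_params[section_params$region == r, , drop = FALSE]
    merged <- merge(covariates[, c("section_id", covariate)], reg,
                    by = "section_id", all.x = TRUE)
    for (param in parameters) {
      res <- spearman(merged[[covariate]], merged[[param]],
                      comparison_id = paste(covariate, r, param,
                                            sep = "."))
      rows[[paste(r, param)]] <- data.frame(
        covariate = covariate, region = r, parameter = param,
        r = res$statistic, p_raw = res$p_raw, n = res$n,
        stringsAsFactors = FALSE
      )
    }
  }
  grid <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  grid$p_adjusted <- fdr_adjust(grid$p_raw)
  grid$significant <- !is.na(grid$p_adjusted) & grid$p_adjusted < 0.05
  grid
}

#' Render a correlation grid as a parameter x region matrix
#'
#' Pivots the long grid returned by [build_grid()] into the familiar
#' table layout: parameters as rows, regions as columns.
#'
#' @param grid Data frame from [build_grid()].
#' @param value Which cell value to show (\code{"r"}, \code{"p_raw"},
#'   \code{"p_adjusted"} or \code{"n"}).
#' @return Numeric matrix.
#' @export
grid_matrix <- function(grid, value = "r") {
  stopifnot(value %in% names(grid))
  regions <- unique(grid$region)
  params <- unique(grid$parameter)
  m <- matrix(NA_real_, length(params), length(regions),
              dimnames = list(params, regions))
  for (i in seq_len(nrow(grid))) {
    m[grid$parameter[i], grid$region[i]] <- grid[[value]][i]
  }
  m
}
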
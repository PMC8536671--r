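#' Match detected objects to ground truth by nearest centroid
#'
#' Greedy one-to-one matching: detected/truth pairs are joined in order of
#' increasing centroid distance until the distance cap is reached. Used to
#' score detection against the simulator's ground truth.
#'
#' @param detected Data frame with \code{centroid_x_um}/\code{centroid_y_um}
#'   (e.g. from [detect()]).
#' @param truth Data frame of ground-truth objects ([simulate_fov()]
#'   \code{objects}).
#' @param max_dist_um Maximum centroid distance for a match (um).
#' @return List: \code{pairs} (data frame of matched row indices
#'   \code{det}, \code{truth} and their \code{dist_um}), \code{recall},
#'   \code{precision}.
#' @export
match_objects <- function(detected, truth, max_dist_um = 1) {
  nd <- nrow(detected)
  nt <- nrow(truth)
  if (nd == 0 || nt == 0) {
    return(list(pairs = data.frame(det = integer(0), truth = integer(0),
                                   dist_um = numeric(0)),
                recall = if (nt == 0) NA_real_ else 0,
                precision = if (nd == 0) NA_real_ else 0))
  }
  d2 <- outer(detected$centroid_x_um, truth$centroid_x_um, "-")^2 +
    outer(detected$centroid_y_um, truth$centroid_y_um, "-")^2
  ord <- order(d2)
  used_d <- logical(nd)
  used_t <- logical(nt)
  pairs <- list()
  for (k in ord) {
    if (d2[k] > max_dist_um^2) break
    i <- ((k - 1) %% nd) + 1
    j <- ((k - 1) %/% nd) + 1
    if (used_d[i] || used_t[j]) next
    used_d[i] <- TRUE
    used_t[j] <- TRUE
    pairs[[length(pairs) + 1]] <- data.frame(det = i, truth = j,
                                             dist_um = sqrt(d2[k]))
  }
  pairs <- if (length(pairs)) {
    do.call(rbind, c(pairs, list(make.row.names = FALSE)))
  } else {
    data.frame(det = integer(0), truth = integer(0), dist_um = numeric(0))
  }
  list(pairs = pairs, recall = nrow(pairs) / nt,
       precision = nrow(pairs) / nd)
}

#' Per-FOV summaries computed from simulator ground truth
#'
#' Builds the same five-parameter FOV summaries as [summarize_fov()], but
#' from the generator's ground-truth tables instead of detected objects.
#' This supports count-level studies (staging, correlation grids) without
#' rendering or re-detecting pixels.
#'
#' @param sim A [simulate_section()] or [simulate_cohort()] result (or any
#'   list with \code{objects} and \code{fovs} tables).
#' @return Data frame of per-FOV summaries with \code{section_id}.
#' @export
ground_truth_summaries <- function(sim) {
  fovs <- sim$fovs
  objects <- sim$objects
  rows <- lapply(seq_len(nrow(fovs)), function(i) {
    fid <- fovs$fov_id[i]
    d <- objects$true_diameter_um[objects$fov_id == fid]
    n <- length(d)
    data.frame(
      fov_id = fid,
      section_id = if ("section_id" %in% names(fovs))
        fovs$section_id[i] else NA_character_,
      region = fovs$region[i],
      count = n,
      area_fraction_pct = fovs$true_area_fraction_pct[i],
      mean_diameter_um = if (n) mean(d) else NA_real_,
      min_diameter_um = if (n) min(d) else NA_real_,
      max_diameter_um = if (n) max(d) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
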
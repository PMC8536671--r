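#' Build per-section regional profiles from FOV summaries
#'
#' Averages the per-FOV CoA counts within each pial-surface region of each
#' section and attaches the deep-white-matter involvement flags that the
#' stage classifier needs. The wall-of-lateral-ventricle flag is derived
#' from the section's \code{LV} fields (any CoA present); the
#' parahippocampal/fusiform flag lies outside the 14 sampled regions and
#' is taken from the optional \code{sections} table (default \code{FALSE}).
#'
#' @param fov_summaries Data frame of per-FOV summaries (see
#'   [summarize_fov()]) with a \code{section_id} column.
#' @param sections Optional data frame with \code{section_id} and a logical
#'   \code{deep_wm_phg_fusiform} column.
#' @return Data frame with one row per section: \code{section_id}, mean
#'   FOV count per pial region (columns named by region), and the two
#'   flags.
#' @export
build_section_profiles <- function(fov_summaries, sections = NULL) {
  stopifnot(all(c("section_id", "region", "count") %in%
                  names(fov_summaries)))
  ids <- unique(fov_summaries$section_id)
  rows <- lapply(ids, function(sid) {
    fs <- fov_summaries[fov_summaries$section_id == sid, , drop = FALSE]
    means <- vapply(pial_regions(), function(r) {
      v <- fs$count[fs$region == r]
      if (length(v)) mean(v) else 0
    }, numeric(1))
    lv <- fs$count[fs$region == "LV"]
    phg <- FALSE
    if (!is.null(sections)) {
      hit <- sections$deep_wm_phg_fusiform[sections$section_id == sid]
      if (length(hit)) phg <- isTRUE(hit[1])
    }
    cbind(data.frame(section_id = sid, stringsAsFactors = FALSE),
          as.data.frame(as.list(means)),
          data.frame(deep_wm_lv = length(lv) > 0 && sum(lv) > 0,
                     deep_wm_phg_fusiform = phg))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Classify one section into CoA stages 0-4
#'
#' Evaluates the staging ladder top-down on a section profile:
#' \itemize{
#'   \item Stage 4: deep white matter of the parahippocampal/fusiform gyri
#'     involved and fimbria pial-surface mean count >= 50.
#'   \item Stage 3: deep white matter of the wall of the lateral ventricle
#'     involved, fimbria count >= 50, and CoA present continuously across
#'     the prosubiculum and subiculum pial surfaces.
#'   \item Stage 2: fimbria count >= 10 with CoA present along the
#'     prosubiculum and subiculum pial surfaces.
#'   \item Stage 1: any CoA at the fimbria pial surface.
#'   \item Stage 0: no CoA.
#' }
#' The density bands printed with overlapping endpoints (0-10, 10-50,
#' 50-500) are resolved as half-open intervals, boundary values going to
#' the higher stage.
#'
#' @param profile One row of [build_section_profiles()] (data frame or
#'   list) with per-region mean counts and the two flags.
#' @return List of class \code{coa_stage}: \code{section_id}, \code{stage},
#'   \code{burden_score} and \code{criteria_trace} (named logical vector of
#'   the ladder tests).
#' @export
classify_stage <- function(profile) {
  fps <- profile$FPS
  trace <- c(
    phg_fusiform_deep_wm = isTRUE(profile$deep_wm_phg_fusiform),
    lv_deep_wm = isTRUE(profile$deep_wm_lv),
    fimbria_ge_50 = fps >= 50,
    fimbria_ge_10 = fps >= 10,
    fimbria_positive = fps > 0,
    pps_sps_present = profile$PPS > 0 && profile$SPS > 0
  )
  stage <- if (trace[["phg_fusiform_deep_wm"]] && trace[["fimbria_ge_50"]]) {
    4L
  } else if (trace[["lv_deep_wm"]] && trace[["fimbria_ge_50"]] &&
             trace[["pps_sps_present"]]) {
    3L
  } else if (trace[["fimbria_ge_10"]] && trace[["pps_sps_present"]]) {
    2L
  } else if (trace[["fimbria_positive"]]) {
    1L
  } else 0L
  structure(
    list(section_id = if (!is.null(profile$section_id))
           profile$section_id else NA_character_,
         stage = stage,
         burden_score = burden_score(profile),
         criteria_trace = trace),
    class = "coa_stage"
  )
}

#' Continuous CoA burden score of a section
#'
#' A computed replacement for the manual lowest-to-highest burden ranking:
#' the sum over pial-surface regions of \code{log1p(mean count)}, plus 2
#' when the wall-of-lateral-ventricle deep white matter is involved and a
#' further 4 for parahippocampal/fusiform involvement. Zero exactly when
#' the section carries no CoA, and strictly increasing in every regional
#' density. Only the induced rank order is interpreted; the weights are a
#' declared convention.
#'
#' @inheritParams classify_stage
#' @return Non-negative numeric score.
#' @export
burden_score <- function(profile) {
  counts <- vapply(pial_regions(), function(r) profile[[r]], numeric(1))
  stopifnot(all(counts >= 0))
  sum(log1p(counts)) + 2 * isTRUE(profile$deep_wm_lv) +
    4 * isTRUE(profile$deep_wm_phg_fusiform)
}

#' Stage every section and rank the cohort into a CoA sequence
#'
#' Applies [classify_stage()] to each profile and orders sections by
#' ascending burden score into the ranked CoA sequence (1 = lowest
#' burden). Ties are broken by \code{section_id}, so the sequence is
#' invariant to input order.
#'
#' @param profiles Data frame from [build_section_profiles()].
#' @return Data frame: \code{section_id}, \code{stage},
#'   \code{burden_score}, \code{rank}, \code{criteria_trace} (JSON
#'   string), sorted by rank.
#' @export
rank_sequence <- function(profiles) {
  stopifnot(nrow(profiles) >= 1)
  res <- lapply(seq_len(nrow(profiles)), function(i) {
    st <- classify_stage(profiles[i, , drop = FALSE])
    data.frame(section_id = st$section_id, stage = st$stage,
               burden_score = st$burden_score,
               criteria_trace = as.character(
                 jsonlite::toJSON(as.list(st$criteria_trace),
                                  auto_unbox = TRUE)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  res <- res[order(res$burden_score, res$section_id), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}
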
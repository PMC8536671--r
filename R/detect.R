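#' Binarize a micrograph into a CoA candidate mask
#'
#' Thresholds the grayscale image so that bright CoA candidates become
#' foreground. \code{method = "otsu"} computes Otsu's threshold on the
#' image (automating the manual black/white rendering step of the original
#' workflow); \code{method = "fixed"} applies a user-supplied intensity
#' level. Pixels strictly above the threshold are foreground.
#'
#' @param image A [micrograph()].
#' @param method \code{"otsu"} or \code{"fixed"}.
#' @param level Threshold intensity, required for \code{method = "fixed"};
#'   must lie within the 16-bit representable range [0, 65535].
#' @return Logical matrix of the same size as the image.
#' @export
binarize <- function(image, method = c("otsu", "fixed"), level = NULL) {
  stopifnot(inherits(image, "coa_micrograph"))
  method <- match.arg(method)
  pix <- image$pixels
  if (method == "otsu") {
    rng <- range(pix)
    if (rng[1] == rng[2]) {
      # constant image: nothing stands out from the background
      return(matrix(FALSE, nrow(pix), ncol(pix)))
    }
    # 256-level histogram: ample granularity for the bright-disc contrast
    thr <- EBImage::otsu(EBImage::Image(pix), range = rng, levels = 256)
  } else {
    if (is.null(level) || !is.finite(level) || level < 0 || level > 65535) {
      stop("fixed threshold level must be a finite intensity in [0, 65535]",
           call. = FALSE)
    }
    thr <- level
  }
  mask <- pix > thr
  if (all(mask)) {
    warning("threshold ", signif(thr, 6),
            " is below every pixel: full-foreground mask", call. = FALSE)
  }
  mask
}

## 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
## touch diagonally are merged afterwards with a union-find pass.
label_components8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  nr <- nrow(lab)
  nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  if (nrow(pairs) > 0) {
    parent <- seq_len(nlab)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(nlab), find, integer(1))
    lab[lab > 0] <- root[lab[lab > 0]]
  }
  lab
}

#' Extract measured objects from a binary mask
#'
#' Labels 8-connected foreground components and measures each one in
#' physical units: exact pixel-count area, centroid as the mean of pixel
#' centres (um, origin at the top-left corner, x rightward, y downward),
#' equivalent diameter \code{2 * sqrt(area / pi)}, and flags saying which
#' image borders the component touches. No size or border filtering is
#' applied here (see [filter_objects()]). Objects are ordered by their
#' first pixel in a row-major scan (top-to-bottom, then left-to-right).
#'
#' @param mask Logical (or 0/1) matrix.
#' @param calibration A [calibration()] matching the mask dimensions.
#' @param fov_id Identifier copied into the output.
#' @return Data frame with one row per component: \code{object_id},
#'   \code{pixel_count}, \code{area_um2}, \code{centroid_x_um},
#'   \code{centroid_y_um}, \code{equivalent_diameter_um},
#'   \code{touches_left}, \code{touches_right}, \code{touches_top},
#'   \code{touches_bottom}, \code{depth_um} (centroid distance from the top
#'   edge, the pial border convention for subpial fields).
#' @export
extract_objects <- function(mask, calibration, fov_id = "fov") {
  assert_calibration(calibration)
  mask <- mask != 0
  if (nrow(mask) != calibration$fov_height_px ||
      ncol(mask) != calibration$fov_width_px) {
    stop("mask is ", nrow(mask), " x ", ncol(mask),
         " but calibration declares ", calibration$fov_height_px, " x ",
         calibration$fov_width_px, call. = FALSE)
  }
  px <- calibration$pixel_size_um
  empty <- data.frame(
    fov_id = character(0), object_id = integer(0),
    pixel_count = integer(0), area_um2 = numeric(0),
    centroid_x_um = numeric(0), centroid_y_um = numeric(0),
    equivalent_diameter_um = numeric(0),
    touches_left = logical(0), touches_right = logical(0),
    touches_top = logical(0), touches_bottom = logical(0),
    depth_um = numeric(0), stringsAsFactors = FALSE
  )
  if (!any(mask)) return(empty)

  lab <- label_components8(mask)
  nr <- nrow(lab)
  nc <- ncol(lab)
  idx <- which(lab > 0)
  labels <- lab[idx]
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L

  pixel_count <- as.vector(tapply(labels, labels, length))
  cx <- as.vector(tapply((cols - 0.5) * px, labels, mean))
  cy <- as.vector(tapply((rows - 0.5) * px, labels, mean))
  t_left <- as.vector(tapply(cols == 1L, labels, any))
  t_right <- as.vector(tapply(cols == nc, labels, any))
  t_top <- as.vector(tapply(rows == 1L, labels, any))
  t_bottom <- as.vector(tapply(rows == nr, labels, any))
  # deterministic order: first pixel in a row-major scan
  first_rowmajor <- as.vector(tapply((rows - 1) * nc + cols, labels, min))
  ord <- order(first_rowmajor)

  area <- pixel_count * px^2
  out <- data.frame(
    fov_id = fov_id,
    object_id = seq_along(ord),
    pixel_count = as.integer(pixel_count[ord]),
    area_um2 = area[ord],
    centroid_x_um = cx[ord], centroid_y_um = cy[ord],
    equivalent_diameter_um = 2 * sqrt(area[ord] / pi),
    touches_left = t_left[ord], touches_right = t_right[ord],
    touches_top = t_top[ord], touches_bottom = t_bottom[ord],
    depth_um = cy[ord],
    stringsAsFactors = FALSE
  )
  out
}

#' Apply the minimum-size and counting-frame exclusion rules
#'
#' Retains exactly those objects with equivalent diameter >= 3 um that do
#' not intersect the left or bottom image border. The left/bottom exclusion
#' is the classical unbiased counting frame: when adjacent fields tile a
#' larger area, every object is counted in exactly one field. Objects
#' touching only the right or top border are kept. Input order is
#' preserved.
#'
#' @param objects Data frame from [extract_objects()].
#' @param min_diameter_um Minimum equivalent diameter (um), inclusive.
#' @return The retained subset of \code{objects}.
#' @export
filter_objects <- function(objects, min_diameter_um = 3) {
  keep <- objects$equivalent_diameter_um >= min_diameter_um &
    !objects$touches_left & !objects$touches_bottom
  objects[keep, , drop = FALSE]
}

#' Detect CoA in a micrograph
#'
#' The full per-field detection pipeline: [binarize()], [extract_objects()]
#' on the mask, then [filter_objects()] with the 3 um minimum size and the
#' left/bottom counting-frame exclusion. Deterministic for a fixed image
#' and method.
#'
#' @inheritParams binarize
#' @param min_diameter_um Minimum equivalent diameter (um).
#' @return Data frame of retained objects (see [extract_objects()]).
#' @export
detect <- function(image, method = c("otsu", "fixed"), level = NULL,
                   min_diameter_um = 3) {
  mask <- binarize(image, method = method, level = level)
  objects <- extract_objects(mask, image$calibration,
                             fov_id = image$fov_id)
  filter_objects(objects, min_diameter_um = min_diameter_um)
}
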
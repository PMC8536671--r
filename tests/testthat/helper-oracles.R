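# Independent oracles used across tests. These deliberately avoid the code
# paths they check: labelling by breadth-first search, BH by the literal
# step-up definition, pooled t by the closed form.

# 8-connected component labelling by BFS over a logical matrix.
bfs_label8 <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (cc in seq_len(nc)) {
    for (rr in seq_len(nr)) {
      if (!mask[rr, cc] || lab[rr, cc] != 0L) next
      cur <- cur + 1L
      queue <- list(c(rr, cc))
      lab[rr, cc] <- cur
      while (length(queue)) {
        p <- queue[[1]]
        queue <- queue[-1]
        for (dr in -1:1) for (dc in -1:1) {
          r2 <- p[1] + dr
          c2 <- p[2] + dc
          if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
              mask[r2, c2] && lab[r2, c2] == 0L) {
            lab[r2, c2] <- cur
            queue[[length(queue) + 1]] <- c(r2, c2)
          }
        }
      }
    }
  }
  lab
}

# Count of objects surviving the 3 um + left/bottom rules, straight from
# pixel sets.
brute_force_filtered_count <- function(mask, pixel_size_um,
                                       min_diameter_um = 3) {
  lab <- bfs_label8(mask)
  if (max(lab) == 0L) return(0L)
  n <- 0L
  nr <- nrow(mask)
  for (l in seq_len(max(lab))) {
    idx <- which(lab == l, arr.ind = TRUE)
    area <- nrow(idx) * pixel_size_um^2
    eq_d <- 2 * sqrt(area / pi)
    if (eq_d >= min_diameter_um && !any(idx[, "col"] == 1L) &&
        !any(idx[, "row"] == nr)) {
      n <- n + 1L
    }
  }
  n
}

# Literal Benjamini-Hochberg step-up.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Pooled-variance two-sample t statistic, closed form.
pooled_t <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Random blob mask: discs of random centre/radius stamped onto a field.
random_blob_mask <- function(nr, nc, n_blobs, r_px_range = c(2, 12)) {
  mask <- matrix(FALSE, nr, nc)
  for (i in seq_len(n_blobs)) {
    cy <- runif(1, 1, nr)
    cx <- runif(1, 1, nc)
    r <- runif(1, r_px_range[1], r_px_range[2])
    rows <- max(1, floor(cy - r)):min(nr, ceiling(cy + r))
    cols <- max(1, floor(cx - r)):min(nc, ceiling(cx + r))
    sub <- outer((rows - cy)^2, (cols - cx)^2, "+") <= r^2
    mask[rows, cols] <- mask[rows, cols] | sub
  }
  mask
}

small_cal <- function(w = 200L, h = 150L) calibration(w, h)

# Dilate a logical mask by one pixel (8-neighbourhood).
bfs_dilate <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  out <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    rt <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    ct <- max(1, 1 - dc):min(nc, nc - dc)
    out[rt, ct] <- out[rt, ct] | mask[rs, cs]
  }
  out
}
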
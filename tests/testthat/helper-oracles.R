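# Independent oracles and small fixture builders shared across tests.

# Exhaustive Otsu: maximize between-class variance over every candidate
# bin-edge threshold; ties broken by the lowest threshold.
brute_force_otsu <- function(m, n_bins = 256L) {
  v <- as.vector(m)
  bin <- pmin(floor(v * n_bins) + 1L, n_bins)
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  best_t <- NA_real_
  best_var <- -Inf
  for (k in seq_len(n_bins - 1L)) {
    lo <- bin <= k
    n0 <- sum(lo); n1 <- length(v) - n0
    if (n0 == 0 || n1 == 0) next
    w0 <- n0 / length(v)
    mu0 <- mean(centers[bin[lo]]); mu1 <- mean(centers[bin[!lo]])
    s <- w0 * (1 - w0) * (mu0 - mu1)^2
    if (s > best_var + 1e-15) {
      best_var <- s
      best_t <- k / n_bins
    }
  }
  best_t
}

# Naive set-morphology: Minkowski dilation/erosion by explicit translation.
brush_offsets <- function(brush) {
  idx <- which(brush > 0, arr.ind = TRUE)
  ctr <- (dim(brush) + 1) / 2
  cbind(idx[, 1] - ctr[1], idx[, 2] - ctr[2])
}

set_dilate <- function(mask, brush) {
  off <- brush_offsets(brush)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  pts <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(off))) {
    r <- pts[, 1] + off[i, 1]; c_ <- pts[, 2] + off[i, 2]
    ok <- r >= 1 & r <= nrow(mask) & c_ >= 1 & c_ <= ncol(mask)
    out[cbind(r[ok], c_[ok])] <- TRUE
  }
  out
}

set_erode <- function(mask, brush) {
  # A erode B = complement of (complement(A) dilate reflected B); with a
  # symmetric disk brush, erosion via: pixel kept iff all brush translates
  # inside mask (border treated as background).
  off <- brush_offsets(brush)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  pts <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(pts))) {
    r <- pts[k, 1] + off[, 1]; c_ <- pts[k, 2] + off[, 2]
    inside <- r >= 1 & r <= nrow(mask) & c_ >= 1 & c_ <= ncol(mask)
    out[pts[k, 1], pts[k, 2]] <- all(inside) && all(mask[cbind(r, c_)])
  }
  out
}

# pixel-distance disk mask
disk_mask <- function(h, w, center, radius) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  sqrt((rows - center[1])^2 + (cols - center[2])^2) <= radius
}

rot90_cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

# greedy centroid-in-disc matching of detections to ground truth
match_truth <- function(detections, truth) {
  tp <- 0L
  used <- rep(FALSE, length(detections))
  if (length(detections)) {
    cent <- t(vapply(detections, function(d) d$centroid, numeric(2)))
    for (k in seq_len(nrow(truth))) {
      d2 <- (cent[, 1] - truth$center_row[k])^2 +
            (cent[, 2] - truth$center_col[k])^2
      d2[used] <- Inf
      j <- which.min(d2)
      if (is.finite(d2[j]) && d2[j] <= truth$radius_px[k]^2) {
        tp <- tp + 1L
        used[j] <- TRUE
      }
    }
  }
  list(tp = tp,
       recall = tp / nrow(truth),
       precision = if (length(detections)) tp / length(detections) else 0)
}

f1_score <- function(detections, truth) {
  m <- match_truth(detections, truth)
  if (m$precision + m$recall == 0) return(0)
  2 * m$precision * m$recall / (m$precision + m$recall)
}

# minimal synthetic detection object for numbering/merging unit tests
fake_detection <- function(centroid, area_px, roi_index = 1L, pixels = integer(0)) {
  structure(list(label = NA_integer_,
                 contour = matrix(numeric(0), 0, 2),
                 centroid = centroid, area_px = area_px,
                 area_um2 = area_px, circularity = 1,
                 equivalent_diameter_um = 2 * sqrt(area_px / pi),
                 touches_border = FALSE, roi_index = roi_index,
                 pixels = pixels),
            class = "sphere_detection")
}
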
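#' Sobel gradient field
#'
#' Convolves the image with the two 3x3 Sobel kernels
#' `Gx = [[-1,0,1],[-2,0,2],[-1,0,1]]` and `Gy = t(Gx)` (reflective
#' borders), and derives the gradient magnitude `G = sqrt(Gx^2 + Gy^2)`
#' and direction `theta = atan2(Gy, Gx)` per pixel.
#'
#' @param image A [gray_image] or numeric matrix, at least 3x3.
#' @return A list of class `gradient_field` with matrices `Gx`, `Gy`, `G`,
#'   `theta` (radians in `(-pi, pi]`).
#' @export
sobel <- function(image) {
  m <- px_matrix(image)
  if (nrow(m) < 3 || ncol(m) < 3) {
    stop(sprintf("image %d x %d too small for the 3x3 Sobel kernels",
                 nrow(m), ncol(m)), call. = FALSE)
  }
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)   # columns: -1,0,+1
  ky <- t(kx)
  gx <- conv2_reflect(m, kx)
  gy <- conv2_reflect(m, ky)
  structure(list(Gx = gx, Gy = gy,
                 G = sqrt(gx^2 + gy^2),
                 theta = atan2(gy, gx)),
            class = "gradient_field")
}

#' Otsu threshold
#'
#' Builds an `n_bins` histogram over `[0, 1]` and returns the bin-edge
#' threshold that maximizes the between-class variance; ties are broken by
#' the lowest qualifying threshold. Pixels strictly above the threshold
#' form the upper class.
#'
#' @param image A [gray_image] or numeric matrix in `[0, 1]`.
#' @param n_bins Number of histogram bins (>= 2; default 256).
#' @return Threshold in `[0, 1]`.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  m <- px_matrix(image)
  stopifnot(n_bins >= 2)
  if (diff(range(m)) == 0) {
    stop("degenerate histogram: image is constant", call. = FALSE)
  }
  bin <- pmin(floor(as.vector(m) * n_bins) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  n <- length(bin)
  p <- counts / n
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  w0 <- cumsum(p)                       # weight of class {bins <= k}
  mu0 <- cumsum(p * centers)
  mu_t <- mu0[n_bins]
  k <- seq_len(n_bins - 1L)
  valid <- w0[k] > 0 & w0[k] < 1
  sigma_b <- rep(-Inf, n_bins - 1L)
  sigma_b[valid] <- (mu_t * w0[k][valid] - mu0[k][valid])^2 /
    (w0[k][valid] * (1 - w0[k][valid]))
  best <- which.max(sigma_b)            # which.max returns the first (lowest) maximum
  best / n_bins
}

#' Adaptive (local-mean) threshold
#'
#' A pixel is foreground iff its intensity exceeds the mean over the
#' surrounding `block_size` x `block_size` window minus `offset` (window
#' means use reflective borders).
#'
#' @param image A [gray_image] or numeric matrix.
#' @param block_size Odd window side in pixels, >= 3.
#' @param offset Intensity offset subtracted from the local mean; positive
#'   values make the test more permissive.
#' @return A logical matrix (`TRUE` = foreground).
#' @export
adaptive_threshold <- function(image, block_size, offset = 0.02) {
  m <- px_matrix(image)
  block_size <- as.integer(block_size)
  if (block_size < 3L || block_size %% 2L == 0L) {
    stop("'block_size' must be an odd integer >= 3", call. = FALSE)
  }
  k <- matrix(1 / block_size^2, block_size, block_size)
  local_mean <- conv2_reflect(m, k)
  m > (local_mean - offset)
}

#' Morphological closing followed by dilation
#'
#' Closing (dilation then erosion) fills background holes; the final
#' dilation enlarges foreground boundaries. Both use a disk structuring
#' element of the given radius, so the output always contains the input.
#'
#' @param mask Logical or 0/1 matrix.
#' @param radius Disk radius in pixels, >= 1.
#' @return Logical matrix.
#' @export
morph_close_dilate <- function(mask, radius = 2) {
  stopifnot(radius >= 1)
  m <- (px_mask(mask)) * 1
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  out <- EBImage::dilate(EBImage::closing(m, brush), brush)
  matrix(as.numeric(out) > 0.5, nrow(m), ncol(m))
}

px_mask <- function(mask) {
  if (is.logical(mask)) return(mask)
  if (is.matrix(mask) && is.numeric(mask)) return(mask > 0.5)
  stop("expected a logical or numeric matrix mask", call. = FALSE)
}

# Connected-component labeling with 8-connectivity.
#
# EBImage::bwlabel is 4-connected; labels whose components touch
# diagonally are merged with a union-find pass over the two diagonal
# neighbor shifts.
label_components <- function(mask) {
  m <- px_mask(mask)
  lab0 <- EBImage::bwlabel(m * 1)
  lab <- matrix(as.integer(lab0), nrow(m), ncol(m))
  n <- max(lab)
  if (n <= 1) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    invisible(NULL)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbor pairs: (r, c) vs (r + 1, c + 1) and (r + 1, c - 1)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs) > 0) {
    pairs <- unique(pairs)
    for (i in seq_len(nrow(pairs))) union_(pairs[i, 1], pairs[i, 2])
  }
  root <- vapply(seq_len(n), find, integer(1))
  relabel <- match(root, sort(unique(root)))
  out <- matrix(0L, nr, nc)
  nz <- lab > 0
  out[nz] <- relabel[lab[nz]]
  out
}
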
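#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Homogenizes contrast across an image by equalizing the histogram of
#' each tile of a grid, with per-bin counts clipped at a fraction of the
#' tile's pixel count (the clipped excess is redistributed uniformly so
#' noise in flat tiles is not amplified). Each tile's mapping sends a bin
#' to the mid-CDF value (the average of the CDF just below and at the
#' bin), which leaves a constant image unchanged; pixels are remapped by
#' bilinear interpolation between the mappings of the four surrounding
#' tile centers, so tile seams are invisible.
#'
#' With a 1x1 grid and `clip_limit = 1` this reduces to global histogram
#' equalization; as `clip_limit` approaches 0 the clipped histogram tends
#' to uniform and the output approaches the input (up to bin
#' quantization).
#'
#' @param image A [gray_image] or numeric matrix in `[0, 1]`.
#' @param clip_limit Fraction in `(0, 1]` of the tile pixel count at which
#'   each histogram bin is clipped.
#' @param tile_grid Integer `(rows, cols)` of the tile grid. If a tile
#'   would be smaller than one pixel (grid exceeds the image size), the
#'   grid falls back to a single global tile with a warning.
#' @param n_bins Number of histogram bins (default 256).
#' @return Object of the same kind as the input, intensities in `[0, 1]`.
#' @export
clahe <- function(image, clip_limit = 0.01, tile_grid = c(8L, 8L), n_bins = 256L) {
  m <- px_matrix(image)
  stopifnot(clip_limit > 0, clip_limit <= 1, n_bins >= 2)
  nr_t <- as.integer(tile_grid[1]); nc_t <- as.integer(tile_grid[2])
  stopifnot(nr_t >= 1, nc_t >= 1)
  h <- nrow(m); w <- ncol(m)
  if (nr_t > h || nc_t > w) {
    warning(sprintf("tile grid %dx%d exceeds image %dx%d; using one global tile",
                    nr_t, nc_t, h, w), call. = FALSE)
    nr_t <- 1L; nc_t <- 1L
  }

  bin <- pmin(floor(m * n_bins) + 1L, n_bins)            # h x w bin index
  # tile membership of each row/column
  row_tile <- pmin(((seq_len(h) - 1L) * nr_t) %/% h + 1L, nr_t)
  col_tile <- pmin(((seq_len(w) - 1L) * nc_t) %/% w + 1L, nc_t)

  # per-tile clipped-histogram LUTs: n_bins x (nr_t * nc_t)
  lut <- matrix(0, n_bins, nr_t * nc_t)
  for (ti in seq_len(nr_t)) {
    for (tj in seq_len(nc_t)) {
      rows <- which(row_tile == ti); cols <- which(col_tile == tj)
      b <- bin[rows, cols]
      n <- length(b)
      hist_counts <- tabulate(b, nbins = n_bins)
      cl <- max(clip_limit * n, 1)
      clipped <- pmin(hist_counts, cl)
      excess <- n - sum(clipped)
      clipped <- clipped + excess / n_bins
      cdf <- cumsum(clipped) / n
      lut[, (tj - 1L) * nr_t + ti] <- (cdf + c(0, cdf[-n_bins])) / 2
    }
  }

  # tile centers (in pixel coordinates) for bilinear interpolation
  tile_center <- function(k, n_tiles, extent) {
    lo <- floor((k - 1L) * extent / n_tiles) + 1L
    hi <- floor(k * extent / n_tiles)
    (lo + hi) / 2
  }
  rc <- tile_center(seq_len(nr_t), nr_t, h)
  cc <- tile_center(seq_len(nc_t), nc_t, w)

  interp1 <- function(pos, centers) {
    n <- length(centers)
    i0 <- findInterval(pos, centers)
    i0 <- pmin(pmax(i0, 1L), max(n - 1L, 1L))
    i1 <- pmin(i0 + 1L, n)
    span <- centers[i1] - centers[i0]
    wgt <- ifelse(span > 0, (pos - centers[i0]) / span, 0)
    wgt <- pmin(pmax(wgt, 0), 1)
    list(i0 = i0, i1 = i1, w = wgt)
  }
  ri <- interp1(seq_len(h), rc)
  ci <- interp1(seq_len(w), cc)

  # expand to full h x w index/weight fields
  R0 <- matrix(ri$i0, h, w); R1 <- matrix(ri$i1, h, w)
  WR <- matrix(ri$w,  h, w)
  C0 <- matrix(ci$i0, h, w, byrow = TRUE); C1 <- matrix(ci$i1, h, w, byrow = TRUE)
  WC <- matrix(ci$w,  h, w, byrow = TRUE)

  lut_at <- function(R, C) lut[cbind(as.vector(bin), (as.vector(C) - 1L) * nr_t + as.vector(R))]
  out <- (1 - WR) * (1 - WC) * lut_at(R0, C0) +
         (1 - WR) * WC       * lut_at(R0, C1) +
         WR       * (1 - WC) * lut_at(R1, C0) +
         WR       * WC       * lut_at(R1, C1)
  out <- matrix(pmin(pmax(out, 0), 1), h, w)
  rewrap(image, out)
}

#' Gaussian smoothing
#'
#' Convolution with a normalized isotropic Gaussian kernel truncated at
#' four sigma, with reflective boundary handling, so the mean intensity of
#' interior-dominated images is preserved.
#'
#' @param image A [gray_image] or numeric matrix in `[0, 1]`.
#' @param sigma Standard deviation in pixels; strictly positive.
#' @return Smoothed image of the same kind as the input.
#' @export
gaussian_smooth <- function(image, sigma = 1.0) {
  if (!is.numeric(sigma) || length(sigma) != 1 || is.na(sigma) || sigma <= 0) {
    stop("'sigma' must be a single positive number", call. = FALSE)
  }
  m <- px_matrix(image)
  k <- gaussian_kernel(sigma)
  out <- conv2_reflect(m, k)
  rewrap(image, pmin(pmax(out, 0), 1))
}

# normalized 2-d Gaussian kernel truncated at 4*sigma (odd size)
gaussian_kernel <- function(sigma) {
  half <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- seq.int(-half, half)
  g1 <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g1, g1)
  k / sum(k)
}

# preserve the container kind of the input (gray_image in, gray_image out)
rewrap <- function(template, pixels) {
  if (inherits(template, "gray_image")) {
    gray_image(pixels, source_path = template$source_path,
               bit_depth_original = template$bit_depth_original)
  } else {
    pixels
  }
}
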
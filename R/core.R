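#' Grayscale image container
#'
#' A light wrapper around a numeric matrix of intensities in `[0, 1]`,
#' in (row, column) layout: the origin is the top-left pixel, row indices
#' increase downward and column indices increase rightward (1-based, as
#' usual in R). Pixel-level metadata (source path, original bit depth) is
#' carried along so reports can cite provenance.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]`.
#' @param source_path Optional path the raster was read from (`""` if
#'   constructed in memory).
#' @param bit_depth_original Integer bit depth of the source file, or `NA`
#'   when unknown or synthetic. Intensities are always normalized to
#'   `[0, 1]` at load; the original depth is metadata only.
#' @return An object of class `gray_image`.
#' @examples
#' img <- gray_image(matrix(runif(32 * 32), 32, 32))
#' dim(img)
#' @export
gray_image <- function(pixels, source_path = "", bit_depth_original = NA_integer_) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("'pixels' must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(pixels)) stop("'pixels' contains NA values", call. = FALSE)
  rng <- range(pixels)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    stop(sprintf("intensities must lie in [0, 1]; observed range [%.4g, %.4g]",
                 rng[1], rng[2]), call. = FALSE)
  }
  pixels[] <- pmin(pmax(pixels, 0), 1)
  structure(
    list(pixels = pixels,
         source_path = as.character(source_path),
         bit_depth_original = as.integer(bit_depth_original)),
    class = "gray_image"
  )
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, intensity range [%.3f, %.3f]%s\n",
              nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels),
              if (nzchar(x$source_path)) paste0(", from ", x$source_path) else ""))
  invisible(x)
}

#' @export
as.matrix.gray_image <- function(x, ...) x$pixels

# Accept either a gray_image or a bare matrix everywhere downstream.
px_matrix <- function(image) {
  if (inherits(image, "gray_image")) return(image$pixels)
  if (is.matrix(image) && is.numeric(image)) return(image)
  stop("expected a 'gray_image' or a numeric matrix", call. = FALSE)
}

# Assert the raster is large enough to enter the pipeline.
check_pipeline_entry <- function(image) {
  m <- px_matrix(image)
  if (nrow(m) < 16 || ncol(m) < 16) {
    stop(sprintf("image too small for pipeline entry: %d x %d (need >= 16 x 16)",
                 nrow(m), ncol(m)), call. = FALSE)
  }
  invisible(m)
}

#' Convert an RGB or grayscale raster to a normalized grayscale image
#'
#' Three-channel input is combined with the ITU-R BT.601 luma weights
#' 0.299/0.587/0.114; single-channel input is only rescaled. Integer-coded
#' samples are normalized by the smallest standard full-scale value (255
#' for 8-bit, 65535 for 16-bit) that covers the observed range; float
#' samples already in `[0, 1]` pass through unchanged.
#'
#' @param image A numeric matrix (grayscale) or a 3-d array with the third
#'   dimension of extent 1 or 3, in (row, column, channel) layout.
#' @param source_path Provenance string stored in the result.
#' @return A [gray_image].
#' @examples
#' rgb <- array(0, dim = c(4, 4, 3))
#' rgb[, , 1] <- 255
#' to_gray(rgb)$pixels[1, 1]  # 0.299
#' @export
to_gray <- function(image, source_path = "") {
  if (inherits(image, "gray_image")) return(image)
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  if (!is.array(image) || length(dim(image)) != 3L) {
    stop(sprintf("unsupported raster for '%s': expected matrix or 3-d array, got dims [%s]",
                 source_path, paste(dim(image), collapse = " x ")), call. = FALSE)
  }
  nch <- dim(image)[3]
  if (!nch %in% c(1L, 3L)) {
    stop(sprintf("unsupported channel count for '%s': %d channels (shape %s); need 1 or 3",
                 source_path, nch, paste(dim(image), collapse = " x ")), call. = FALSE)
  }
  bit_depth <- NA_integer_
  mx <- max(image)
  if (is.integer(image) || mx > 1 + 1e-9) {
    full_scale <- if (mx <= 255) 255 else 65535
    bit_depth <- if (full_scale == 255) 8L else 16L
    image <- image / full_scale
  }
  gray <- if (nch == 3L) {
    0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  } else {
    image[, , 1]
  }
  gray <- matrix(gray, dim(image)[1], dim(image)[2])
  gray_image(pmin(pmax(gray, 0), 1), source_path = source_path,
             bit_depth_original = bit_depth)
}

#' Microscope calibration: magnification label and pixel size
#'
#' The physical pixel size depends on the objective *and* the camera
#' sensor, so it must be supplied by the user; the package never defaults
#' it silently. Areas scale with the square of the pixel size.
#'
#' @param magnification Label such as `"4x"`, `"10x"`, `"40x"`.
#' @param microns_per_pixel Physical size of one pixel in micrometers;
#'   strictly positive.
#' @return An object of class `calibration`.
#' @examples
#' cal <- calibration("10x", 0.65)
#' pixels_to_um2(400, calibration("4x", 0.5))  # 100
#' @export
calibration <- function(magnification, microns_per_pixel) {
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1 ||
      is.na(microns_per_pixel) || microns_per_pixel <= 0) {
    stop("'microns_per_pixel' must be a single positive number", call. = FALSE)
  }
  structure(list(magnification = as.character(magnification),
                 microns_per_pixel = as.numeric(microns_per_pixel)),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> %s, %.4g um/px (%.4g um^2/px^2)\n",
              x$magnification, x$microns_per_pixel, x$microns_per_pixel^2))
  invisible(x)
}

#' Convert a pixel area to square micrometers
#'
#' @param area_px Pixel count (non-negative).
#' @param cal A [calibration].
#' @return `area_px * microns_per_pixel^2`, in square micrometers.
#' @export
pixels_to_um2 <- function(area_px, cal) {
  stopifnot(inherits(cal, "calibration"))
  if (any(area_px < 0)) stop("'area_px' must be non-negative", call. = FALSE)
  area_px * cal$microns_per_pixel^2
}

#' Pipeline configuration
#'
#' Collects every tunable of the detection pipeline with validated
#' defaults. All defaults are exposed so they can be overridden from a
#' config file or CLI flags.
#'
#' @param clahe_clip_limit Contrast clip limit, a fraction in `(0, 1]` of
#'   each tile's pixel count; 1 means unclipped equalization.
#' @param clahe_tile_grid Integer `(rows, cols)` tile grid for CLAHE.
#' @param gaussian_sigma Gaussian smoothing sigma in pixels.
#' @param gabor_spec A [gabor_bank_spec].
#' @param roi_min_side_px Minimum side of an accepted region of interest,
#'   in pixels; `NA` selects the resolution-dependent rule
#'   `max(16, min(height, width) / 64)`.
#' @param roi_padding_px Padding added around each proposed region.
#' @param min_sphere_area_um2 Detections smaller than this calibrated area
#'   are discarded as debris.
#' @param min_circularity Detections with `4*pi*A/P^2` below this are
#'   discarded (erythrocyte/crystal guard).
#' @param struct_element_radius_px Disk radius of the morphological
#'   structuring element.
#' @param adaptive_block_fraction Adaptive-threshold block size as a
#'   fraction of the shorter image side (rounded to the nearest odd px).
#' @param adaptive_offset Adaptive-threshold offset in intensity units.
#' @param sphere_polarity `"auto"`, `"bright"` or `"dark"`: whether
#'   spheres are brighter or darker than their local background; `"auto"`
#'   compares the ROI center patch with its border frame.
#' @param seed Integer seed; consumed only by synthetic generation.
#' @return An object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(clahe_clip_limit = 0.01,
                            clahe_tile_grid = c(8L, 8L),
                            gaussian_sigma = 1.0,
                            gabor_spec = gabor_bank_spec(),
                            roi_min_side_px = NA_real_,
                            roi_padding_px = 12,
                            min_sphere_area_um2 = 300,
                            min_circularity = 0.4,
                            struct_element_radius_px = 2,
                            adaptive_block_fraction = 1 / 8,
                            adaptive_offset = 0.02,
                            sphere_polarity = c("auto", "bright", "dark"),
                            seed = 1L) {
  sphere_polarity <- match.arg(sphere_polarity)
  stopifnot(
    clahe_clip_limit > 0, clahe_clip_limit <= 1,
    length(clahe_tile_grid) == 2, all(clahe_tile_grid >= 1),
    gaussian_sigma > 0,
    inherits(gabor_spec, "gabor_bank_spec"),
    is.na(roi_min_side_px) || roi_min_side_px > 0,
    roi_padding_px >= 0,
    min_sphere_area_um2 > 0,
    min_circularity >= 0, min_circularity <= 1,
    struct_element_radius_px >= 1,
    adaptive_block_fraction > 0, adaptive_block_fraction < 1
  )
  structure(list(
    clahe_clip_limit = clahe_clip_limit,
    clahe_tile_grid = as.integer(clahe_tile_grid),
    gaussian_sigma = gaussian_sigma,
    gabor_spec = gabor_spec,
    roi_min_side_px = roi_min_side_px,
    roi_padding_px = roi_padding_px,
    min_sphere_area_um2 = min_sphere_area_um2,
    min_circularity = min_circularity,
    struct_element_radius_px = struct_element_radius_px,
    adaptive_block_fraction = adaptive_block_fraction,
    adaptive_offset = adaptive_offset,
    sphere_polarity = sphere_polarity,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}
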
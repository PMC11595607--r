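#' Summarize detections for one image
#'
#' @param image The analyzed [gray_image] (for the image area and
#'   provenance).
#' @param detections Numbered detections from [detect_spheres()].
#' @param cal The [calibration] used.
#' @param processing_time_s Optional elapsed seconds (informational).
#' @return An `image_report`: source path, magnification, `sphere_count`,
#'   the detections, `total_area_um2` and `percent_area` (percentage of
#'   the image area covered by detections).
#' @export
summarize_image <- function(image, detections, cal, processing_time_s = NA_real_) {
  m <- px_matrix(image)
  stopifnot(inherits(cal, "calibration"))
  total_px <- sum(vapply(detections, function(d) d$area_px, 0))
  image_area_um2 <- pixels_to_um2(nrow(m) * ncol(m), cal)
  structure(list(
    source_path = if (inherits(image, "gray_image")) image$source_path else "",
    magnification = cal$magnification,
    sphere_count = length(detections),
    detections = detections,
    total_area_um2 = pixels_to_um2(total_px, cal),
    percent_area = 100 * total_px / (nrow(m) * ncol(m)),
    image_area_um2 = image_area_um2,
    processing_time_s = processing_time_s
  ), class = "image_report")
}

#' @export
print.image_report <- function(x, ...) {
  cat(sprintf("<image_report> %s: %d spheres, %.1f um^2 total (%.2f%% of image)\n",
              if (nzchar(x$source_path)) basename(x$source_path) else "<in memory>",
              x$sphere_count, x$total_area_um2, x$percent_area))
  invisible(x)
}

#' Sphere formation efficiency
#'
#' The percentage of seeded cells that grew into a sphere:
#' `SFE% = 100 * n_spheres / n_seeded`.
#'
#' @param n_spheres Number of spheres counted (>= 0).
#' @param n_seeded Number of cells seeded (> 0).
#' @return A list of class `sfe_result` with `n_spheres`, `n_seeded` and
#'   `sfe_percent`.
#' @examples
#' sphere_formation_efficiency(5, 1000)$sfe_percent  # 0.5
#' @export
sphere_formation_efficiency <- function(n_spheres, n_seeded) {
  if (!is.numeric(n_seeded) || length(n_seeded) != 1 || is.na(n_seeded) ||
      n_seeded <= 0) {
    stop("'n_seeded' must be a single positive count", call. = FALSE)
  }
  if (!is.numeric(n_spheres) || length(n_spheres) != 1 || is.na(n_spheres) ||
      n_spheres < 0) {
    stop("'n_spheres' must be a single non-negative count", call. = FALSE)
  }
  structure(list(n_spheres = n_spheres, n_seeded = n_seeded,
                 sfe_percent = 100 * n_spheres / n_seeded),
            class = "sfe_result")
}

#' @export
print.sfe_result <- function(x, ...) {
  cat(sprintf("<sfe_result> %g / %g seeded = %.4g%%\n",
              x$n_spheres, x$n_seeded, x$sfe_percent))
  invisible(x)
}
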
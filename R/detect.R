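#' Propose regions of interest from the Gabor texture response
#'
#' The aggregate response is thresholded at the local mean plus 5% of the
#' global response range (so a perfectly flat response yields no regions),
#' closed and dilated morphologically, and 8-connected components are
#' taken. Each component's bounding box is padded by `roi_padding_px` and
#' clipped to the image; boxes with a side below `roi_min_side_px`
#' (default: the resolution rule `max(16, min(height, width) / 64)`) are
#' discarded, as are thin, sparsely filled components such as chamber-wall
#' rings (component fill below 15% of its bounding box). Regions are
#' sorted by `(r0, c0)`.
#'
#' @param response A `gabor_response` from [apply_gabor_bank()].
#' @param cfg A [pipeline_config].
#' @return A list of regions, each `list(box = c(r0, r1, c0, c1), score)`
#'   with 1-based inclusive bounds and `score` the mean aggregate response
#'   inside the box. The empty list is a valid outcome.
#' @export
propose_rois <- function(response, cfg = pipeline_config()) {
  stopifnot(inherits(response, "gabor_response"))
  a <- response$aggregate
  h <- nrow(a); w <- ncol(a)
  rng <- range(a)
  if (diff(rng) < 1e-9) return(list())

  block <- odd_block(cfg$adaptive_block_fraction * min(h, w))
  local_mean <- conv2_reflect(a, matrix(1 / block^2, block, block))
  fg <- a > local_mean + 0.05 * diff(rng)
  if (!any(fg)) return(list())
  cleaned <- morph_close_dilate(fg, cfg$struct_element_radius_px)
  labels <- label_components(cleaned)
  n <- max(labels)
  if (n == 0) return(list())

  min_side <- if (is.na(cfg$roi_min_side_px)) {
    max(16, floor(min(h, w) / 64))
  } else cfg$roi_min_side_px
  pad <- cfg$roi_padding_px

  rois <- list()
  for (i in seq_len(n)) {
    idx <- which(labels == i, arr.ind = TRUE)
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    if ((r1 - r0 + 1) < min_side || (c1 - c0 + 1) < min_side) next
    fill <- nrow(idx) / ((r1 - r0 + 1) * (c1 - c0 + 1))
    if (fill < 0.15) next
    box <- c(max(1, r0 - pad), min(h, r1 + pad),
             max(1, c0 - pad), min(w, c1 + pad))
    rois[[length(rois) + 1L]] <- list(
      box = box,
      score = mean(a[box[1]:box[2], box[3]:box[4]])
    )
  }
  if (length(rois) > 1) {
    ord <- order(vapply(rois, function(r) r$box[1], 0),
                 vapply(rois, function(r) r$box[3], 0))
    rois <- rois[ord]
  }
  rois
}

odd_block <- function(x) {
  b <- max(3L, as.integer(round(x)))
  if (b %% 2L == 0L) b + 1L else b
}

#' Extract sphere detections from regions of interest
#'
#' Within each region: the intensity mask from the Otsu threshold (upper
#' or lower class per the configured polarity; `"auto"` compares the
#' region's center patch with its border frame) is united with the
#' Otsu-thresholded Sobel edge magnitude, cleaned with
#' [morph_close_dilate()], and 8-connected components are taken. Edge
#' bands and the final dilation serve connectivity only: objects are
#' measured on the hole-filled intensity support inside each component
#' (falling back to the eroded filled component when that support is
#' empty), so sizes are not inflated by the structuring element, and each
#' connected fragment of that support becomes its own detection — the
#' cleaned union can bridge close neighbors whose intensity supports are
#' clearly disjoint. Objects smaller than `min_sphere_area_um2` or less
#' round than `min_circularity` are discarded; duplicates from
#' overlapping regions (pixel IoU > 0.5, or overlap > 50% of the smaller)
#' are merged keeping the larger.
#'
#' @param image The (preprocessed) [gray_image] or matrix the regions
#'   refer to.
#' @param rois Regions from [propose_rois()].
#' @param cfg A [pipeline_config].
#' @param cal A [calibration].
#' @return A list of `sphere_detection` objects (unlabeled; see
#'   [number_spheres()]).
#' @export
extract_spheres <- function(image, rois, cfg = pipeline_config(), cal) {
  m <- px_matrix(image)
  stopifnot(inherits(cal, "calibration"))
  h <- nrow(m); w <- ncol(m)
  detections <- list()
  for (ri in seq_along(rois)) {
    box <- rois[[ri]]$box
    if (box[1] < 1 || box[2] > h || box[3] < 1 || box[4] > w ||
        box[1] > box[2] || box[3] > box[4]) {
      stop(sprintf("ROI %d out of bounds: [%d, %d] x [%d, %d] in %d x %d image",
                   ri, box[1], box[2], box[3], box[4], h, w), call. = FALSE)
    }
    sub <- m[box[1]:box[2], box[3]:box[4], drop = FALSE]
    if (diff(range(sub)) < 1e-9) next   # degenerate histogram: background only
    dets <- extract_in_roi(sub, cfg, cal, box, ri, c(h, w))
    detections <- c(detections, dets)
  }
  merge_duplicates(detections)
}

extract_in_roi <- function(sub, cfg, cal, box, roi_index, image_dim) {
  thr <- otsu_threshold(sub)
  bright <- sub > thr
  polarity <- cfg$sphere_polarity
  if (polarity == "auto") {
    # regions are padded, so their border frame is background: the class
    # that dominates the frame is the background class
    hh <- nrow(sub); ww <- ncol(sub)
    frame_mask <- matrix(TRUE, hh, ww)
    if (hh > 2 && ww > 2) frame_mask[2:(hh - 1), 2:(ww - 1)] <- FALSE
    polarity <- if (mean(bright[frame_mask]) <= 0.5) "bright" else "dark"
  }
  fg <- if (polarity == "bright") bright else !bright

  g <- sobel(sub)$G
  edge_mask <- matrix(FALSE, nrow(sub), ncol(sub))
  if (diff(range(g)) > 1e-9) {
    gn <- (g - min(g)) / diff(range(g))
    edge_mask <- gn > otsu_threshold(gn)
  }

  cleaned <- morph_close_dilate(fg | edge_mask, cfg$struct_element_radius_px)
  labels <- label_components(cleaned)
  n <- max(labels)
  if (n == 0) return(list())

  filled_fg <- as_mask(EBImage::fillHull(fg * 1))
  brush <- EBImage::makeBrush(2L * as.integer(cfg$struct_element_radius_px) + 1L,
                              shape = "disc")
  out <- list()
  for (i in seq_len(n)) {
    comp <- labels == i
    meas_all <- comp & filled_fg
    if (!any(meas_all)) {
      meas_all <- as_mask(EBImage::erode(EBImage::fillHull(comp * 1), brush))
      if (!any(meas_all)) next
    }
    # the cleaned union groups candidate pixels, but the edge bands and
    # dilation can bridge neighboring objects: each connected fragment of
    # the intensity support is its own detection
    frag <- label_components(meas_all)
    for (fi in seq_len(max(frag))) {
      meas <- frag == fi
      det <- measure_object(meas, cfg, cal, box, roi_index, image_dim)
      if (!is.null(det)) out[[length(out) + 1L]] <- det
    }
  }
  out
}

# size/shape filters plus feature extraction for one measured object;
# NULL when the object is rejected as debris
measure_object <- function(meas, cfg, cal, box, roi_index, image_dim) {
  area_px <- sum(meas)
  area_um2 <- pixels_to_um2(area_px, cal)
  if (area_um2 < cfg$min_sphere_area_um2) return(NULL)

  idx <- which(meas, arr.ind = TRUE)
  centroid <- c(mean(idx[, 1]), mean(idx[, 2]))
  contour <- largest_contour(meas)
  perim <- contour_length(contour)
  circ <- if (perim > 0) 4 * pi * area_px / perim^2 else 0
  if (circ < cfg$min_circularity) return(NULL)
  # to full-image coordinates
  contour_full <- cbind(contour[, 1] + box[1] - 1L, contour[, 2] + box[3] - 1L)
  idx_full <- cbind(idx[, 1] + box[1] - 1L, idx[, 2] + box[3] - 1L)
  touches <- any(idx_full[, 1] == 1 | idx_full[, 1] == image_dim[1] |
                 idx_full[, 2] == 1 | idx_full[, 2] == image_dim[2])
  structure(list(
    label = NA_integer_,
    contour = contour_full,
    centroid = c(centroid[1] + box[1] - 1, centroid[2] + box[3] - 1),
    area_px = area_px,
    area_um2 = area_um2,
    circularity = circ,
    equivalent_diameter_um = 2 * sqrt(area_um2 / pi),
    touches_border = touches,
    roi_index = roi_index,
    pixels = (idx_full[, 2] - 1L) * image_dim[1] + idx_full[, 1]
  ), class = "sphere_detection")
}

as_mask <- function(x) {
  d <- dim(x)
  matrix(as.numeric(x) > 0.5, d[1], d[2])
}

# outer contour of the largest 8-connected fragment of a mask,
# as 1-based (row, col) coordinates
largest_contour <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) > 1) {
    sizes <- tabulate(lab[lab > 0])
    mask <- lab == which.max(sizes)
  }
  oc <- EBImage::ocontour(mask * 1)
  if (length(oc) == 0) return(matrix(numeric(0), 0, 2))
  oc <- oc[[which.max(vapply(oc, nrow, 0L))]]
  cbind(oc[, 1] + 1L, oc[, 2] + 1L)
}

# closed polygon length of an ordered contour (chain-code distances)
contour_length <- function(contour) {
  n <- nrow(contour)
  if (n < 2) return(0)
  d <- sqrt(rowSums((contour - contour[c(2:n, 1), ])^2))
  sum(d)
}

# Merge detections from overlapping ROIs: pixel IoU > 0.5, or overlap
# covering > 50% of the smaller detection (an object clipped by one ROI and
# seen whole in another), keeps the larger.
merge_duplicates <- function(detections) {
  n <- length(detections)
  if (n < 2) return(detections)
  keep <- rep(TRUE, n)
  for (i in seq_len(n - 1)) {
    if (!keep[i]) next
    for (j in seq.int(i + 1, n)) {
      if (!keep[j]) next
      if (detections[[i]]$roi_index == detections[[j]]$roi_index) next
      inter <- length(intersect(detections[[i]]$pixels, detections[[j]]$pixels))
      if (inter == 0) next
      uni <- detections[[i]]$area_px + detections[[j]]$area_px - inter
      smaller <- min(detections[[i]]$area_px, detections[[j]]$area_px)
      if (inter / uni > 0.5 || inter / smaller > 0.5) {
        drop <- if (detections[[i]]$area_px >= detections[[j]]$area_px) j else i
        keep[drop] <- FALSE
        if (drop == i) break
      }
    }
  }
  detections[keep]
}

#' Assign deterministic raster-order labels to detections
#'
#' Labels 1..N are assigned in raster order of the centroids (row, then
#' column, rounded to the nearest pixel); exact ties go to the larger
#' detection. The ordering depends only on centroid positions and areas,
#' so shuffling the input leaves the assignment unchanged — the property
#' that lets the same chamber position keep the same number across a time
#' course.
#'
#' @param detections List of `sphere_detection` objects.
#' @return The detections sorted by label, with `label` filled in.
#' @export
number_spheres <- function(detections) {
  if (length(detections) == 0) return(detections)
  r <- vapply(detections, function(d) round(d$centroid[1]), 0)
  c_ <- vapply(detections, function(d) round(d$centroid[2]), 0)
  a <- vapply(detections, function(d) d$area_px, 0)
  ord <- order(r, c_, -a)
  detections <- detections[ord]
  for (i in seq_along(detections)) detections[[i]]$label <- i
  detections
}

#' @export
print.sphere_detection <- function(x, ...) {
  cat(sprintf("<sphere %s> centroid (%.1f, %.1f), %d px = %.1f um^2, circularity %.2f\n",
              ifelse(is.na(x$label), "?", x$label),
              x$centroid[1], x$centroid[2], x$area_px, x$area_um2, x$circularity))
  invisible(x)
}

#' Run the full detection pipeline on one image
#'
#' Preprocessing (CLAHE then Gaussian smoothing), Gabor-bank texture
#' response, region proposal, per-region segmentation, duplicate merging
#' and raster-order numbering.
#'
#' @param image A [gray_image] (use [to_gray()] / [read_gray_image()] for
#'   raw rasters).
#' @param cal A [calibration].
#' @param cfg A [pipeline_config].
#' The contrast-homogenized image drives texture response and region
#' proposal only; per-region thresholding and measurement run on the
#' original intensities, because CLAHE's nonlinear remapping (and, to a
#' lesser degree, smoothing against an asymmetric background) shifts the
#' apparent object boundary and would bias areas low.
#'
#' @return A list with `detections` (numbered), `rois`, and `preprocessed`
#'   (the contrast-homogenized image used for region proposal).
#' @examples
#' sc <- generate_scene(random_scene_spec(3, seed = 7))
#' res <- detect_spheres(sc$image, calibration("10x", 1))
#' length(res$detections)
#' @export
detect_spheres <- function(image, cal, cfg = pipeline_config()) {
  check_pipeline_entry(image)
  pre <- clahe(image, cfg$clahe_clip_limit, cfg$clahe_tile_grid)
  pre <- gaussian_smooth(pre, cfg$gaussian_sigma)
  response <- apply_gabor_bank(pre, cfg$gabor_spec)
  rois <- propose_rois(response, cfg)
  dets <- extract_spheres(image, rois, cfg, cal)
  list(detections = number_spheres(dets), rois = rois, preprocessed = pre)
}
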
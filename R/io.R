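#' Read an image file as a grayscale image
#'
#' PNG, JPEG and TIFF (8/16-bit, gray or RGB) are supported via EBImage;
#' RGB is converted with [to_gray()]'s BT.601 luma weights. Intensities
#' are normalized to `[0, 1]` and the raster is returned in (row, column)
#' layout.
#'
#' @param path File path.
#' @return A [gray_image] with `source_path` set.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path, call. = FALSE)
  img <- EBImage::readImage(path)
  arr <- EBImage::imageData(img)
  d <- dim(arr)
  if (length(d) == 2) {
    m <- t(arr)
    return(gray_image(pmin(pmax(m, 0), 1), source_path = path))
  }
  if (length(d) == 3) {
    arr <- aperm(arr, c(2, 1, 3))          # EBImage is (x, y, channel)
    if (d[3] == 4L) arr <- arr[, , 1:3, drop = FALSE]  # drop alpha
    out <- to_gray(arr, source_path = path)
    return(out)
  }
  stop(sprintf("unsupported raster in '%s': dims [%s]", path,
               paste(d, collapse = " x ")), call. = FALSE)
}

#' Write a grayscale image to disk
#'
#' @param image A [gray_image] or numeric matrix in `[0, 1]`.
#' @param path Output path; the extension selects the format (png/tiff/jpeg).
#' @export
write_gray_image <- function(image, path) {
  m <- px_matrix(image)
  EBImage::writeImage(t(m), path)
  invisible(path)
}

# 3x5 digit glyphs for raster label rendering (no graphics device needed)
digit_glyphs <- local({
  g <- list(
    "0" = c("111", "101", "101", "101", "111"),
    "1" = c("010", "110", "010", "010", "111"),
    "2" = c("111", "001", "111", "100", "111"),
    "3" = c("111", "001", "111", "001", "111"),
    "4" = c("101", "101", "111", "001", "001"),
    "5" = c("111", "100", "111", "001", "111"),
    "6" = c("111", "100", "111", "101", "111"),
    "7" = c("111", "001", "010", "010", "010"),
    "8" = c("111", "101", "111", "101", "111"),
    "9" = c("111", "101", "111", "001", "111")
  )
  lapply(g, function(rows) {
    do.call(rbind, lapply(rows, function(r) as.integer(strsplit(r, "")[[1]]) == 1L))
  })
})

# stamp an integer onto an RGB array at (row, col) in the given color
draw_number <- function(rgb, row, col, number, color, scale = 2L) {
  digits <- strsplit(as.character(number), "")[[1]]
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  x <- col
  for (d in digits) {
    glyph <- digit_glyphs[[d]]
    gh <- nrow(glyph) * scale; gw <- ncol(glyph) * scale
    big <- glyph[rep(seq_len(nrow(glyph)), each = scale),
                 rep(seq_len(ncol(glyph)), each = scale)]
    rr <- row:(row + gh - 1); cc <- x:(x + gw - 1)
    ok_r <- rr >= 1 & rr <= h; ok_c <- cc >= 1 & cc <= w
    if (any(ok_r) && any(ok_c)) {
      sub <- big[ok_r, ok_c, drop = FALSE]
      for (ch in 1:3) {
        plane <- rgb[rr[ok_r], cc[ok_c], ch]
        plane[sub] <- color[ch]
        rgb[rr[ok_r], cc[ok_c], ch] <- plane
      }
    }
    x <- x + gw + scale
  }
  rgb
}

draw_points <- function(rgb, pts, color) {
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  pts <- pts[pts[, 1] >= 1 & pts[, 1] <= h & pts[, 2] >= 1 & pts[, 2] <= w, ,
             drop = FALSE]
  for (ch in 1:3) {
    rgb[cbind(pts[, 1], pts[, 2], ch)] <- color[ch]
  }
  rgb
}

#' Render an annotated copy of an analyzed image
#'
#' Follows the reporting convention of the pipeline's figures: the
#' measured contour is overlaid in red, an enclosing circle is drawn in
#' green, and the sphere number is stamped in red next to the circle.
#'
#' @param image The analyzed [gray_image].
#' @param detections Numbered detections.
#' @param path Output PNG path.
#' @export
write_annotated_image <- function(image, detections, path) {
  m <- px_matrix(image)
  h <- nrow(m); w <- ncol(m)
  rgb <- array(rep(m, 3), dim = c(h, w, 3))
  green <- c(0, 1, 0); red <- c(1, 0, 0)
  for (det in detections) {
    if (nrow(det$contour) > 0) {
      rgb <- draw_points(rgb, det$contour, red)
      radius <- max(sqrt((det$contour[, 1] - det$centroid[1])^2 +
                         (det$contour[, 2] - det$centroid[2])^2)) + 3
    } else {
      radius <- sqrt(det$area_px / pi) + 3
    }
    t_ <- seq(0, 2 * pi, length.out = max(32, round(2 * pi * radius)))
    circ <- cbind(round(det$centroid[1] + radius * sin(t_)),
                  round(det$centroid[2] + radius * cos(t_)))
    rgb <- draw_points(rgb, circ, green)
    rgb <- draw_number(rgb, round(det$centroid[1] - radius - 12),
                       round(det$centroid[2] - 3), det$label, red)
  }
  EBImage::writeImage(EBImage::Image(aperm(rgb, c(2, 1, 3)), colormode = "Color"),
                      path)
  invisible(path)
}

# the bit-exact CSV schema of results.csv
results_columns <- c("image", "sphere_id", "centroid_row", "centroid_col",
                     "area_px", "area_um2", "equivalent_diameter_um",
                     "circularity", "percent_of_image_area",
                     "percent_of_roi_area", "touches_border",
                     "magnification", "microns_per_pixel", "error")

empty_results <- function() {
  df <- data.frame(image = character(0), sphere_id = integer(0),
                   centroid_row = numeric(0), centroid_col = numeric(0),
                   area_px = numeric(0), area_um2 = numeric(0),
                   equivalent_diameter_um = numeric(0), circularity = numeric(0),
                   percent_of_image_area = numeric(0),
                   percent_of_roi_area = numeric(0),
                   touches_border = logical(0), magnification = character(0),
                   microns_per_pixel = numeric(0), error = character(0))
  df[, results_columns]
}

#' Tabulate detections and the per-image summary as CSV rows
#'
#' One row per detection plus one summary row (empty `sphere_id`) per
#' image. `percent_of_roi_area` is the detection's share of its proposing
#' region; `percent_of_image_area` its share of the whole image (both
#' readings of per-region area usage are served).
#'
#' @param report An `image_report` from [summarize_image()].
#' @param rois The regions the detections came from.
#' @param cal The [calibration] used.
#' @param image_name Name used in the `image` column.
#' @param error Error message for failed images (`""` on success).
#' @return A data frame with the `results.csv` schema.
#' @export
results_rows <- function(report, rois, cal, image_name, error = "") {
  m_area <- report$image_area_um2 / cal$microns_per_pixel^2   # image px count
  rows <- empty_results()
  for (det in report$detections) {
    roi_area <- {
      b <- rois[[det$roi_index]]$box
      (b[2] - b[1] + 1) * (b[4] - b[3] + 1)
    }
    rows[nrow(rows) + 1L, ] <- list(
      image_name, det$label, det$centroid[1], det$centroid[2],
      det$area_px, det$area_um2, det$equivalent_diameter_um,
      det$circularity, 100 * det$area_px / m_area,
      100 * det$area_px / roi_area, det$touches_border,
      cal$magnification, cal$microns_per_pixel, ""
    )
  }
  rows[nrow(rows) + 1L, ] <- list(
    image_name, NA_integer_, NA_real_, NA_real_,
    sum(vapply(report$detections, function(d) d$area_px, 0)),
    report$total_area_um2, NA_real_, NA_real_,
    report$percent_area, NA_real_, NA,
    cal$magnification, cal$microns_per_pixel, error
  )
  rows
}

#' Batch manifest
#'
#' @param input_dir Directory of images to analyze (must exist).
#' @param output_dir Directory for the annotated images and `results.csv`
#'   (created if absent).
#' @param magnification Objective label recorded in the report.
#' @param microns_per_pixel Calibrated pixel size (required; see
#'   [calibration]).
#' @param image_format One of `"png"`, `"jpg"`, `"tif"`.
#' @param config A [pipeline_config] (or path to a config file, parsed
#'   with [read_pipeline_config()]).
#' @return A `batch_manifest`.
#' @export
batch_manifest <- function(input_dir, output_dir, magnification,
                           microns_per_pixel, image_format = "png",
                           config = pipeline_config()) {
  if (!dir.exists(input_dir)) stop("input_dir does not exist: ", input_dir,
                                   call. = FALSE)
  if (!image_format %in% c("png", "jpg", "tif")) {
    stop("image_format must be one of png/jpg/tif", call. = FALSE)
  }
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 magnification = magnification,
                 microns_per_pixel = microns_per_pixel,
                 image_format = image_format, config = config),
            class = "batch_manifest")
}

#' Run the pipeline over a directory of images
#'
#' Images are processed in lexicographic filename order. For each image an
#' annotated `<stem>_annotated.png` is written; all detection rows and one
#' summary row per image accumulate into `results.csv` in the output
#' directory. Unreadable images are logged, skipped, and recorded in the
#' CSV `error` column.
#'
#' @param manifest A [batch_manifest].
#' @param quiet Suppress per-image log lines.
#' @return Invisibly, a list with `reports` (per-image `image_report`s),
#'   `results` (the CSV data frame) and `csv_path`.
#' @export
run_batch <- function(manifest, quiet = FALSE) {
  stopifnot(inherits(manifest, "batch_manifest"))
  exts <- switch(manifest$image_format,
                 png = "png", jpg = "jpe?g", tif = "tiff?")
  files <- sort(list.files(manifest$input_dir,
                           pattern = paste0("\\.(", exts, ")$"),
                           ignore.case = TRUE, full.names = TRUE))
  files <- files[!grepl("_annotated\\.", files)]
  if (length(files) == 0) {
    stop(sprintf("no .%s images found in %s", manifest$image_format,
                 manifest$input_dir), call. = FALSE)
  }
  dir.create(manifest$output_dir, showWarnings = FALSE, recursive = TRUE)
  cal <- calibration(manifest$magnification, manifest$microns_per_pixel)
  cfg <- manifest$config

  results <- empty_results()
  reports <- list()
  for (f in files) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      img <- read_gray_image(f)
      run <- detect_spheres(img, cal, cfg)
      elapsed <- proc.time()[["elapsed"]] - t0
      report <- summarize_image(img, run$detections, cal, elapsed)
      stem <- tools::file_path_sans_ext(basename(f))
      write_annotated_image(img, run$detections,
                            file.path(manifest$output_dir,
                                      paste0(stem, "_annotated.png")))
      list(report = report, rois = run$rois, error = "")
    }, error = function(e) {
      list(report = NULL, rois = list(), error = conditionMessage(e))
    })
    if (is.null(res$report)) {
      if (!quiet) message(sprintf("[skip] %s: %s", basename(f), res$error))
      row <- empty_results()
      row[1L, ] <- list(basename(f), NA_integer_, NA_real_, NA_real_,
                        NA_real_, NA_real_, NA_real_, NA_real_, NA_real_,
                        NA_real_, NA, manifest$magnification,
                        manifest$microns_per_pixel, res$error)
      results <- rbind(results, row)
    } else {
      if (!quiet) {
        message(sprintf("[ok]   %s: %d spheres in %.2f s", basename(f),
                        res$report$sphere_count, res$report$processing_time_s))
      }
      reports[[basename(f)]] <- res$report
      results <- rbind(results,
                       results_rows(res$report, res$rois, cal, basename(f)))
    }
  }
  csv_path <- file.path(manifest$output_dir, "results.csv")
  utils::write.csv(results, csv_path, row.names = FALSE)
  invisible(list(reports = reports, results = results, csv_path = csv_path))
}

#' Read a flat key/value pipeline configuration file
#'
#' The file holds `key = value` lines (TOML-like; `#` comments allowed).
#' Recognized keys mirror [pipeline_config()] arguments (e.g.
#' `clahe_clip_limit`, `clahe_tile_grid = 8, 8`, `gaussian_sigma`,
#' `min_sphere_area_um2`, `gabor_frequencies = 0.25, 0.1667, 0.125`,
#' `gabor_orientations_deg = 0, 30, 60, 90, 120, 150`, `gabor_gamma`,
#' `gabor_eta`, `gabor_kernel_size`, `sphere_polarity`), plus the optional
#' calibration keys `magnification` and `microns_per_pixel` (returned as
#' attributes; command-line flags override them).
#'
#' @param path Config file path.
#' @return A [pipeline_config]; calibration keys, when present, are
#'   attached as attributes `magnification` / `microns_per_pixel`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = "="))
    val <- gsub('^"|"$', "", val)
    num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    kv[[key]] <- if (!anyNA(num)) num else val
  }
  spec_args <- list()
  if (!is.null(kv$gabor_frequencies)) spec_args$frequencies <- kv$gabor_frequencies
  if (!is.null(kv$gabor_orientations_deg)) {
    spec_args$orientations <- kv$gabor_orientations_deg * pi / 180
  }
  if (!is.null(kv$gabor_gamma)) spec_args$gamma <- kv$gabor_gamma
  if (!is.null(kv$gabor_eta)) spec_args$eta <- kv$gabor_eta
  if (!is.null(kv$gabor_kernel_size)) spec_args$kernel_size <- kv$gabor_kernel_size
  cfg_args <- kv[names(kv) %in% names(formals(pipeline_config))]
  if (length(spec_args)) cfg_args$gabor_spec <- do.call(gabor_bank_spec, spec_args)
  cfg <- do.call(pipeline_config, cfg_args)
  if (!is.null(kv$magnification)) attr(cfg, "magnification") <- as.character(kv$magnification)
  if (!is.null(kv$microns_per_pixel)) attr(cfg, "microns_per_pixel") <- kv$microns_per_pixel
  cfg
}
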
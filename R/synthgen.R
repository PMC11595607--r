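#' Synthetic sphere-culture scene specification
#'
#' Describes a synthetic phase-contrast-like microscopy scene: bright
#' disc-shaped spheres with a dark surrounding halo, over either a uniform
#' background (multiwell-plate regime) or a nonuniform one (microfluidic
#' regime: intensity gradient, dark chamber-wall ring, small
#' erythrocyte-like speck clusters), plus additive Gaussian noise. The
#' seed fixes all randomness so every scene is reproducible.
#'
#' @param image_size Integer `(height, width)` in pixels.
#' @param spheres List of sphere descriptors, each a list with `center`
#'   `(row, col)`, `radius` (px), and optional `core` intensity,
#'   `halo_width` (px) and `halo_intensity`. The halo annulus lies
#'   *outside* the disc support; the ground-truth mask is the set of
#'   pixels whose center is within `radius` of the sphere center.
#' @param background Either `list(type = "uniform", level = )` or
#'   `list(type = "linear", level = , slope_row = , slope_col = )` (slopes
#'   are the total intensity change across the image extent).
#' @param chamber `NULL`, or `list(center, radius, depth, width)`
#'   describing a dark chamber-wall ring (Gaussian radial profile of the
#'   given depth and width).
#' @param artifacts `list(count, radius_range, intensity)`: number of
#'   erythrocyte-like speck clusters, speck radius range in px, and speck
#'   intensity.
#' @param noise_sigma Standard deviation of additive Gaussian noise.
#' @param seed Integer seed fixing artifact placement and noise.
#' @param allow_overlap Permit overlapping sphere supports (default FALSE;
#'   overlapping spheres are otherwise rejected).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(256L, 256L),
                       spheres = list(),
                       background = list(type = "uniform", level = 0.45),
                       chamber = NULL,
                       artifacts = list(count = 0L, radius_range = c(2, 4),
                                        intensity = 0.8),
                       noise_sigma = 0.01,
                       seed = 1L,
                       allow_overlap = FALSE) {
  h <- as.integer(image_size[1]); w <- as.integer(image_size[2])
  stopifnot(h >= 16, w >= 16, noise_sigma >= 0)
  spheres <- lapply(spheres, function(s) {
    s <- utils::modifyList(list(core = 0.85, halo_width = 3, halo_intensity = 0.25), s)
    stopifnot(s$radius > 0)
    if (s$center[1] - s$radius < 1 || s$center[1] + s$radius > h ||
        s$center[2] - s$radius < 1 || s$center[2] + s$radius > w) {
      stop("sphere support exceeds image bounds", call. = FALSE)
    }
    s
  })
  if (!allow_overlap && length(spheres) > 1) {
    for (i in seq_along(spheres)) {
      for (j in seq_len(i - 1L)) {
        d <- sqrt(sum((spheres[[i]]$center - spheres[[j]]$center)^2))
        if (d < spheres[[i]]$radius + spheres[[j]]$radius) {
          stop("overlapping spheres rejected (set allow_overlap = TRUE to permit)",
               call. = FALSE)
        }
      }
    }
  }
  structure(list(image_size = c(h, w), spheres = spheres,
                 background = background, chamber = chamber,
                 artifacts = artifacts, noise_sigma = noise_sigma,
                 seed = as.integer(seed), allow_overlap = allow_overlap),
            class = "scene_spec")
}

# run code under a seed without disturbing the caller's RNG state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Render a synthetic scene with pixel-exact ground truth
#'
#' @param spec A [scene_spec].
#' @return A list with `image` (a [gray_image]) and `truth`: a data frame
#'   with one row per sphere (`center_row`, `center_col`, `radius_px`,
#'   `area_px`) plus attribute `masks`, a list of linear pixel-index
#'   vectors giving each sphere's noise-free disc support.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)

  bg <- spec$background
  img <- switch(bg$type,
    uniform = matrix(bg$level, h, w),
    linear = bg$level + (rows - 1) / (h - 1) * bg$slope_row +
             (cols - 1) / (w - 1) * bg$slope_col,
    stop("unknown background type: ", bg$type)
  )

  if (!is.null(spec$chamber)) {
    ch <- spec$chamber
    d <- sqrt((rows - ch$center[1])^2 + (cols - ch$center[2])^2)
    img <- img * (1 - ch$depth * exp(-(d - ch$radius)^2 / (2 * ch$width^2)))
  }

  masks <- vector("list", length(spec$spheres))
  truth <- data.frame(center_row = numeric(0), center_col = numeric(0),
                      radius_px = numeric(0), area_px = integer(0))
  for (i in seq_along(spec$spheres)) {
    s <- spec$spheres[[i]]
    d <- sqrt((rows - s$center[1])^2 + (cols - s$center[2])^2)
    halo <- d > s$radius & d <= s$radius + s$halo_width
    img[halo] <- s$halo_intensity
    core <- d <= s$radius
    # gentle radial shading keeps the core from looking artificially flat
    img[core] <- s$core - 0.06 * (d[core] / s$radius)^2
    masks[[i]] <- which(core)
    truth[i, ] <- list(s$center[1], s$center[2], s$radius, sum(core))
  }

  img <- with_local_seed(spec$seed, {
    if (spec$artifacts$count > 0) {
      for (k in seq_len(spec$artifacts$count)) {
        cr <- stats::runif(1, 10, h - 10)
        cc <- stats::runif(1, 10, w - 10)
        n_specks <- sample(2:4, 1)
        for (sp in seq_len(n_specks)) {
          r <- stats::runif(1, spec$artifacts$radius_range[1],
                            spec$artifacts$radius_range[2])
          ar <- cr + stats::runif(1, -6, 6)
          ac <- cc + stats::runif(1, -6, 6)
          d <- sqrt((rows - ar)^2 + (cols - ac)^2)
          img[d <= r] <- spec$artifacts$intensity
        }
      }
    }
    if (spec$noise_sigma > 0) {
      img <- img + matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w)
    }
    img
  })

  attr(truth, "masks") <- masks
  list(image = gray_image(pmin(pmax(img, 0), 1)), truth = truth)
}

#' Draw a random scene specification
#'
#' Samples `n_spheres` non-overlapping spheres (rejection sampling with a
#' border margin) under one of the two acquisition regimes the pipeline
#' supports: `"uniform"` emulates a 12-multiwell plate field, and
#' `"microfluidic"` adds an intensity gradient, a dark chamber-wall ring
#' and erythrocyte-like speck clusters.
#'
#' @param n_spheres Number of spheres to place.
#' @param image_size Integer `(height, width)`.
#' @param background `"uniform"` or `"microfluidic"`.
#' @param radius_range Sphere radius range in pixels.
#' @param noise_sigma Additive noise level.
#' @param seed Integer seed (placement, artifacts and noise).
#' @return A [scene_spec].
#' @export
random_scene_spec <- function(n_spheres,
                              image_size = c(256L, 256L),
                              background = c("uniform", "microfluidic"),
                              radius_range = c(12, 24),
                              noise_sigma = 0.01,
                              seed = 1L) {
  background <- match.arg(background)
  h <- image_size[1]; w <- image_size[2]
  margin <- radius_range[2] + 6
  # microfluidic spheres sit inside the chamber, clear of the wall ring
  chamber_r <- 0.46 * min(h, w)
  chamber_w <- 5
  max_center_dist <- chamber_r - 2 * chamber_w - 4
  placed <- with_local_seed(seed, {
    out <- list()
    tries <- 0L
    while (length(out) < n_spheres && tries < 20000L) {
      tries <- tries + 1L
      r <- stats::runif(1, radius_range[1], radius_range[2])
      cr <- stats::runif(1, margin, h - margin)
      cc <- stats::runif(1, margin, w - margin)
      if (background == "microfluidic" &&
          sqrt((cr - h / 2)^2 + (cc - w / 2)^2) + r + 4 > max_center_dist) next
      ok <- TRUE
      for (s in out) {
        if (sqrt(sum((c(cr, cc) - s$center)^2)) < r + s$radius + 8) {
          ok <- FALSE
          break
        }
      }
      if (ok) out[[length(out) + 1L]] <- list(center = c(cr, cc), radius = r)
    }
    out
  })
  if (length(placed) < n_spheres) {
    stop(sprintf("could not place %d non-overlapping spheres in a %d x %d image",
                 n_spheres, h, w), call. = FALSE)
  }
  if (background == "uniform") {
    scene_spec(image_size = image_size, spheres = placed,
               background = list(type = "uniform", level = 0.45),
               noise_sigma = noise_sigma, seed = seed)
  } else {
    scene_spec(image_size = image_size, spheres = placed,
               background = list(type = "linear", level = 0.38,
                                 slope_row = 0.10, slope_col = 0.12),
               chamber = list(center = c(h / 2, w / 2),
                              radius = 0.46 * min(h, w),
                              depth = 0.5, width = 5),
               artifacts = list(count = 6L, radius_range = c(2, 4),
                                intensity = 0.8),
               noise_sigma = noise_sigma, seed = seed)
  }
}

#' Write a synthetic dataset to disk
#'
#' Renders `n_images` seeded scenes and writes each as a PNG together with
#' a `truth` JSON (centers, radii, pixel areas).
#'
#' @param out_dir Output directory (created if absent).
#' @param n_images Number of images.
#' @param spheres_per_image Spheres per image (recycled if scalar).
#' @param background `"uniform"` or `"microfluidic"`.
#' @param image_size Integer `(height, width)`.
#' @param seed Base seed; image `i` uses `seed + i`.
#' @return Invisibly, a data frame with `image` and `truth_json` paths and
#'   the true sphere count per image.
#' @export
synth_dataset <- function(out_dir, n_images = 5L, spheres_per_image = 4L,
                          background = c("uniform", "microfluidic"),
                          image_size = c(256L, 256L), seed = 1L) {
  background <- match.arg(background)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_sph <- rep_len(spheres_per_image, n_images)
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    sc <- generate_scene(random_scene_spec(
      n_sph[i], image_size = image_size, background = background,
      seed = seed + i))
    stem <- sprintf("synthetic_%03d", i)
    img_path <- file.path(out_dir, paste0(stem, ".png"))
    json_path <- file.path(out_dir, paste0(stem, "_truth.json"))
    write_gray_image(sc$image, img_path)
    jsonlite::write_json(sc$truth, json_path, digits = NA)
    rows[[i]] <- data.frame(image = img_path, truth_json = json_path,
                            n_spheres = nrow(sc$truth))
  }
  invisible(do.call(rbind, rows))
}
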
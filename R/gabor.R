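#' Gabor filter-bank specification
#'
#' A bank is the Cartesian product of spatial frequencies and
#' orientations of the 2-d Gabor function
#' \deqn{g(x, y) = \frac{f^2}{\pi \gamma \eta}
#'   \exp\!\left(-\frac{x'^2 f^2}{\gamma^2} - \frac{y'^2 f^2}{\eta^2}\right)
#'   e^{-j 2 \pi f x'}}
#' with \eqn{x' = x\cos\theta + y\sin\theta},
#' \eqn{y' = -x\sin\theta + y\cos\theta}. Here `x` is the column offset and
#' `y` the row offset from the kernel center; `f` is in cycles per pixel
#' and `gamma`/`eta` set the envelope sharpness along the major and minor
#' axes.
#'
#' Defaults: three frequencies `1/4, 1/6, 1/8` cycles/px, six
#' orientations `0..150` degrees in 30-degree steps, `gamma = 10`,
#' `eta = 0.5`, 21-px kernels — an 18-kernel bank spanning the scales and
#' orientations of sphere rims at the supported magnifications.
#'
#' @param frequencies Positive frequencies, cycles per pixel.
#' @param orientations Orientations in radians.
#' @param gamma,eta Envelope sharpness along the major/minor axis.
#' @param kernel_size Odd kernel side length in pixels, >= 3.
#' @return An object of class `gabor_bank_spec`.
#' @export
gabor_bank_spec <- function(frequencies = c(1 / 4, 1 / 6, 1 / 8),
                            orientations = seq(0, 150, by = 30) * pi / 180,
                            gamma = 10,
                            eta = 0.5,
                            kernel_size = 21L) {
  stopifnot(length(frequencies) >= 1, all(frequencies > 0),
            length(orientations) >= 1,
            gamma > 0, eta > 0)
  kernel_size <- as.integer(kernel_size)
  if (kernel_size < 3L || kernel_size %% 2L == 0L) {
    stop("'kernel_size' must be an odd integer >= 3", call. = FALSE)
  }
  structure(list(frequencies = as.numeric(frequencies),
                 orientations = as.numeric(orientations),
                 gamma = gamma, eta = eta,
                 kernel_size = kernel_size),
            class = "gabor_bank_spec")
}

#' Build the complex Gabor kernels of a bank
#'
#' One complex kernel per (frequency, orientation) pair, evaluated on the
#' integer offset grid centered at the kernel midpoint. The kernel center
#' value is `f^2 / (pi * gamma * eta)` (unit envelope, unit carrier).
#'
#' @param spec A [gabor_bank_spec].
#' @return A list of complex matrices; each carries attributes `frequency`
#'   and `orientation`.
#' @export
build_gabor_bank <- function(spec = gabor_bank_spec()) {
  stopifnot(inherits(spec, "gabor_bank_spec"))
  half <- (spec$kernel_size - 1L) / 2
  off <- seq.int(-half, half)
  x <- matrix(off, spec$kernel_size, spec$kernel_size, byrow = TRUE)  # column offset
  y <- matrix(off, spec$kernel_size, spec$kernel_size)                # row offset
  kernels <- vector("list", length(spec$frequencies) * length(spec$orientations))
  i <- 0L
  for (f in spec$frequencies) {
    for (theta in spec$orientations) {
      xp <- x * cos(theta) + y * sin(theta)
      yp <- -x * sin(theta) + y * cos(theta)
      amp <- f^2 / (pi * spec$gamma * spec$eta)
      env <- exp(-(xp^2 * f^2 / spec$gamma^2 + yp^2 * f^2 / spec$eta^2))
      k <- amp * env * exp(complex(imaginary = -2 * pi * f * xp))
      attr(k, "frequency") <- f
      attr(k, "orientation") <- theta
      i <- i + 1L
      kernels[[i]] <- k
    }
  }
  kernels
}

#' Apply a Gabor bank to an image
#'
#' Each kernel is convolved (complex convolution, reflective borders) with
#' the image and the pointwise magnitude taken; the per-pixel maximum over
#' the bank is the aggregate texture response used for region proposal.
#'
#' @param image A [gray_image] or numeric matrix.
#' @param bank A list of complex kernels from [build_gabor_bank()], or a
#'   [gabor_bank_spec] (kernels are then built on the fly).
#' @return An object of class `gabor_response` with elements `per_filter`
#'   (list of non-negative magnitude matrices) and `aggregate` (their
#'   pointwise maximum).
#' @export
apply_gabor_bank <- function(image, bank = gabor_bank_spec()) {
  if (inherits(bank, "gabor_bank_spec")) bank <- build_gabor_bank(bank)
  stopifnot(is.list(bank), length(bank) >= 1)
  m <- px_matrix(image)
  ks <- nrow(bank[[1]])
  if (nrow(m) < ks || ncol(m) < ks) {
    stop(sprintf("image %d x %d smaller than the %d-px Gabor kernel",
                 nrow(m), ncol(m), ks), call. = FALSE)
  }
  per_filter <- lapply(bank, function(k) Mod(conv2_reflect_complex(m, k)))
  aggregate <- Reduce(pmax, per_filter)
  structure(list(per_filter = per_filter, aggregate = aggregate),
            class = "gabor_response")
}

#' @export
print.gabor_response <- function(x, ...) {
  cat(sprintf("<gabor_response> %d filters, %d x %d px, aggregate range [%.3g, %.3g]\n",
              length(x$per_filter), nrow(x$aggregate), ncol(x$aggregate),
              min(x$aggregate), max(x$aggregate)))
  invisible(x)
}
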
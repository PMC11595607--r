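# Convolution with reflective (mirror) boundary handling.
#
# EBImage::filter2 performs true convolution via FFT but only offers
# circular/replicate boundaries; reflective borders are obtained by
# mirror-padding by the kernel half-size first, filtering, and cropping.

pad_reflect <- function(m, pr, pc) {
  nr <- nrow(m); nc <- ncol(m)
  if (pr >= nr || pc >= nc) {
    # reflect repeatedly for very small images
    ri <- reflect_index(seq.int(1 - pr, nr + pr), nr)
    ci <- reflect_index(seq.int(1 - pc, nc + pc), nc)
    return(m[ri, ci, drop = FALSE])
  }
  ri <- c(seq.int(pr + 1, 2), seq_len(nr), seq.int(nr - 1, nr - pr))
  ci <- c(seq.int(pc + 1, 2), seq_len(nc), seq.int(nc - 1, nc - pc))
  m[ri, ci, drop = FALSE]
}

# Mirror an arbitrary integer index into 1..n (reflection without repeated
# edge sample, period 2n - 2).
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1) %% (2 * n - 2)
  ifelse(j < n, j + 1, 2 * n - 1 - j)
}

# 2-d convolution of a numeric matrix with an odd-sized kernel,
# reflective borders; output has the input's shape.
conv2_reflect <- function(m, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  stopifnot(kr %% 2 == 1, kc %% 2 == 1)
  pr <- (kr - 1L) %/% 2L; pc <- (kc - 1L) %/% 2L
  if (pr == 0 && pc == 0) return(m * kernel[1, 1])
  padded <- pad_reflect(m, pr, pc)
  out <- EBImage::filter2(padded, kernel, boundary = "circular")
  out[(pr + 1):(pr + nrow(m)), (pc + 1):(pc + ncol(m)), drop = FALSE]
}

# Convolution with a complex kernel: real and imaginary parts separately.
conv2_reflect_complex <- function(m, kernel) {
  re <- conv2_reflect(m, Re(kernel))
  im <- conv2_reflect(m, Im(kernel))
  matrix(complex(real = re, imaginary = im), nrow(m), ncol(m))
}
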
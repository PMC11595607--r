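test_that("sobel vanishes on constants and reproduces the unit step response", {
  g <- sobel(matrix(0.42, 12, 12))
  expect_lt(max(g$G), 1e-12)

  m <- matrix(0, 16, 16); m[, 9:16] <- 1
  g <- sobel(m)
  interior <- 3:14
  expect_equal(abs(g$Gx[interior, 8]), rep(4, length(interior)))
  expect_equal(abs(g$Gx[interior, 9]), rep(4, length(interior)))
  expect_equal(g$Gy, matrix(0, 16, 16))
  expect_equal(g$G[interior, 8], rep(4, length(interior)))
  expect_equal(g$G, sqrt(g$Gx^2 + g$Gy^2))
  expect_equal(g$theta, atan2(g$Gy, g$Gx))
})

test_that("transposing the image swaps the roles of Gx and Gy", {
  set.seed(2)
  x <- matrix(runif(20 * 14), 20, 14)
  g <- sobel(x)
  gt <- sobel(t(x))
  expect_equal(gt$Gx, t(g$Gy))
  expect_equal(gt$Gy, t(g$Gx))
})

test_that("sobel magnitude is invariant to adding a constant", {
  set.seed(3)
  x <- matrix(runif(16^2, 0, 0.5), 16, 16)
  expect_equal(sobel(x + 0.3)$G, sobel(x)$G)
  expect_error(sobel(matrix(0, 2, 2)), "too small")
})

test_that("otsu separates a bimodal image and is translation-equivariant", {
  set.seed(13)
  v <- sample(c(rep(0.2, 60), rep(0.8, 40)))
  m <- matrix(v, 10, 10)
  t_ <- otsu_threshold(m)
  expect_gt(t_, 0.2)
  expect_lt(t_, 0.8)
  expect_equal(sum(m > t_), 40)

  c_ <- 32 / 256  # a whole number of bins, so the histogram shifts exactly
  expect_equal(otsu_threshold(m + c_), t_ + c_)
  expect_error(otsu_threshold(matrix(0.5, 4, 4)), "degenerate")
})

test_that("otsu equals the exhaustive between-class-variance maximizer", {
  set.seed(37)
  for (trial in 1:60) {
    m <- matrix(sample(seq(0, 7) / 8 + 1 / 16, 144, replace = TRUE), 12, 12)
    if (diff(range(m)) == 0) next
    expect_equal(otsu_threshold(m), brute_force_otsu(m))
  }
})

test_that("adaptive threshold behaves on constants and recovers a bright disk", {
  m <- matrix(0.5, 16, 16)
  expect_true(all(adaptive_threshold(m, 5, offset = 0.02)))
  expect_false(any(adaptive_threshold(m, 5, offset = -0.02)))
  expect_error(adaptive_threshold(m, 4), "odd")

  d <- disk_mask(64, 64, c(32, 32), 10)
  img <- matrix(0.1, 64, 64); img[d] <- 0.9
  got <- adaptive_threshold(img, 41, offset = 0.02)
  core <- disk_mask(64, 64, c(32, 32), 8.5)
  outside <- !disk_mask(64, 64, c(32, 32), 11.5)
  expect_true(all(got[core]))
  expect_false(any(got[outside & disk_mask(64, 64, c(32, 32), 20)]))
})

test_that("closing plus dilation matches the set-morphology oracle", {
  empty <- matrix(FALSE, 12, 12)
  expect_equal(morph_close_dilate(empty, 2), empty)
  full <- matrix(TRUE, 12, 12)
  expect_equal(morph_close_dilate(full, 2), full)

  mask <- disk_mask(40, 40, c(20, 20), 10)
  mask[20, 20] <- FALSE    # 1-px interior hole
  got <- morph_close_dilate(mask, 2)
  brush <- EBImage::makeBrush(5, "disc") > 0
  want <- set_dilate(set_erode(set_dilate(mask, brush), brush), brush)
  expect_equal(got, want)
  expect_true(got[20, 20])              # hole filled
  expect_true(all(got[mask]))           # extensive
})

test_that("morphological cleanup is increasing and extensive", {
  set.seed(17)
  for (trial in 1:5) {
    a <- matrix(runif(30^2) < 0.2, 30, 30)
    b <- a | (matrix(runif(30^2) < 0.1, 30, 30))
    fa <- morph_close_dilate(a, 2)
    fb <- morph_close_dilate(b, 2)
    expect_true(all(fa[a]))        # A subset of f(A)
    expect_true(all(fb[fa]))       # A subset of B implies f(A) subset of f(B)
  }
})

test_that("component labeling is 8-connected", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE   # diagonal touch
  m[5, 5] <- TRUE                    # separate
  lab <- spherequant:::label_components(m)
  expect_equal(max(lab), 2)
  expect_equal(lab[2, 2], lab[3, 3])
  expect_true(lab[5, 5] != lab[2, 2])
})
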
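test_that("clahe leaves a constant image constant", {
  out <- clahe(matrix(0.5, 64, 64), clip_limit = 0.01, tile_grid = c(8, 8))
  expect_lt(diff(range(out)), 1e-12)
  expect_lt(abs(out[1, 1] - 0.5), 1 / 256)
})

test_that("clahe with one tile and no clipping equals global equalization", {
  # two-level histogram, equal mass: mid-CDF maps 0.2 -> (0 + 0.5)/2 and
  # 0.8 -> (0.5 + 1)/2
  g <- matrix(rep(c(0.2, 0.8), each = 32 * 64), 64, 64)
  out <- clahe(g, clip_limit = 1, tile_grid = c(1, 1))
  expect_equal(sort(unique(as.numeric(out))), c(0.25, 0.75))
  expect_true(all(out[g == 0.2] == 0.25))
})

test_that("clahe approaches the identity as the clip limit vanishes", {
  set.seed(11)
  x <- matrix(runif(64^2), 64, 64)
  out <- clahe(x, clip_limit = 1e-9, tile_grid = c(1, 1))
  expect_lt(max(abs(out - x)), 0.02)
})

test_that("clahe does not reduce histogram entropy at clip limit 1", {
  entropy64 <- function(m) {
    p <- tabulate(pmin(floor(m * 64) + 1, 64), 64) / length(m)
    -sum(p[p > 0] * log2(p[p > 0]))
  }
  set.seed(21)
  for (i in 1:5) {
    x <- matrix(pmin(pmax(stats::rbeta(48^2, 2, 5), 0), 1), 48, 48)
    out <- clahe(x, clip_limit = 1, tile_grid = c(4, 4))
    expect_gte(entropy64(out), entropy64(x) - 1e-9)
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("clahe falls back to a global tile when the grid exceeds the image", {
  x <- matrix(runif(20 * 20), 20, 20)
  expect_warning(out <- clahe(x, 0.5, tile_grid = c(32, 32)), "global tile")
  expect_equal(out, suppressWarnings(clahe(x, 0.5, tile_grid = c(1, 1))))
})

test_that("gaussian smoothing preserves constants, ramps and the mean", {
  expect_equal(gaussian_smooth(matrix(0.3, 24, 24), 1.5), matrix(0.3, 24, 24))

  # affine functions are fixed points away from borders
  ramp <- matrix(seq(0, 1, length.out = 40), 40, 40)
  out <- gaussian_smooth(ramp, 1)
  expect_equal(out[10:30, 10:30], ramp[10:30, 10:30], tolerance = 1e-10)

  # interior-dominated image: a flat frame wider than the kernel half-size
  # makes the reflective boundary exact, so the mean is preserved
  set.seed(5)
  x <- matrix(0.5, 64, 64)
  x[12:53, 12:53] <- runif(42^2, 0.3, 0.7)
  expect_lt(abs(mean(gaussian_smooth(x, 2)) - mean(x)), 1e-6)
})

test_that("an impulse response equals the analytic normalized kernel peak", {
  sigma <- 2
  m <- matrix(0, 41, 41); m[21, 21] <- 1
  out <- gaussian_smooth(m, sigma)
  half <- ceiling(4 * sigma)
  g1 <- exp(-(-half:half)^2 / (2 * sigma^2))
  expect_equal(out[21, 21], 1 / sum(outer(g1, g1)) * max(outer(g1, g1)))
  expect_error(gaussian_smooth(m, 0), "positive")
})

test_that("gaussian smoothing has the semigroup property on interior pixels", {
  set.seed(9)
  x <- matrix(runif(80^2), 80, 80)
  twice <- gaussian_smooth(gaussian_smooth(x, 1.2), 1.6)
  once <- gaussian_smooth(x, sqrt(1.2^2 + 1.6^2))
  interior <- 20:60
  expect_lt(max(abs(twice[interior, interior] - once[interior, interior])), 1e-3)
})
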
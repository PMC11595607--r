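test_that("an empty scene renders the bare background", {
  sc <- generate_scene(scene_spec(spheres = list(), noise_sigma = 0,
                                  background = list(type = "uniform", level = 0.37)))
  expect_equal(sc$image$pixels, matrix(0.37, 256, 256))
  expect_equal(nrow(sc$truth), 0)
})

test_that("ground-truth areas match the pixel-distance oracle exactly", {
  for (r in c(6, 11.5, 20)) {
    sc <- generate_scene(scene_spec(
      spheres = list(list(center = c(100, 120), radius = r)), noise_sigma = 0))
    want <- sum(disk_mask(256, 256, c(100, 120), r))
    expect_equal(sc$truth$area_px, want)
    expect_setequal(attr(sc$truth, "masks")[[1]],
                    which(disk_mask(256, 256, c(100, 120), r)))
    # discretization bound vs the analytic disk area
    expect_lt(abs(want - pi * r^2), 4 * pi * r + 4)
  }
})

test_that("scene generation is deterministic per seed and leaves the RNG alone", {
  spec <- random_scene_spec(3, background = "microfluidic", seed = 99)
  a <- generate_scene(spec)
  set.seed(1); before <- runif(1)
  b <- generate_scene(spec)
  set.seed(1); after <- runif(1)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(before, after)

  other <- generate_scene(random_scene_spec(3, background = "microfluidic", seed = 100))
  expect_false(identical(a$image$pixels, other$image$pixels))
})

test_that("overlapping spheres are rejected unless explicitly allowed", {
  overlapping <- list(list(center = c(50, 50), radius = 10),
                      list(center = c(55, 55), radius = 10))
  expect_error(scene_spec(spheres = overlapping), "overlap")
  expect_silent(scene_spec(spheres = overlapping, allow_overlap = TRUE))
  expect_error(scene_spec(spheres = list(list(center = c(5, 50), radius = 10))),
               "bounds")
})

test_that("raising the noise level degrades detection F1 monotonically", {
  cal <- calibration("10x", 1)
  base <- random_scene_spec(5, seed = 42)
  # levels span the breakdown transition of the detector
  f1 <- vapply(c(0.15, 0.20, 0.25), function(ns) {
    sc <- generate_scene(scene_spec(image_size = base$image_size,
                                    spheres = base$spheres,
                                    background = base$background,
                                    noise_sigma = ns, seed = 42))
    f1_score(detect_spheres(sc$image, cal)$detections, sc$truth)
  }, 0)
  expect_true(all(diff(f1) < 0))
})
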
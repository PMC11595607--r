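cal1 <- calibration("10x", 1)

test_that("a flat image proposes no regions of interest", {
  resp <- apply_gabor_bank(matrix(0.5, 128, 128))
  expect_length(propose_rois(resp, pipeline_config()), 0)
})

test_that("region proposal brackets isolated disks", {
  sc <- generate_scene(scene_spec(
    spheres = list(list(center = c(128, 128), radius = 30)),
    noise_sigma = 0.01, seed = 4))
  pre <- gaussian_smooth(clahe(sc$image), 1)
  rois <- propose_rois(apply_gabor_bank(pre), pipeline_config())
  expect_length(rois, 1)
  b <- rois[[1]]$box
  expect_true(b[1] <= 98 && b[2] >= 158 && b[3] <= 98 && b[4] >= 158)

  sc2 <- generate_scene(scene_spec(
    spheres = list(list(center = c(64, 64), radius = 16),
                   list(center = c(192, 192), radius = 16)),
    noise_sigma = 0.01, seed = 4))
  pre2 <- gaussian_smooth(clahe(sc2$image), 1)
  rois2 <- propose_rois(apply_gabor_bank(pre2), pipeline_config())
  expect_length(rois2, 2)
  # sorted by (r0, c0) and disjoint
  expect_lt(rois2[[1]]$box[2], rois2[[2]]$box[1])
})

test_that("a blank image yields zero detections even with a forced ROI", {
  img <- gray_image(matrix(0.5, 64, 64))
  rois <- list(list(box = c(10, 50, 10, 50), score = 0))
  expect_length(extract_spheres(img, rois, pipeline_config(), cal1), 0)
  expect_error(
    extract_spheres(img, list(list(box = c(0, 80, 1, 30), score = 0)),
                    pipeline_config(), cal1),
    "out of bounds")
})

test_that("a disk is recovered with its analytic area and a speck is filtered", {
  sc <- generate_scene(scene_spec(
    spheres = list(list(center = c(128, 128), radius = 20),
                   list(center = c(60, 200), radius = 1.5, halo_width = 1)),
    noise_sigma = 0.01, seed = 6))
  res <- detect_spheres(sc$image, cal1)   # min area 300 um2 filters the speck
  expect_length(res$detections, 1)
  d <- res$detections[[1]]
  expect_lt(abs(d$area_um2 - pi * 400) / (pi * 400), 0.1)
  expect_equal(d$centroid, c(128, 128), tolerance = 0.5)
  expect_gt(d$circularity, 0.8)
  expect_lte(d$circularity, 1.1)
  expect_false(d$touches_border)
  expect_equal(d$equivalent_diameter_um, 2 * sqrt(d$area_um2 / pi))
})

test_that("numbering follows raster order with larger-area tie-break", {
  expect_length(number_spheres(list()), 0)

  d <- list(fake_detection(c(40, 5), 100), fake_detection(c(10, 50), 80))
  out <- number_spheres(d)
  expect_equal(vapply(out, function(x) x$label, 0L), c(1L, 2L))
  expect_equal(out[[1]]$centroid, c(10, 50))

  row3 <- list(fake_detection(c(20, 90), 50), fake_detection(c(20, 5), 50),
               fake_detection(c(20, 50), 50))
  lab <- number_spheres(row3)
  expect_equal(vapply(lab, function(x) x$centroid[2], 0), c(5, 50, 90))

  tie <- list(fake_detection(c(30, 30), 10), fake_detection(c(30, 30), 99))
  expect_equal(number_spheres(tie)[[1]]$area_px, 99)
})

test_that("labels are stable under permutations of the input", {
  set.seed(41)
  dets <- lapply(1:7, function(i) {
    fake_detection(c(runif(1, 1, 200), runif(1, 1, 200)), sample(50:500, 1))
  })
  ref <- number_spheres(dets)
  key <- function(l) vapply(l, function(d) paste(d$label, d$centroid[1], d$centroid[2]), "")
  for (p in 1:5) {
    got <- number_spheres(sample(dets))
    expect_equal(key(got), key(ref))
  }
})

test_that("duplicates across regions merge by overlap, keeping the larger", {
  big <- fake_detection(c(50, 50), 400, roi_index = 1L, pixels = 1:400)
  clipped <- fake_detection(c(48, 52), 120, roi_index = 2L, pixels = 1:120)
  separate <- fake_detection(c(150, 150), 90, roi_index = 2L, pixels = 5000:5089)
  out <- spherequant:::merge_duplicates(list(big, clipped, separate))
  expect_length(out, 2)
  expect_equal(vapply(out, function(d) d$area_px, 0), c(400, 90))
})
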
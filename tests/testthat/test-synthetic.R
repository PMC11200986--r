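# The synthetic quadruped generator: determinism, visibility semantics,
# scale mix, schema validity, and the overlay renderer.

test_that("generation is byte-identical under a fixed seed", {
  cfg <- synth_config(n_images = 3L, image_size = 64L, seed = 7L,
                      instances_per_image = 1L,
                      scale_mix = c(medium = 1, large = 0))
  sc <- load_keypoint_schema("ap10k")
  d1 <- tempfile("g1"); d2 <- tempfile("g2")
  generate_synthetic_dataset(cfg, sc, d1)
  generate_synthetic_dataset(cfg, sc, d2)
  j1 <- readBin(file.path(d1, "annotations.json"), "raw", 1e6)
  j2 <- readBin(file.path(d2, "annotations.json"), "raw", 1e6)
  expect_identical(j1, j2)
  p1 <- readBin(file.path(d1, "synth_0001.png"), "raw", 1e6)
  p2 <- readBin(file.path(d2, "synth_0001.png"), "raw", 1e6)
  expect_identical(p1, p2)
})

test_that("occlusion_rate = 0 yields only fully visible keypoints", {
  aset <- fixture_dataset(n_images = 6L, occlusion_rate = 0)
  for (a in aset$annotations) expect_true(all(a$keypoints[, 3] == 2))
  # nonzero occlusion produces some v = 1 but never v = 0
  cfg <- synth_config(n_images = 10L, image_size = 64L, seed = 3L,
                      instances_per_image = 1L,
                      scale_mix = c(medium = 1, large = 0), occlusion_rate = 0.5)
  as2 <- generate_synthetic_dataset(cfg, load_keypoint_schema("ap10k"),
                                    tempfile("occ"))
  vs <- unlist(lapply(as2$annotations, function(a) a$keypoints[, 3]))
  expect_true(any(vs == 1))
  expect_true(all(vs %in% c(1, 2)))
})

test_that("generator annotations pass schema and set validation", {
  aset <- fixture_dataset(n_images = 4L)
  # re-validating by reconstruction raises no error
  expect_silent(annotation_set(aset$images, aset$annotations, aset$schema))
  for (a in aset$annotations) {
    expect_equal(nrow(a$keypoints), 17L)
    expect_gt(a$area, 0)
    # keypoints inside the bbox
    vis <- a$keypoints[, 3] > 0
    expect_true(all(a$keypoints[vis, 1] >= a$bbox[1] - 1e-9))
    expect_true(all(a$keypoints[vis, 1] <= a$bbox[1] + a$bbox[3] + 1e-9))
  }
})

test_that("the empirical medium fraction honors the scale mix", {
  cfg <- synth_config(n_images = 300L, image_size = 192L,
                      instances_per_image = 1L,
                      scale_mix = c(medium = 0.5, large = 0.5),
                      occlusion_rate = 0, seed = 11L)
  # a roughly isotropic mini-schema so large instances always fit the frame
  sc3 <- keypoint_schema("tri", c("nose", "tail base", "left back paw"),
                         rbind(c(0L, 1L), c(1L, 2L)))
  aset <- generate_synthetic_dataset(cfg, sc3, tempfile("mix"))
  cls <- vapply(aset$annotations, function(a) partition_by_scale(a$area),
                character(1))
  n <- length(cls)
  frac <- mean(cls == "medium")
  se <- sqrt(0.25 / n)
  expect_lt(abs(frac - 0.5), 5 * se)
  expect_true(all(cls %in% c("medium", "large")))
})

test_that("instances that cannot fit the frame raise a generation error", {
  cfg <- synth_config(n_images = 1L, image_size = 48L,
                      instances_per_image = 1L,
                      scale_mix = c(medium = 0, large = 1), seed = 1L)
  expect_error(generate_synthetic_dataset(cfg, toy_schema(), tempfile("big")),
               "does not fit")
})

test_that("skeleton overlay draws only labeled primitives", {
  sc <- load_keypoint_schema("ap10k")
  img <- array(0.5, dim = c(64, 64, 3))
  kp_all0 <- cbind(runif(17, 10, 50), runif(17, 10, 50), 0)
  out0 <- render_skeleton_overlay(img, kp_all0, sc)
  expect_equal(unclass(out0)[1:64, 1:64, ], img[, , ], tolerance = 0)
  expect_equal(attr(out0, "n_markers"), 0L)
  expect_equal(attr(out0, "n_segments"), 0L)
  kp1 <- kp_all0; kp1[3, 3] <- 2
  out1 <- render_skeleton_overlay(img, kp1, sc)
  expect_equal(attr(out1, "n_markers"), 1L)
  expect_false(identical(unclass(out1)[1:64, 1:64, ], img[, , ]))
  kp_full <- cbind(runif(17, 10, 50), runif(17, 10, 50), 2)
  outf <- render_skeleton_overlay(img, kp_full, sc)
  expect_equal(attr(outf, "n_segments"), nrow(sc$skeleton))
  expect_equal(attr(outf, "n_markers"), 17L)
})

test_that("crop_resize maps keypoints consistently with its transform", {
  set.seed(14)
  img <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  bb <- c(8, 12, 32, 24)
  crop <- crop_resize(img, bb, 16L)
  expect_equal(dim(crop), c(16L, 16L, 3L))
  sc <- attr(crop, "scale"); off <- attr(crop, "offset")
  # a point at the bbox corner maps to the crop origin
  expect_equal((c(8, 12) - off) * sc, c(0, 0))
  expect_equal((c(8 + 32, 12 + 24) - off) * sc, c(16, 16))
  # constant image stays constant under resampling
  cimg <- array(0.42, dim = c(64, 64, 3))
  expect_equal(max(abs(crop_resize(cimg, bb, 16L) - 0.42)), 0)
})
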
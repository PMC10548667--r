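# Synthetic canopy generator: determinism, geometry and density calibration.

test_that("scenes are reproducible and boxes stay inside the image", {
  cfg <- scene_config(image_size = 160)
  a <- render_scene(cfg, seed = 11)
  b <- render_scene(cfg, seed = 11)
  expect_identical(a$ann$image, b$ann$image)
  expect_identical(a$ann$boxes, b$ann$boxes)
  if (nrow(a$ann$boxes) > 0) {
    expect_true(all(a$ann$boxes[, c(1, 3)] >= 0 & a$ann$boxes[, c(1, 3)] <= 160))
    expect_true(all(a$ann$boxes[, c(2, 4)] >= 0 & a$ann$boxes[, c(2, 4)] <= 160))
  }
  c2 <- render_scene(cfg, seed = 12)
  expect_false(identical(a$ann$image, c2$ann$image))
})

test_that("forced instance counts control the ground truth", {
  cfg <- scene_config(preset = "easy", image_size = 160)
  empty <- render_scene(cfg, seed = 5, force_count = 0)
  expect_equal(nrow(empty$ann$boxes), 0)

  one <- render_scene(scene_config(preset = "easy", image_size = 160,
                                   blur_range = c(0, 0), clutter = 0),
                      seed = 6, force_count = 1)
  expect_equal(nrow(one$ann$boxes), 1)
  # the single head is a bright region: pixels inside the box are brighter
  # than the image median (high-contrast easy preset)
  b <- one$ann$boxes[1, ]
  inside <- one$ann$image[(floor(b[2]) + 1):ceiling(b[4]),
                          (floor(b[1]) + 1):ceiling(b[3]), 1]
  expect_gt(max(inside), stats::median(one$ann$image[, , 1]) + 0.1)
})

test_that("rendered objects are visible against the background", {
  cfg <- scene_config(preset = "easy", image_size = 160)
  sc <- render_scene(cfg, seed = 21)
  img <- sc$ann$image
  med <- stats::median(img[, , 1])
  for (k in seq_len(nrow(sc$ann$boxes))) {
    b <- sc$ann$boxes[k, ]
    patch <- img[(floor(b[2]) + 1):ceiling(b[4]), (floor(b[1]) + 1):ceiling(b[3]), 1]
    expect_gt(max(abs(patch - med)), 0.05)
  }
})

test_that("the density law is right-skewed around the calibrated statistics", {
  cfg <- scene_config()
  x <- wheatlfanet:::wl_with_seed(123, sample_instance_count(cfg, 2000))
  expect_true(all(x >= 0))
  expect_gt(mean(x), median(x))           # right skew
  expect_true(abs(mean(x) - 42) < 3)
  expect_true(abs(median(x) - 24) <= 2)
})

test_that("datasets on disk are complete and regenerate identically", {
  cfg <- scene_config(preset = "easy", image_size = 128)
  dir1 <- file.path(tempdir(), "synth_t1")
  man1 <- generate_dataset(cfg, 5, dir1, seed = 2)
  expect_equal(nrow(man1), 5)
  expect_true(all(file.exists(man1$image)))
  expect_true(all(file.exists(man1$labels)))
  anns <- read_gwhd_csv(file.path(dir1, "annotations.csv"))
  expect_length(anns, 5)
  # per-image normalized labels agree with the csv annotations
  for (i in 1:5) {
    nb <- read_normalized_boxes(man1$labels[i], c(128, 128))
    expect_equal(nrow(anns[[i]]$boxes), nrow(nb))
    if (nrow(nb) > 0)
      expect_equal(unclass(nb), anns[[i]]$boxes, ignore_attr = TRUE, tolerance = 1e-3)
  }
  dir2 <- file.path(tempdir(), "synth_t2")
  man2 <- generate_dataset(cfg, 5, dir2, seed = 2)
  man2$image <- man1$image; man2$labels <- man1$labels  # paths differ by design
  expect_equal(man1, man2)
  expect_identical(read_image(man1$image[1]),
                   read_image(file.path(dir2, basename(man1$image[1]))))
  unlink(c(dir1, dir2), recursive = TRUE)
})
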
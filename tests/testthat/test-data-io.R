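# Annotation parsing, coordinate transforms and the dataset split.

test_that("gwhd csv parses box strings and the no_box sentinel", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("image_name,BoxesString,domain",
               "img_a,0 0 10 10;5 5 20 20,site1",
               "img_b,no_box,site2"), path)
  anns <- read_gwhd_csv(path)
  expect_length(anns, 2)
  expect_equal(nrow(anns[[1]]$boxes), 2)
  expect_equal(anns[[1]]$boxes[2, ], c(5, 5, 20, 20), ignore_attr = TRUE)
  expect_equal(nrow(anns[[2]]$boxes), 0)
  expect_equal(anns[[2]]$source, "site2")
  unlink(path)
})

test_that("gwhd csv round-trips coordinates exactly", {
  set.seed(400)
  anns <- list(
    annotated_image("a", NULL, cbind(runif(3, 0, 50), runif(3, 0, 50),
                                     runif(3, 60, 99), runif(3, 60, 99)), "s"),
    annotated_image("b", NULL, matrix(numeric(0), 0, 4), "s"))
  path <- tempfile(fileext = ".csv")
  write_gwhd_csv(anns, path)
  back <- read_gwhd_csv(path)
  expect_equal(back[[1]]$boxes, anns[[1]]$boxes, ignore_attr = TRUE)
  expect_equal(nrow(back[[2]]$boxes), 0)
  unlink(path)
})

test_that("malformed gwhd rows fail with the row index", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("image_name,BoxesString", "ok,0 0 5 5", "bad,1 2 3"), path)
  expect_error(read_gwhd_csv(path), "row 2")
  unlink(path)
})

test_that("normalized boxes convert between center and corner pixel form", {
  path <- tempfile(fileext = ".txt")
  writeLines("0 0.5 0.5 1 1", path)
  b <- read_normalized_boxes(path, c(640, 640))
  expect_equal(b[1, ], c(0, 0, 640, 640), ignore_attr = TRUE)

  writeLines("0 0.25 0.25 0.5 0.5", path)
  b <- read_normalized_boxes(path, c(200, 100))  # H = 200, W = 100
  expect_equal(b[1, ], c(0, 0, 50, 100), ignore_attr = TRUE)

  writeLines("0 1.5 0.5 0.2 0.2", path)
  expect_error(read_normalized_boxes(path, c(100, 100)), "line 1")

  # write(read(x)) is textually stable under canonical formatting
  boxes <- matrix(c(10, 20, 60, 90, 5, 5, 25, 45), 2, 4, byrow = TRUE)
  write_normalized_boxes(boxes, c(100, 100), path)
  txt1 <- readLines(path)
  b2 <- read_normalized_boxes(path, c(100, 100))
  write_normalized_boxes(unclass(b2), c(100, 100), path)
  expect_equal(readLines(path), txt1)
  expect_equal(unclass(b2), boxes, ignore_attr = TRUE, tolerance = 1e-4)
  unlink(path)
})

test_that("resize scales the long side and pads to the stride multiple", {
  set.seed(401)
  img <- array(runif(768 * 1024 * 3), c(768, 1024, 3))
  boxes <- matrix(c(100, 100, 300, 250), 1)
  rz <- resize_to_input(annotated_image("x", img, boxes), 640, 32)
  expect_equal(dim(rz$ann$image), c(480, 640, 3))  # 768 * 0.625 = 480
  expect_equal(rz$transform$scale, 0.625)
  expect_equal(rz$ann$boxes[1, ], boxes[1, ] * 0.625, ignore_attr = TRUE)

  # already conforming input is untouched
  img2 <- array(runif(640 * 640 * 3), c(640, 640, 3))
  rz2 <- resize_to_input(annotated_image("y", img2), 640, 32)
  expect_identical(rz2$ann$image, img2)
  expect_equal(rz2$transform$scale, 1)

  # detection round trip back to original coordinates
  dets <- data.frame(x1 = 62.5, y1 = 62.5, x2 = 187.5, y2 = 156.25,
                     confidence = 0.9)
  back <- detections_to_original(dets, rz$transform)
  expect_equal(as.numeric(back[1, 1:4]), c(100, 100, 300, 250), tolerance = 1e-6)
})

test_that("png image io round-trips at 8-bit precision", {
  set.seed(402)
  img <- array(round(runif(20 * 30 * 3) * 255) / 255, c(20, 30, 3))
  path <- tempfile(fileext = ".png")
  write_image(img, path)
  expect_equal(read_image(path), img, tolerance = 1e-9)
  unlink(path)
})

test_that("the 7:2:1 split reproduces the documented sizes", {
  sp <- split_dataset(seq_len(6387), seed = 3)
  expect_equal(lengths(sp), c(train = 4471, val = 1277, test = 639))
  sp10 <- split_dataset(seq_len(10), seed = 1)
  expect_equal(lengths(sp10), c(train = 7, val = 2, test = 1))

  # reproducible per seed; sizes are seed-independent
  expect_identical(split_dataset(1:100, seed = 7), split_dataset(1:100, seed = 7))
  other <- split_dataset(1:100, seed = 8)
  expect_equal(lengths(other), lengths(split_dataset(1:100, seed = 7)))
  expect_false(identical(other, split_dataset(1:100, seed = 7)))

  # disjoint and exhaustive
  all_ids <- sort(unlist(sp, use.names = FALSE))
  expect_equal(all_ids, seq_len(6387))
  expect_error(split_dataset(c(1, 1, 2)), "duplicate")
})
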
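# Detection and counting evaluation.

test_that("matching handles the degenerate and exact cases", {
  gts <- rand_boxes(4, lim = 30, min_size = 3)
  perfect <- data.frame(x1 = gts[, 1], y1 = gts[, 2], x2 = gts[, 3], y2 = gts[, 4],
                        confidence = runif(4))
  expect_equal(match_detections(perfect, gts, 0.5), c(tp = 4, fp = 0, fn = 0))
  expect_equal(match_detections(perfect[0, ], gts, 0.5), c(tp = 0, fp = 0, fn = 4))
})

test_that("matching agrees with a brute-force oracle", {
  set.seed(300)
  for (i in 1:40) {
    gts <- rand_boxes(sample(1:6, 1), lim = 28, min_size = 2)
    nd <- sample(1:8, 1)
    dets <- as.data.frame(rand_boxes(nd, lim = 28, min_size = 2))
    names(dets) <- c("x1", "y1", "x2", "y2")
    dets$confidence <- runif(nd)
    expect_equal(match_detections(dets, gts, 0.4), match_oracle(dets, gts, 0.4))
  }
})

test_that("precision/recall ratios and conventions", {
  expect_equal(precision_recall(9, 1, 3), c(precision = 0.9, recall = 0.75))
  expect_equal(precision_recall(0, 0, 0), c(precision = 0, recall = 0))
  expect_equal(precision_recall(5, 0, 0), c(precision = 1, recall = 1))
})

test_that("average precision integrates the precision envelope", {
  # perfect detector
  gts <- list(rand_boxes(3, lim = 30, min_size = 3))
  d <- as.data.frame(gts[[1]]); names(d) <- c("x1", "y1", "x2", "y2")
  d$confidence <- c(0.9, 0.8, 0.7)
  expect_equal(average_precision(list(d), gts)$ap, 1)
  # no detections
  expect_equal(average_precision(list(d[0, ]), gts)$ap, 0)
  expect_error(average_precision(list(d), list(rand_boxes(0))), "ground-truth")

  # hand-integrated toy curve: ranks TP, FP, TP, TP over 3 gts
  # recalls 1/3,1/3,2/3,1; precisions 1,1/2,2/3,3/4; envelope 1,3/4,3/4,3/4
  # AP = 1/3 * 1 + 1/3 * 3/4 + 1/3 * 3/4 = 5/6
  gt <- matrix(c(0, 0, 10, 10, 20, 20, 30, 30, 40, 40, 50, 50), 3, 4, byrow = TRUE)
  dets <- data.frame(
    x1 = c(0, 60, 20, 40), y1 = c(0, 60, 20, 40),
    x2 = c(10, 70, 30, 50), y2 = c(10, 70, 30, 50),
    confidence = c(0.9, 0.8, 0.7, 0.6))
  res <- average_precision(list(dets), list(gt), 0.5)
  expect_equal(res$ap, 1 / 3 + 1 / 4 + 1 / 4, tolerance = 1e-12)
})

test_that("adding a lowest-confidence false positive never raises AP", {
  set.seed(301)
  gts <- list(rand_boxes(5, lim = 30, min_size = 3))
  d <- as.data.frame(gts[[1]][1:3, ]); names(d) <- c("x1", "y1", "x2", "y2")
  d$confidence <- c(0.9, 0.8, 0.7)
  base <- average_precision(list(d), gts)$ap
  worse <- rbind(d, data.frame(x1 = 100, y1 = 100, x2 = 110, y2 = 110,
                               confidence = 0.01))
  expect_lte(average_precision(list(worse), gts)$ap, base)
})

test_that("counting metrics match direct arithmetic", {
  r <- counting_metrics(c(10, 20), c(12, 16))
  expect_equal(r$mae, 3)
  expect_equal(r$rmse, sqrt(10))
  expect_equal(r$mape, 20)
  g <- c(3, 7, 11, 19)
  expect_equal(counting_metrics(g, g)[c("mae", "rmse", "mape")],
               list(mae = 0, rmse = 0, mape = 0))
  expect_equal(counting_metrics(g, g)$r2, 1)
  # constant predictor at the mean has R^2 = 0
  expect_equal(counting_metrics(g, rep(mean(g), 4))$r2, 0)
  expect_error(counting_metrics(1:3, 1:4), "mismatch")
  # zero-count images are excluded from MAPE and flagged
  r0 <- counting_metrics(c(0, 10), c(2, 12))
  expect_equal(r0$mape, 20)
  expect_equal(r0$mape_excluded, 1)
})

test_that("rmse dominates mae on random count vectors", {
  set.seed(302)
  for (i in 1:30) {
    g <- rpois(20, 30); p <- pmax(0, g + sample(-5:5, 20, TRUE))
    r <- counting_metrics(g, p)
    expect_gte(r$rmse, r$mae - 1e-12)
  }
})

test_that("f1 is the harmonic mean with the documented special cases", {
  expect_equal(f1_score(1, 1), 1)
  expect_equal(f1_score(1, 0), 0)
  expect_equal(f1_score(0, 0), 0)
  expect_equal(f1_score(0.905, 0.843), 0.873, tolerance = 1e-3)
  set.seed(303)
  p <- runif(20); r <- runif(20)
  expect_equal(f1_score(p, r), f1_score(r, p))
  expect_true(all(f1_score(p, r) <= 2 * pmin(p, r) / (1 + pmin(p, r)) + 1e-12))
})

test_that("afc curve equals pointwise recomputation and integrates F1", {
  set.seed(304)
  gts <- list(rand_boxes(4, lim = 30, min_size = 3), rand_boxes(2, lim = 30, min_size = 3))
  dets <- lapply(gts, function(g) {
    d <- as.data.frame(g); names(d) <- c("x1", "y1", "x2", "y2")
    d$confidence <- runif(nrow(d), 0.3, 0.95)
    rbind(d, data.frame(x1 = 0, y1 = 25, x2 = 4, y2 = 29, confidence = 0.5))
  })
  grid <- seq(0, 1, by = 0.25)
  afc <- afc_curve(dets, gts, 0.5, grid)
  for (i in seq_along(grid)) {
    tot <- c(tp = 0, fp = 0, fn = 0)
    for (k in seq_along(dets)) {
      d <- dets[[k]][dets[[k]]$confidence >= grid[i], , drop = FALSE]
      tot <- tot + match_detections(d, gts[[k]], 0.5)
    }
    pr <- precision_recall(tot["tp"], tot["fp"], tot["fn"])
    expect_equal(afc$f1[i], unname(f1_score(pr["precision"], pr["recall"])))
  }
  expect_equal(afc$area,
               sum(diff(grid) * (afc$f1[-1] + afc$f1[-length(grid)]) / 2))
  # no detections: F1 identically zero
  empty <- lapply(dets, function(d) d[0, ])
  expect_equal(afc_curve(empty, gts, 0.5, grid)$area, 0)
  # perfect detector with confidence 1 everywhere
  perf <- lapply(gts, function(g) {
    d <- as.data.frame(g); names(d) <- c("x1", "y1", "x2", "y2")
    d$confidence <- 1
    d
  })
  expect_equal(afc_curve(perf, gts, 0.5, grid)$area, 1)
})

test_that("evaluation report combines detection and counting metrics", {
  gts <- list(rand_boxes(3, lim = 30, min_size = 3), rand_boxes(2, lim = 30, min_size = 3))
  dets <- lapply(gts, function(g) {
    d <- as.data.frame(g); names(d) <- c("x1", "y1", "x2", "y2")
    d$confidence <- 0.9
    d
  })
  rep <- evaluate_detections(dets, gts)
  expect_equal(rep$ap, 1)
  expect_equal(rep$precision, 1)
  expect_equal(rep$counting$mae, 0)
  expect_equal(rep$counting$r2, 1)
  path <- tempfile()
  write_eval_report(rep, path)
  js <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(js$ap, 1)
  expect_true(file.exists(paste0(path, "_counts.csv")))
  unlink(paste0(path, c(".json", "_counts.csv")))
})
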
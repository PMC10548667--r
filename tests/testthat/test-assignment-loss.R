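# Box geometry, the composite loss, and anchor assignment.

test_that("iou handles identity, disjoint and partial overlap", {
  expect_equal(iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(iou(c(0, 0, 10, 10), c(20, 20, 30, 30)), 0)
  expect_equal(iou(c(0, 0, 10, 10), c(5, 0, 15, 10)), 1 / 3)
  expect_equal(iou(c(3, 3, 3, 3), c(3, 3, 3, 3)), 0)  # both degenerate
})

test_that("iou is symmetric, bounded and agrees with rasterization", {
  set.seed(100)
  for (i in 1:150) {
    a <- rand_boxes(1); b <- rand_boxes(1)
    v <- iou(a, b)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, iou(b, a))
    expect_equal(v, raster_iou(a[1, ], b[1, ]), tolerance = 1e-9)
  }
})

test_that("localization loss has the documented fixed points and bounds", {
  b <- c(3, 4, 13, 24)
  expect_equal(localization_loss(b, b), 0)
  # concentric, same aspect ratio, half linear size: loss = 1 - IoU = 0.75
  expect_equal(localization_loss(c(5, 5, 15, 15), c(0, 0, 20, 20)), 0.75,
               tolerance = 1e-9)
  # far-separated equal boxes: center penalty pushes the loss above 1
  expect_gt(localization_loss(c(0, 0, 10, 10), c(500, 500, 510, 510)), 1)
  expect_error(localization_loss(c(0, 0, 1, 1), c(5, 5, 5, 9)), "zero")
})

test_that("localization loss is invariant to joint translation and scaling", {
  set.seed(101)
  for (i in 1:25) {
    p <- rand_boxes(1, min_size = 2); g <- rand_boxes(1, min_size = 2)
    base <- localization_loss(p, g)
    sh <- runif(2, -50, 50)
    expect_equal(localization_loss(p + rep(sh, 2), g + rep(sh, 2)), base,
                 tolerance = 1e-8)
    sc <- runif(1, 0.1, 20)
    expect_equal(localization_loss(p * sc, g * sc), base, tolerance = 1e-8)
  }
})

test_that("ciou gradient matches finite differences with frozen alpha", {
  set.seed(102)
  for (i in 1:5) {
    p <- c(runif(2, 5, 25), runif(2, 3, 15))
    g <- c(runif(2, 5, 25), runif(2, 3, 15))
    res <- wheatlfanet:::wl_ciou(matrix(p, 1), matrix(g, 1), grad = TRUE)
    base <- wheatlfanet:::wl_ciou(matrix(p, 1), matrix(g, 1))
    v0 <- (4 / pi^2) * (atan(g[3] / g[4]) - atan(p[3] / p[4]))^2
    alpha0 <- v0 / ((1 - base$iou) + v0 + 1e-9)
    loss_frozen <- function(pv) {
      r <- wheatlfanet:::wl_ciou(matrix(pv, 1), matrix(g, 1))
      v <- (4 / pi^2) * (atan(g[3] / g[4]) - atan(pv[3] / pv[4]))^2
      r$loss - (v / ((1 - r$iou) + v + 1e-9)) * v + alpha0 * v
    }
    eps <- 1e-6
    fd <- vapply(1:4, function(k) {
      pp <- p; pp[k] <- pp[k] + eps
      mm <- p; mm[k] <- mm[k] - eps
      (loss_frozen(pp) - loss_frozen(mm)) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(fd - res$grad)), 1e-6)
  }
})

test_that("bce with logits is exact and stable", {
  expect_equal(bce_with_logits(1, 0), log(2))
  expect_equal(bce_with_logits(0, 0), log(2))
  expect_lt(bce_with_logits(1, 30), 1e-12)        # confident correct
  expect_true(is.finite(bce_with_logits(0, 1000)))  # no overflow
  # mean normalization
  expect_equal(bce_with_logits(c(1, 0), c(0, 0)), log(2))
})

test_that("attenuation follows the printed formula", {
  expect_equal(attenuation(1, alpha_h = 0.25), 0)
  expect_equal(attenuation(0, alpha_h = 1, eps = 0), 1 - exp(-1))
  expect_equal(attenuation(-50, alpha_h = 1, eps = 0), 1, tolerance = 1e-10)
  # decreasing in x
  xs <- seq(-1, 1, by = 0.1)
  expect_true(all(diff(attenuation(xs)) < 0))
})

test_that("jx loss weights per-sample cross-entropy by the attenuation", {
  expect_lt(jx_loss(c(1 - 1e-12), c(1)), 1e-10)
  expect_equal(jx_loss(0.5, 0, alpha_h = 1, eps = 0),
               (1 - exp(-0.5)) * log(2), tolerance = 1e-12)
  # attenuation factors are <= 1, so jx never exceeds the unattenuated BCE
  set.seed(103)
  p <- runif(50, 0.01, 0.99); y <- rbinom(50, 1, 0.5)
  bce <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
  expect_lte(jx_loss(p, y), bce)
})

test_that("total loss is the weighted sum with the published weights", {
  expect_equal(total_loss(0, 0, 0)$total, 0)
  expect_equal(total_loss(1, 1, 1)$total, 1.05)
  expect_equal(total_loss(2, 2, 2)$total, 2 * total_loss(1, 1, 1)$total)
  expect_error(total_loss(-1, 0, 0), "negative")
  w <- loss_weights()
  expect_equal(c(w$loc, w$obj, w$cls), c(0.05, 0.7, 0.3))
})

test_that("assignment gives each gt its best anchor, deterministically", {
  cfg <- tiny_net_cfg()
  anchors <- anchor_grid(cfg, c(32, 32))
  # no ground truth: all negative
  res <- assign_targets(matrix(numeric(0), 0, 4), anchors)
  expect_equal(sum(res$objectness), 0)

  # a gt exactly equal to one anchor box: that anchor and only it is positive
  a17 <- anchors[17, ]
  res <- assign_targets(matrix(c(a17$x1, a17$y1, a17$x2, a17$y2), 1), anchors)
  expect_equal(sum(res$objectness), 1)
  expect_equal(which(res$objectness == 1), 17)
  expect_equal(res$positive$iou, 1)

  # exhaustive argmax oracle on random gts
  set.seed(104)
  for (i in 1:10) {
    gt <- rand_boxes(3, lim = 30, min_size = 2)
    res <- assign_targets(gt, anchors)
    ab <- as.matrix(anchors[, c("x1", "y1", "x2", "y2")])
    for (k in 1:3) {
      ious <- vapply(seq_len(nrow(ab)), function(j) pair_iou(gt[k, ], ab[j, ]),
                     numeric(1))
      expect_equal(res$positive[k, c("scale", "row", "col", "anchor")],
                   anchors[which.max(ious), c("scale", "row", "col", "anchor")],
                   ignore_attr = TRUE)
    }
  }
  expect_error(assign_targets(rand_boxes(1), anchors[0, ]), "empty")
})

test_that("loss gradients on head outputs match finite differences", {
  # center offsets (exact), objectness and class (attenuation held constant,
  # so agreement is to the size of the dropped derivative term)
  set.seed(105)
  cfg <- tiny_net_cfg()
  h8 <- array(rnorm(4 * 4 * 18 * 1, 0, 0.5), c(4, 4, 18, 1))
  h16 <- array(rnorm(2 * 2 * 18 * 1, 0, 0.5), c(2, 2, 18, 1))
  gts <- list(matrix(c(4, 6, 14, 12, 18, 20, 28, 30), 2, 4, byrow = TRUE))
  L <- function(hs) wheatlfanet:::wl_detection_loss(hs, gts, cfg, c(32, 32),
                                                    need_grad = FALSE)$total
  ls <- wheatlfanet:::wl_detection_loss(list(h8, h16), gts, cfg, c(32, 32))
  expect_true(all(is.finite(ls$grads[[1]])) && all(is.finite(ls$grads[[2]])))
  pos <- assign_targets(gts[[1]], anchor_grid(cfg, c(32, 32)))$positive[1, ]
  base <- (pos$anchor - 1) * 6
  eps <- 1e-6
  for (ch in base + c(1, 2)) {
    # center offsets: exact up to the non-differentiated CIoU alpha weight,
    # whose induced discrepancy is a few percent at most
    hp <- h8; hp[pos$row + 1, pos$col + 1, ch, 1] <- hp[pos$row + 1, pos$col + 1, ch, 1] + eps
    hm <- h8; hm[pos$row + 1, pos$col + 1, ch, 1] <- hm[pos$row + 1, pos$col + 1, ch, 1] - eps
    fd <- (L(list(hp, h16)) - L(list(hm, h16))) / (2 * eps)
    expect_equal(ls$grads[[1]][pos$row + 1, pos$col + 1, ch, 1], fd,
                 tolerance = 0.03)
  }
})
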
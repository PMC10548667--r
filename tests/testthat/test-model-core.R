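# Encoder/decoder building blocks and the assembled network.

test_that("conv block matches stride arithmetic and the SiLU fixed point", {
  set.seed(1)
  blk <- conv_block(3, 32, kernel = 3, stride = 2)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  y <- conv_block_forward(blk, x)
  expect_equal(dim(y), c(32, 32, 32))

  # zero kernel: conv output 0, BN(0) = 0 with fresh statistics, SiLU(0) = 0
  blk$w$value[] <- 0
  expect_equal(max(abs(conv_block_forward(blk, x))), 0)

  expect_error(conv_block(3, 8, kernel = 4), "odd")
  expect_error(conv_block_forward(conv_block(4, 8), x), "channels")
})

test_that("batch normalization standardizes with batch statistics", {
  # per-channel values {1, 3} across the batch -> {-1, +1} with unit scale
  blk <- conv_block(1, 1, kernel = 1, act = FALSE, eps = 1e-12)
  blk$w$value[] <- 1
  x <- array(c(1, 3), c(1, 1, 1, 2))
  y <- conv_block_forward(blk, x, train = TRUE)
  expect_equal(as.vector(y), c(-1, 1), tolerance = 1e-5)
})

test_that("conv forward agrees with a nested-loop oracle", {
  set.seed(42)
  for (case in list(c(k = 3, s = 1), c(k = 3, s = 2), c(k = 1, s = 1), c(k = 5, s = 1))) {
    x <- array(rnorm(12 * 10 * 3 * 2), c(12, 10, 3, 2))
    w <- array(rnorm(case["k"]^2 * 3 * 4), c(case["k"], case["k"], 3, 4))
    pad <- (case["k"] - 1) %/% 2
    got <- wheatlfanet:::.conv2d_fwd(x, w, NULL, as.integer(case["s"]), as.integer(pad))
    want <- naive_conv(x, w, case["s"], pad)
    expect_lt(max(abs(got - want)), 1e-5)
  }
})

test_that("bottleneck is a residual with the documented hidden width", {
  set.seed(2)
  blk <- bottleneck(64, expansion = 0.5)
  expect_equal(blk$n1, 32)  # n1 = c2 * e

  x <- array(rnorm(8 * 8 * 64), c(8, 8, 64))
  for (cv in c("cv1", "cv2", "cv3")) blk[[cv]]$w$value[] <- 0
  expect_equal(bottleneck_forward(blk, x), x)  # zero branch -> identity

  expect_error(bottleneck_forward(bottleneck(16), array(0, c(4, 4, 8))), "residual")
})

test_that("bottleneck forward matches a composed nested-loop oracle", {
  set.seed(3)
  blk <- bottleneck(8, expansion = 0.5)
  # make BN the identity so the oracle is the plain conv composition
  for (cv in c("cv1", "cv2", "cv3")) {
    bn <- blk[[cv]]$bn
    bn$run_mean[] <- 0
    bn$run_var[] <- 1 - bn$eps
  }
  x <- array(rnorm(4 * 4 * 8), c(4, 4, 8, 1))
  silu <- function(z) z * plogis(z)
  h <- silu(naive_conv(x, blk$cv1$w$value, 1, 0))
  h <- silu(naive_conv(h, blk$cv2$w$value, 1, 1))
  h <- silu(naive_conv(h, blk$cv3$w$value, 1, 1))
  want <- x + h
  got <- bottleneck_forward(blk, array(x, c(4, 4, 8)))
  expect_lt(max(abs(got - array(want, c(4, 4, 8)))), 1e-5)
})

test_that("csp layer parameter count matches the symbolic formula", {
  cnt_conv <- function(k, cin, cout) k * k * cin * cout + 2 * cout
  csp_count <- function(cin, cout, n) {
    h <- cout / 2; n1 <- h / 2
    cnt_conv(1, cin, cout) +
      n * (cnt_conv(1, h, n1) + cnt_conv(3, n1, n1) + cnt_conv(3, n1, h)) +
      cnt_conv(1, (2 + n) * h, cout)
  }
  set.seed(4)
  expect_equal(count_parameters(csp_layer(128, 128, n = 2)), csp_count(128, 128, 2))
  expect_equal(count_parameters(csp_layer(64, 32, n = 1)), csp_count(64, 32, 1))

  # stride-1 configuration preserves spatial dims
  blk <- csp_layer(16, 16, n = 2)
  y <- csp_layer_forward(blk, array(rnorm(9 * 7 * 16), c(9, 7, 16)))
  expect_equal(dim(y)[1:2], c(9, 7))
  expect_error(csp_layer(8, 7, n = 1), "even")
})

test_that("sppf pooling matches a sliding-max oracle and keeps spatial dims", {
  # stride-1 max pool: 5x5 integer input, kernel 3
  set.seed(5)
  x <- array(sample(1:99, 25), c(5, 5, 1, 1))
  y1 <- wheatlfanet:::.maxpool_fwd(x, 3L)$out
  want <- array(0, dim(x))
  for (i in 1:5) for (j in 1:5) {
    want[i, j, 1, 1] <- max(x[max(1, i - 1):min(5, i + 1), max(1, j - 1):min(5, j + 1), 1, 1])
  }
  expect_equal(y1, want)
  # cascade once more
  y2 <- wheatlfanet:::.maxpool_fwd(y1, 3L)$out
  want2 <- array(0, dim(x))
  for (i in 1:5) for (j in 1:5)
    want2[i, j, 1, 1] <- max(want[max(1, i - 1):min(5, i + 1), max(1, j - 1):min(5, j + 1), 1, 1])
  expect_equal(y2, want2)

  # constant plane is a fixed point of the pooling pyramid
  xc <- array(7, c(6, 6, 1, 1))
  expect_equal(wheatlfanet:::.maxpool_fwd(xc, 5L)$out, xc)

  blk <- simcspsppf(32, 32)
  out <- simcspsppf_forward(blk, array(rnorm(8 * 8 * 32), c(8, 8, 32)))
  expect_equal(dim(out), c(8, 8, 32))
  expect_error(simcspsppf_forward(simcspsppf(4, 4, pool_kernel = 31),
                                  array(0, c(3, 3, 4))), "kernel")
})

test_that("network has the documented shape algebra and batching", {
  set.seed(6)
  net <- build_network(tiny_net_cfg())
  x <- array(runif(96 * 64 * 3 * 2), c(96, 64, 3, 2))
  heads <- network_predict(net, x)
  expect_equal(dim(heads[[1]]), c(12, 8, 18, 2))   # stride 8
  expect_equal(dim(heads[[2]]), c(6, 4, 18, 2))    # stride 16
  # batch dimension: each sample independent of batch composition (eval BN)
  h1 <- network_predict(net, x[, , , 1, drop = FALSE])
  expect_equal(heads[[1]][, , , 1], h1[[1]][, , , 1], tolerance = 1e-10)
  expect_error(network_predict(net, array(0, c(50, 64, 3, 1))), "multiple")
})

test_that("parameter counting is exact on hand-counted layers", {
  set.seed(7)
  blk <- conv_block(3, 32, kernel = 3)            # no bias under BN
  expect_equal(count_parameters(blk), 3 * 3 * 3 * 32 + 2 * 32)  # 928
  net1 <- build_network(tiny_net_cfg())
  # parameter count is invariant to input size by construction (no input
  # size enters); flops scale linearly in H*W
  f1 <- estimate_flops(net1, 320)
  f2 <- estimate_flops(net1, 160)
  expect_equal(f1 / f2, 4)
})

test_that("single-conv flops match the hand count", {
  # one stride-1 conv 3->32 k3 on a 640x640 map: 2 * (864 * 640 * 640) flops
  set.seed(8)
  blk <- conv_block(3, 32, kernel = 3, stride = 1)  # scale 1 by default
  got <- 2 * blk$k^2 * blk$cin * blk$cout * (640 * blk$scale)^2
  expect_equal(got, 2 * 864 * 640 * 640)
  expect_equal(got / 1e9, 0.708, tolerance = 1e-3)
})

test_that("conv/BN fusion preserves outputs and reduces layers", {
  set.seed(9)
  net <- build_network(tiny_net_cfg())
  # randomize running statistics so fusion is non-trivial
  for (cv in wheatlfanet:::wl_net_convs(net)) {
    if (is.null(cv$bn)) next
    cv$bn$run_mean <- rnorm(length(cv$bn$run_mean), 0, 0.3)
    cv$bn$run_var <- runif(length(cv$bn$run_var), 0.5, 2)
    cv$bn$gamma$value <- runif(length(cv$bn$gamma$value), 0.5, 1.5)
    cv$bn$beta$value <- rnorm(length(cv$bn$beta$value), 0, 0.2)
  }
  fused <- fuse_conv_bn(net)
  for (rep in 1:3) {
    x <- array(runif(48 * 48 * 3 * 1), c(48, 48, 3, 1))
    a <- network_predict(net, x)
    b <- network_predict(fused, x)
    expect_lt(max(abs(a[[1]] - b[[1]]) / (abs(a[[1]]) + 1e-3)), 1e-5)
    expect_lt(max(abs(a[[2]] - b[[2]]) / (abs(a[[2]]) + 1e-3)), 1e-5)
  }
  expect_lt(wheatlfanet:::network_layer_count(fused),
            wheatlfanet:::network_layer_count(net))

  # identity statistics leave the kernel untouched
  blk <- conv_block(2, 2, kernel = 3, eps = 1e-3)
  blk$bn$run_mean[] <- 0
  blk$bn$run_var[] <- 1 - blk$bn$eps
  fblk <- wheatlfanet:::wl_fuse_conv(blk)
  expect_equal(fblk$w$value, blk$w$value, tolerance = 1e-12)
  expect_equal(fblk$b$value, c(0, 0), tolerance = 1e-12)

  # fused blocks have a bias in place of BN: 864 + 32 for a 3->32 k3 block
  set.seed(10)
  fb <- wheatlfanet:::wl_fuse_conv(conv_block(3, 32, kernel = 3))
  expect_equal(count_parameters(fb), 864 + 32)

  net$training <- TRUE
  expect_error(fuse_conv_bn(net), "training")
  net$training <- FALSE
  expect_error(wheatlfanet:::forward_network(fused, array(0, c(48, 48, 3, 1)),
                                             train = TRUE), "fused")
})

test_that("checkpoints round-trip the network exactly", {
  set.seed(11)
  net <- build_network(tiny_net_cfg())
  x <- array(runif(48 * 48 * 3), c(48, 48, 3, 1))
  a <- network_predict(net, x)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(net, path)
  net2 <- load_checkpoint(path)
  b <- network_predict(net2, x)
  expect_equal(a, b, tolerance = 1e-12)
  # fused checkpoint round trip
  f <- fuse_conv_bn(net)
  save_checkpoint(f, path)
  f2 <- load_checkpoint(path)
  expect_equal(network_predict(f2, x), network_predict(f, x), tolerance = 1e-12)
  unlink(path)
})

test_that("forward passes are deterministic given fixed weights", {
  set.seed(12)
  net <- build_network(tiny_net_cfg())
  x <- array(runif(48 * 48 * 3), c(48, 48, 3, 1))
  expect_identical(network_predict(net, x), network_predict(net, x))
})
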
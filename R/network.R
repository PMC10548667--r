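# WheatLFANet: stem + three CSP encoder stages, SimCSPSPPF neck, cross-stage
# fusion decoder, and two anchor-based prediction heads at strides 8 and 16.

#' Network configuration
#'
#' Complete architectural hyperparameters from which the network is built
#' deterministically. The defaults are the published configuration: stage
#' output widths 32/64/128, two detection scales at strides 8 and 16, three
#' anchors per scale. Stage depths (the number of bottlenecks per CSPLayer)
#' are the designated tuning knob of the family; the defaults (2, 2, 3) for
#' the encoder, 2 for the post-neck CSPLayer and (2, 2) for the decoder give
#' 721,028 trainable parameters (0.72 M) and 4.06 GFLOPs at 640x640.
#'
#' @param widths encoder stage output channels (C1, C2, C3).
#' @param depths bottlenecks per encoder-stage CSPLayer.
#' @param neck_depth bottlenecks in the CSPLayer after the SimCSPSPPF neck.
#' @param decoder_depths bottlenecks in the two decoder CSPLayers
#'   (stride-8 branch, stride-16 branch).
#' @param stem_mid output channels of the first stem convolution.
#' @param num_classes object classes (wheat varieties are merged into one).
#' @param anchors_per_scale anchor shapes per prediction scale.
#' @param anchor_sizes list of per-scale matrices (anchors x 2, width/height
#'   in input pixels).
#' @param strides output strides of the prediction heads (increasing).
#' @param input_stride_multiple images are padded so H and W are multiples of
#'   this before entering the network.
#' @param bn_eps,bn_momentum batch-normalization variance floor and
#'   running-statistics update rate.
#' @return a `wl_config` list.
#' @export
network_config <- function(widths = c(32, 64, 128),
                           depths = c(2, 2, 3),
                           neck_depth = 2,
                           decoder_depths = c(2, 2),
                           stem_mid = widths[1],
                           num_classes = 1,
                           anchors_per_scale = 3,
                           anchor_sizes = list(
                             matrix(c(12, 16, 19, 36, 40, 28), ncol = 2, byrow = TRUE),
                             matrix(c(36, 75, 76, 55, 72, 146), ncol = 2, byrow = TRUE)),
                           strides = c(8, 16),
                           input_stride_multiple = 32,
                           bn_eps = 1e-3,
                           bn_momentum = 0.03) {
  stopifnot(length(widths) == 3, all(widths > 0), all(widths %% 2 == 0),
            length(depths) == 3, all(depths >= 1),
            all(diff(strides) > 0), length(anchor_sizes) == length(strides))
  for (a in anchor_sizes) stopifnot(nrow(a) == anchors_per_scale, ncol(a) == 2)
  structure(list(widths = widths, depths = depths, neck_depth = neck_depth,
                 decoder_depths = decoder_depths, stem_mid = stem_mid,
                 num_classes = num_classes, anchors_per_scale = anchors_per_scale,
                 anchor_sizes = anchor_sizes, strides = strides,
                 input_stride_multiple = input_stride_multiple,
                 bn_eps = bn_eps, bn_momentum = bn_momentum),
            class = "wl_config")
}

wl_set_scale <- function(blk, scale) {
  if (blk$kind == "conv") {
    blk$scale <- scale
    return(blk)
  }
  for (nm in names(blk)) {
    if (is.list(blk[[nm]]) && !is.null(blk[[nm]]$kind))
      blk[[nm]] <- wl_set_scale(blk[[nm]], scale)
  }
  if (!is.null(blk$bnecks))
    blk$bnecks <- lapply(blk$bnecks, wl_set_scale, scale = scale)
  blk
}

#' Build the detector network
#'
#' Constructs the full network from a [network_config()]: a stem of two
#' overlapping stride-2 3x3 convolutions (to 1/4 resolution), three CSP
#' encoder stages, the SimCSPSPPF neck plus a CSPLayer at stride 16, a
#' nearest-neighbour x2 upsample merged with the stride-8 encoder output for
#' the first decoded map, a stride-2 fusion branch rejoining the neck for the
#' second, and one 1x1 prediction convolution per scale emitting
#' `anchors_per_scale * (5 + num_classes)` channels. Weight initialization
#' draws from the current RNG state; seed before calling for reproducible
#' weights. The objectness bias starts at logit(0.01) so the untrained
#' network predicts a sparse foreground.
#'
#' @param cfg a [network_config()].
#' @return a `wl_network` environment.
#' @export
build_network <- function(cfg = network_config()) {
  C1 <- cfg$widths[1]; C2 <- cfg$widths[2]; C3 <- cfg$widths[3]
  eps <- cfg$bn_eps
  nout <- cfg$anchors_per_scale * (5 + cfg$num_classes)
  cb <- function(...) conv_block(..., eps = eps)
  layers <- list(
    stem1 = wl_set_scale(cb(3, cfg$stem_mid, 3, 2), 1 / 2),
    stem2 = wl_set_scale(cb(cfg$stem_mid, C1, 3, 2), 1 / 4),
    csp1 = wl_set_scale(csp_layer(C1, C1, cfg$depths[1]), 1 / 4),
    down2 = wl_set_scale(cb(C1, C2, 3, 2), 1 / 8),
    csp2 = wl_set_scale(csp_layer(C2, C2, cfg$depths[2]), 1 / 8),
    down3 = wl_set_scale(cb(C2, C3, 3, 2), 1 / 16),
    csp3 = wl_set_scale(csp_layer(C3, C3, cfg$depths[3]), 1 / 16),
    sppf = wl_set_scale(simcspsppf(C3, C3), 1 / 16),
    neck = wl_set_scale(csp_layer(C3, C3, cfg$neck_depth), 1 / 16),
    lat = wl_set_scale(cb(C3, C2, 1, 1), 1 / 8),
    dec1 = wl_set_scale(csp_layer(2 * C2, C2, cfg$decoder_depths[1]), 1 / 8),
    head8 = wl_set_scale(cb(C2, nout, 1, 1, act = FALSE, bn = FALSE), 1 / 8),
    downf = wl_set_scale(cb(C2, C2, 3, 2), 1 / 16),
    dec2 = wl_set_scale(csp_layer(C2 + C3, C3, cfg$decoder_depths[2]), 1 / 16),
    head16 = wl_set_scale(cb(C3, nout, 1, 1, act = FALSE, bn = FALSE), 1 / 16)
  )
  for (hd in c("head8", "head16")) {
    b <- layers[[hd]]$b$value
    obj_idx <- (seq_len(cfg$anchors_per_scale) - 1) * (5 + cfg$num_classes) + 5
    b[obj_idx] <- log(0.01 / 0.99)
    layers[[hd]]$b$value <- b
  }
  net <- new.env(parent = emptyenv())
  net$cfg <- cfg
  net$layers <- layers
  net$training <- FALSE
  net$fused <- FALSE
  class(net) <- "wl_network"
  net
}

# Forward pass. `x` is (H, W, 3, N); returns a list of raw head outputs, one
# per configured stride, each (H/s, W/s, A*(5+nc), N). When `ctx` is a tape
# the pass is recorded for backprop.
forward_network <- function(net, x, train = FALSE, ctx = NULL) {
  d <- dim(wl_val(x))
  if (d[1] %% 16 != 0 || d[2] %% 16 != 0)
    stop("network input dimensions must be multiples of 16, got ",
         d[1], "x", d[2], " (pad with resize_to_input)")
  if (train && net$fused) stop("cannot run a fused network in training mode")
  L <- net$layers
  y <- wl_conv_fwd(ctx, L$stem1, x, train)
  y <- wl_conv_fwd(ctx, L$stem2, y, train)
  y <- wl_csp_fwd(ctx, L$csp1, y, train)
  y <- wl_conv_fwd(ctx, L$down2, y, train)
  e2 <- wl_csp_fwd(ctx, L$csp2, y, train)
  y <- wl_conv_fwd(ctx, L$down3, e2, train)
  y <- wl_csp_fwd(ctx, L$csp3, y, train)
  y <- wl_sppf_fwd(ctx, L$sppf, y, train)
  nk <- wl_csp_fwd(ctx, L$neck, y, train)
  u <- wl_conv_fwd(ctx, L$lat, op_upsample2x(ctx, nk), train)
  d1 <- wl_csp_fwd(ctx, L$dec1, op_concat_c(ctx, list(u, e2)), train)
  p8 <- wl_conv_fwd(ctx, L$head8, d1, train)
  f <- wl_conv_fwd(ctx, L$downf, d1, train)
  d2 <- wl_csp_fwd(ctx, L$dec2, op_concat_c(ctx, list(f, nk)), train)
  p16 <- wl_conv_fwd(ctx, L$head16, d2, train)
  list(p8, p16)
}

#' Predict raw head outputs for a batch of images
#'
#' Runs the network in inference mode. Use [decode_predictions()] and [nms()]
#' to turn the raw grids into detections.
#'
#' @param net a `wl_network`.
#' @param x image array (H, W, 3) or (H, W, 3, N), values in `[0, 1]`,
#'   H and W multiples of 16.
#' @return list of per-scale raw output arrays.
#' @export
network_predict <- function(net, x) {
  forward_network(net, wl_batched(x), train = FALSE, ctx = NULL)
}

wl_net_params <- function(net) {
  out <- list()
  for (nm in names(net$layers))
    out <- c(out, wl_layer_params(net$layers[[nm]], paste0(nm, ".")))
  out
}

wl_net_convs <- function(net) {
  out <- list()
  for (nm in names(net$layers))
    out <- c(out, wl_layer_convs(net$layers[[nm]], paste0(nm, ".")))
  out
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars: convolution kernels, biases and BN
#' scale/shift. Running BN statistics are buffers, not parameters. The count
#' does not depend on input size.
#'
#' @param x a `wl_network` or a single layer object.
#' @return integer count.
#' @export
count_parameters <- function(x) {
  ps <- if (inherits(x, "wl_network")) wl_net_params(x) else wl_layer_params(x)
  sum(vapply(ps, function(p) length(p$value), numeric(1)))
}

#' Estimate inference FLOPs
#'
#' Floating-point operations of one inference pass, using the common
#' 2-operations-per-multiply-accumulate convention and counting convolution
#' layers only (BN, activations, pooling and resampling are excluded). FLOPs
#' scale linearly with input area.
#'
#' @param net a `wl_network`.
#' @param input_hw input height/width, length-1 or length-2; multiples of 16.
#' @return FLOPs as a numeric scalar (divide by 1e9 for GFLOPs).
#' @export
estimate_flops <- function(net, input_hw = c(640, 640)) {
  if (length(input_hw) == 1) input_hw <- rep(input_hw, 2)
  convs <- wl_net_convs(net)
  sum(vapply(convs, function(cv) {
    2 * cv$k^2 * cv$cin * cv$cout * (input_hw[1] * cv$scale) * (input_hw[2] * cv$scale)
  }, numeric(1)))
}

# Number of primitive layers (each conv2d and each BN counts as one).
network_layer_count <- function(net) {
  convs <- wl_net_convs(net)
  sum(vapply(convs, function(cv) 1L + (!is.null(cv$bn)), integer(1)))
}

wl_fuse_conv <- function(blk) {
  if (blk$kind == "conv") {
    if (is.null(blk$bn)) {
      blk$w <- wl_param(blk$w$value)
      if (!is.null(blk$b)) blk$b <- wl_param(blk$b$value)
      return(blk)
    }
    s <- blk$bn$gamma$value / sqrt(blk$bn$run_var + blk$bn$eps)
    w <- blk$w$value
    for (co in seq_len(blk$cout)) w[, , , co] <- w[, , , co] * s[co]
    b <- blk$bn$beta$value - blk$bn$run_mean * s
    blk$w <- wl_param(w)
    blk$b <- wl_param(b)
    blk$bn <- NULL
    return(blk)
  }
  for (nm in names(blk)) {
    if (is.list(blk[[nm]]) && !is.null(blk[[nm]]$kind))
      blk[[nm]] <- wl_fuse_conv(blk[[nm]])
  }
  if (!is.null(blk$bnecks)) blk$bnecks <- lapply(blk$bnecks, wl_fuse_conv)
  blk
}

#' Fuse convolution and batch-normalization layers
#'
#' Folds each frozen BN layer into the preceding convolution:
#' `W' = W * gamma / sqrt(var + eps)` per output channel and
#' `b' = beta - mean * gamma / sqrt(var + eps)`. The fused network computes
#' identical outputs in inference mode with strictly fewer layers; it cannot
#' be trained further.
#'
#' @param net a `wl_network` in inference mode.
#' @return a new fused `wl_network` (the input is left untouched).
#' @export
fuse_conv_bn <- function(net) {
  if (net$training) stop("fuse_conv_bn: network is in training mode; BN statistics are not frozen")
  out <- new.env(parent = emptyenv())
  out$cfg <- net$cfg
  out$layers <- lapply(net$layers, wl_fuse_conv)
  out$training <- FALSE
  out$fused <- TRUE
  class(out) <- "wl_network"
  out
}

#' Save / load a network checkpoint
#'
#' A checkpoint is a single serialized file holding the [network_config()],
#' every weight array keyed by a stable layer path, the BN running statistics
#' and the fused flag.
#'
#' @param net a `wl_network`.
#' @param path file path.
#' @export
save_checkpoint <- function(net, path) {
  ps <- wl_net_params(net)
  state <- lapply(ps, function(p) p$value)
  run <- list()
  convs <- wl_net_convs(net)
  for (nm in names(convs)) {
    cv <- convs[[nm]]
    if (!is.null(cv$bn))
      run[[nm]] <- list(mean = cv$bn$run_mean, var = cv$bn$run_var)
  }
  saveRDS(list(cfg = net$cfg, state = state, running = run, fused = net$fused), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns the restored `wl_network`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  net <- build_network(ck$cfg)
  if (ck$fused) net <- fuse_conv_bn(net)
  ps <- wl_net_params(net)
  stopifnot(setequal(names(ps), names(ck$state)))
  for (nm in names(ps)) ps[[nm]]$value <- ck$state[[nm]]
  convs <- wl_net_convs(net)
  for (nm in names(ck$running)) {
    convs[[nm]]$bn$run_mean <- ck$running[[nm]]$mean
    convs[[nm]]$bn$run_var <- ck$running[[nm]]$var
  }
  net
}

#' Summarize network complexity
#'
#' Prints trainable parameters (in millions, two decimals), GFLOPs at the
#' given input size, and per-layer output shapes.
#'
#' @param net a `wl_network`.
#' @param input_hw input size used for the FLOPs figure.
#' @return invisibly, a list with `params`, `params_m`, `gflops` and a
#'   per-convolution data frame.
#' @export
network_info <- function(net, input_hw = c(640, 640)) {
  if (length(input_hw) == 1) input_hw <- rep(input_hw, 2)
  p <- count_parameters(net)
  g <- estimate_flops(net, input_hw) / 1e9
  convs <- wl_net_convs(net)
  df <- data.frame(
    layer = names(convs),
    kernel = vapply(convs, function(cv) cv$k, numeric(1)),
    in_ch = vapply(convs, function(cv) cv$cin, numeric(1)),
    out_ch = vapply(convs, function(cv) cv$cout, numeric(1)),
    out_h = vapply(convs, function(cv) input_hw[1] * cv$scale, numeric(1)),
    out_w = vapply(convs, function(cv) input_hw[2] * cv$scale, numeric(1)),
    row.names = NULL)
  cat(sprintf("params: %.2f M (%d)\n", p / 1e6, p))
  cat(sprintf("flops: %.2f GFLOPs @ %dx%d\n", g, input_hw[1], input_hw[2]))
  invisible(list(params = p, params_m = round(p / 1e6, 2), gflops = g, layers = df))
}
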
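# Network building blocks: Conv (Conv2d + BN + SiLU), residual Bottleneck,
# CSPLayer and the SimCSPSPPF pyramid-pooling neck.

wl_bn_new <- function(channels, eps = 1e-3, momentum = 0.03) {
  bn <- new.env(parent = emptyenv())
  bn$gamma <- wl_param(rep(1, channels))
  bn$beta <- wl_param(rep(0, channels))
  bn$run_mean <- rep(0, channels)
  bn$run_var <- rep(1, channels)
  bn$eps <- eps
  bn$momentum <- momentum
  bn
}

#' Convolution block (Conv2d + batch norm + SiLU)
#'
#' The elementary layer of the network: a 2-D convolution with an odd square
#' kernel and `(k-1)/2` zero padding, batch normalization over the batch and
#' spatial axes of each channel, and the SiLU activation `z * sigmoid(z)`.
#' Convolutions followed by BN carry no bias (it would be absorbed by the
#' normalization); blocks built with `bn = FALSE` (the prediction heads) get a
#' bias instead.
#'
#' @param in_channels,out_channels channel counts.
#' @param kernel odd kernel size.
#' @param stride 1 or 2 (stride 2 halves the spatial dimensions).
#' @param act apply SiLU (`TRUE` for all but the prediction heads).
#' @param bn apply batch normalization.
#' @param eps BN variance floor.
#' @return an opaque layer object for [conv_block_forward()].
#' @export
conv_block <- function(in_channels, out_channels, kernel = 3, stride = 1,
                       act = TRUE, bn = TRUE, eps = 1e-3) {
  if (kernel %% 2 != 1) stop("conv_block: kernel size must be odd, got ", kernel)
  if (!stride %in% c(1, 2)) stop("conv_block: stride must be 1 or 2")
  if (eps <= 0) stop("conv_block: eps must be positive")
  fan_in <- kernel * kernel * in_channels
  bound <- sqrt(6 / fan_in)
  w <- array(runif(fan_in * out_channels, -bound, bound),
             c(kernel, kernel, in_channels, out_channels))
  list(kind = "conv", w = wl_param(w),
       b = if (bn) NULL else wl_param(rep(0, out_channels)),
       bn = if (bn) wl_bn_new(out_channels, eps = eps) else NULL,
       cin = in_channels, cout = out_channels, k = kernel,
       stride = stride, pad = (kernel - 1) %/% 2, act = act, scale = 1)
}

wl_conv_fwd <- function(ctx, blk, x, train) {
  xv <- wl_val(x)
  if (dim(xv)[3] != blk$cin)
    stop("conv block: input has ", dim(xv)[3], " channels, expected ", blk$cin)
  y <- op_conv(ctx, x, blk$w, blk$b, blk$stride, blk$pad)
  if (!is.null(blk$bn)) y <- op_bn(ctx, y, blk$bn, train)
  if (blk$act) y <- op_silu(ctx, y)
  y
}

#' Run a convolution block
#'
#' @param block a layer from [conv_block()].
#' @param x input array of shape (H, W, C) or (H, W, C, N).
#' @param train use batch statistics in BN (and update running statistics);
#'   otherwise running statistics are applied.
#' @return output array; stride-2 blocks halve H and W.
#' @export
conv_block_forward <- function(block, x, train = FALSE) {
  wl_plain(wl_conv_fwd(NULL, block, wl_batched(x), train), x)
}

# accept (H,W,C) for user-facing forwards, keep (H,W,C,N) internally
wl_batched <- function(x) {
  if (length(dim(x)) == 3) array(x, c(dim(x), 1)) else x
}
wl_plain <- function(y, x_orig) {
  if (length(dim(x_orig)) == 3) array(y, dim(y)[1:3]) else y
}

#' Residual bottleneck block
#'
#' The CSPLayer's gradient branch: a 1x1 convolution reducing to
#' `n1 = round(channels * expansion)` hidden channels, a `kernel1` convolution
#' at the hidden width, a `kernel2` convolution restoring `channels`, and a
#' residual addition of the input. Input and output channel counts must match
#' for the residual form.
#'
#' @param channels input = output channel count.
#' @param expansion hidden-width fraction in (0, 1].
#' @param kernel1,kernel2 odd kernel sizes of the two inner convolutions.
#' @return an opaque layer object for [bottleneck_forward()].
#' @export
bottleneck <- function(channels, expansion = 0.5, kernel1 = 3, kernel2 = 3) {
  if (expansion <= 0 || expansion > 1) stop("bottleneck: expansion must be in (0,1]")
  n1 <- max(1L, as.integer(round(channels * expansion)))
  list(kind = "bottleneck",
       cv1 = conv_block(channels, n1, kernel = 1),
       cv2 = conv_block(n1, n1, kernel = kernel1),
       cv3 = conv_block(n1, channels, kernel = kernel2),
       channels = channels, n1 = n1)
}

wl_bneck_fwd <- function(ctx, blk, x, train) {
  y <- wl_conv_fwd(ctx, blk$cv1, x, train)
  y <- wl_conv_fwd(ctx, blk$cv2, y, train)
  y <- wl_conv_fwd(ctx, blk$cv3, y, train)
  op_add(ctx, x, y)
}

#' @rdname bottleneck
#' @param block a layer from [bottleneck()].
#' @param x input array (H, W, C) or (H, W, C, N) with C = `channels`.
#' @param train BN mode, see [conv_block_forward()].
#' @export
bottleneck_forward <- function(block, x, train = FALSE) {
  xb <- wl_batched(x)
  if (dim(xb)[3] != block$channels)
    stop("bottleneck: residual form requires input channels == output channels")
  wl_plain(wl_bneck_fwd(NULL, block, xb, train), x)
}

#' Cross-stage partial layer
#'
#' An entry 1x1 convolution maps to `out_channels`, the result is split into
#' two equal halves, one half runs through `n` stacked residual bottlenecks,
#' and the two halves together with every intermediate bottleneck output are
#' concatenated and projected back to `out_channels` by an exit 1x1
#' convolution. Only part of the feature map flows through the heavy branch,
#' which keeps parameters low while preserving gradient diversity.
#'
#' @param in_channels,out_channels channel counts; `out_channels` must be even
#'   so the split halves match.
#' @param n number of stacked bottlenecks (depth knob).
#' @param expansion bottleneck hidden-width fraction.
#' @return an opaque layer object for [csp_layer_forward()].
#' @export
csp_layer <- function(in_channels, out_channels, n = 1, expansion = 0.5) {
  if (out_channels %% 2 != 0) stop("csp_layer: out_channels must be even")
  if (n < 1) stop("csp_layer: n must be >= 1")
  h <- out_channels %/% 2
  list(kind = "csp",
       entry = conv_block(in_channels, out_channels, kernel = 1),
       bnecks = lapply(seq_len(n), function(i) bottleneck(h, expansion)),
       exit = conv_block((2 + n) * h, out_channels, kernel = 1),
       h = h, n = n, cin = in_channels, cout = out_channels)
}

wl_csp_fwd <- function(ctx, blk, x, train) {
  y <- wl_conv_fwd(ctx, blk$entry, x, train)
  h <- blk$h
  a <- op_slice_c(ctx, y, 0L, h)
  b <- op_slice_c(ctx, y, h, h)
  parts <- list(a, b)
  cur <- b
  for (bn in blk$bnecks) {
    cur <- wl_bneck_fwd(ctx, bn, cur, train)
    parts <- c(parts, list(cur))
  }
  wl_conv_fwd(ctx, blk$exit, op_concat_c(ctx, parts), train)
}

#' @rdname csp_layer
#' @param block a layer from [csp_layer()].
#' @param x input array (H, W, C) or (H, W, C, N).
#' @param train BN mode, see [conv_block_forward()].
#' @export
csp_layer_forward <- function(block, x, train = FALSE) {
  wl_plain(wl_csp_fwd(NULL, block, wl_batched(x), train), x)
}

#' Simplified CSP spatial-pyramid-pooling-fast neck
#'
#' Operates on the stride-16 encoder output. One branch (`x1`) passes through
#' 1x1 / 3x3 / 1x1 convolutions at the hidden width and then three cascaded
#' stride-1 max pools sharing one kernel, so the concatenation
#' `[x1, y1, y2, maxpool(y2)]` stacks receptive fields of increasing size at
#' unchanged resolution; a parallel 1x1 branch (`y0`) preserves positional
#' detail and is concatenated with the pooled branch before the output 1x1
#' convolution.
#'
#' @param in_channels,out_channels channel counts.
#' @param pool_kernel odd max-pool kernel (stride 1, `(k-1)/2` padding).
#' @param hidden_channels internal width; defaults to `out_channels / 2`.
#' @return an opaque layer object for [simcspsppf_forward()].
#' @export
simcspsppf <- function(in_channels, out_channels, pool_kernel = 5,
                       hidden_channels = out_channels %/% 2) {
  if (pool_kernel %% 2 != 1) stop("simcspsppf: pool kernel must be odd")
  hc <- hidden_channels
  list(kind = "sppf",
       cv1 = conv_block(in_channels, hc, kernel = 1),
       cv2 = conv_block(hc, hc, kernel = 3),
       cv3 = conv_block(hc, hc, kernel = 1),
       cv0 = conv_block(in_channels, hc, kernel = 1),
       cv4 = conv_block(4 * hc, hc, kernel = 1),
       cv5 = conv_block(hc, hc, kernel = 3),
       out = conv_block(2 * hc, out_channels, kernel = 1),
       k = pool_kernel, hc = hc, cin = in_channels, cout = out_channels)
}

wl_sppf_fwd <- function(ctx, blk, x, train) {
  d <- dim(wl_val(x))
  pad <- (blk$k - 1) %/% 2
  if (blk$k > d[1] + pad || blk$k > d[2] + pad)
    stop("simcspsppf: pool kernel larger than feature map")
  x1 <- wl_conv_fwd(ctx, blk$cv3,
                    wl_conv_fwd(ctx, blk$cv2,
                                wl_conv_fwd(ctx, blk$cv1, x, train), train), train)
  y0 <- wl_conv_fwd(ctx, blk$cv0, x, train)
  y1 <- op_maxpool(ctx, x1, blk$k)
  y2 <- op_maxpool(ctx, y1, blk$k)
  y2p <- op_maxpool(ctx, y2, blk$k)
  y3 <- wl_conv_fwd(ctx, blk$cv5,
                    wl_conv_fwd(ctx, blk$cv4,
                                op_concat_c(ctx, list(x1, y1, y2, y2p)), train), train)
  wl_conv_fwd(ctx, blk$out, op_concat_c(ctx, list(y0, y3)), train)
}

#' @rdname simcspsppf
#' @param block a layer from [simcspsppf()].
#' @param x input array (H, W, C) or (H, W, C, N).
#' @param train BN mode, see [conv_block_forward()].
#' @export
simcspsppf_forward <- function(block, x, train = FALSE) {
  wl_plain(wl_sppf_fwd(NULL, block, wl_batched(x), train), x)
}

# --- parameter walking -------------------------------------------------------

# Named, stable flat list of parameter nodes for a layer tree.
wl_layer_params <- function(blk, prefix = "") {
  out <- list()
  add <- function(name, p) {
    out[[paste0(prefix, name)]] <<- p
  }
  switch(blk$kind,
    conv = {
      add("w", blk$w)
      if (!is.null(blk$b)) add("b", blk$b)
      if (!is.null(blk$bn)) {
        add("bn.gamma", blk$bn$gamma)
        add("bn.beta", blk$bn$beta)
      }
    },
    bottleneck = {
      for (nm in c("cv1", "cv2", "cv3"))
        out <- c(out, wl_layer_params(blk[[nm]], paste0(prefix, nm, ".")))
    },
    csp = {
      out <- c(out, wl_layer_params(blk$entry, paste0(prefix, "entry.")))
      for (i in seq_along(blk$bnecks))
        out <- c(out, wl_layer_params(blk$bnecks[[i]], paste0(prefix, "m", i, ".")))
      out <- c(out, wl_layer_params(blk$exit, paste0(prefix, "exit.")))
    },
    sppf = {
      for (nm in c("cv1", "cv2", "cv3", "cv0", "cv4", "cv5", "out"))
        out <- c(out, wl_layer_params(blk[[nm]], paste0(prefix, nm, ".")))
    },
    stop("unknown layer kind: ", blk$kind)
  )
  out
}

# All conv sub-blocks of a layer tree, with path names (used by fusion,
# complexity accounting and checkpointing of running statistics).
wl_layer_convs <- function(blk, prefix = "") {
  switch(blk$kind,
    conv = setNames(list(blk), substr(prefix, 1, nchar(prefix) - 1)),
    bottleneck = c(wl_layer_convs(blk$cv1, paste0(prefix, "cv1.")),
                   wl_layer_convs(blk$cv2, paste0(prefix, "cv2.")),
                   wl_layer_convs(blk$cv3, paste0(prefix, "cv3."))),
    csp = c(wl_layer_convs(blk$entry, paste0(prefix, "entry.")),
            do.call(c, lapply(seq_along(blk$bnecks), function(i)
              wl_layer_convs(blk$bnecks[[i]], paste0(prefix, "m", i, ".")))),
            wl_layer_convs(blk$exit, paste0(prefix, "exit."))),
    sppf = do.call(c, lapply(c("cv1", "cv2", "cv3", "cv0", "cv4", "cv5", "out"),
                             function(nm) wl_layer_convs(blk[[nm]], paste0(prefix, nm, "."))))
  )
}
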
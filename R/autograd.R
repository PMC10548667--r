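# Minimal reverse-mode tape over (H, W, C, N) arrays.
#
# A "node" is an environment holding the forward value, an accumulated
# gradient, its parent nodes and a backward closure. Parameters are
# free-standing nodes that persist across forward passes; everything else is
# recorded on a tape (in creation = topological order) and released after the
# backward sweep. When no tape is supplied the ops run in plain inference
# mode and return bare arrays.

wl_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p$mom <- NULL
  p$is_param <- TRUE
  class(p) <- "wl_param"
  p
}

wl_tape <- function() {
  ctx <- new.env(parent = emptyenv())
  ctx$nodes <- vector("list", 256L)
  ctx$n <- 0L
  ctx
}

wl_node <- function(ctx, value, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  nd$is_param <- FALSE
  if (ctx$n == length(ctx$nodes)) ctx$nodes <- c(ctx$nodes, vector("list", length(ctx$nodes)))
  ctx$n <- ctx$n + 1L
  ctx$nodes[[ctx$n]] <- nd
  nd
}

wl_val <- function(x) if (is.environment(x)) x$value else x

wl_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

# Seed `outputs` with `grads` and sweep the tape backwards, accumulating into
# parameter nodes. Non-parameter gradients are dropped as soon as consumed.
wl_backward <- function(ctx, outputs, grads) {
  for (i in seq_along(outputs)) wl_accum(outputs[[i]], grads[[i]])
  for (i in rev(seq_len(ctx$n))) {
    nd <- ctx$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    pgrads <- nd$backfn(nd$grad)
    for (j in seq_along(nd$parents)) {
      # bare arrays (e.g. the network input) are not differentiated
      if (is.environment(nd$parents[[j]]) && !is.null(pgrads[[j]]))
        wl_accum(nd$parents[[j]], pgrads[[j]])
    }
    nd$grad <- NULL
  }
  ctx$n <- 0L
  ctx$nodes <- vector("list", 256L)
  invisible(NULL)
}

wl_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- primitive ops -----------------------------------------------------------

op_conv <- function(ctx, x, w, b, stride, pad) {
  xv <- wl_val(x)
  bv <- if (is.null(b)) NULL else b$value
  out <- .conv2d_fwd(xv, w$value, bv, as.integer(stride), as.integer(pad))
  if (is.null(ctx)) return(out)
  need_gx <- is.environment(x)  # bare input arrays take no gradient
  parents <- c(list(x, w), if (!is.null(b)) list(b))
  wl_node(ctx, out, parents, function(g) {
    bw <- .conv2d_bwd(xv, w$value, g, as.integer(stride), as.integer(pad),
                      need_gx, !is.null(b))
    c(list(bw$gx, bw$gw), if (!is.null(b)) list(bw$gb))
  })
}

op_silu <- function(ctx, x) {
  xv <- wl_val(x)
  out <- .silu_fwd(xv)
  if (is.null(ctx)) return(out)
  wl_node(ctx, out, list(x), function(g) list(.silu_bwd(xv, g)))
}

# Batch normalization (biased batch variance, epsilon inside the square root).
# In training mode batch statistics are used and running statistics updated in
# place on the layer environment; in inference mode running statistics apply.
op_bn <- function(ctx, x, bn, train) {
  xv <- wl_val(x)
  if (train) {
    st <- .bn_stats(xv)
    mu <- st$mean
    va <- st$var
    m <- bn$momentum
    bn$run_mean <- (1 - m) * bn$run_mean + m * mu
    bn$run_var <- (1 - m) * bn$run_var + m * va
  } else {
    mu <- bn$run_mean
    va <- bn$run_var
  }
  invstd <- 1 / sqrt(va + bn$eps)
  out <- .bn_apply(xv, bn$gamma$value, bn$beta$value, mu, invstd)
  if (is.null(ctx)) return(out)
  wl_node(ctx, out, list(x, bn$gamma, bn$beta), function(g) {
    bw <- .bn_bwd(xv, g, bn$gamma$value, mu, invstd, train)
    list(bw$gx, bw$dgamma, bw$dbeta)
  })
}

op_maxpool <- function(ctx, x, k) {
  xv <- wl_val(x)
  fw <- .maxpool_fwd(xv, as.integer(k))
  if (is.null(ctx)) return(fw$out)
  wl_node(ctx, fw$out, list(x), function(g) list(.maxpool_bwd(g, fw$idx)))
}

op_upsample2x <- function(ctx, x) {
  out <- .upsample2x_fwd(wl_val(x))
  if (is.null(ctx)) return(out)
  wl_node(ctx, out, list(x), function(g) list(.upsample2x_bwd(g)))
}

op_concat_c <- function(ctx, xs) {
  vals <- lapply(xs, wl_val)
  dims <- vapply(vals, function(v) dim(v)[3], numeric(1))
  out <- .concat_c(vals)
  if (is.null(ctx)) return(out)
  wl_node(ctx, out, xs, function(g) {
    res <- vector("list", length(xs))
    at <- 0L
    for (i in seq_along(xs)) {
      res[[i]] <- .slice_c(g, at, as.integer(dims[i]))
      at <- at + as.integer(dims[i])
    }
    res
  })
}

# contiguous channel slice [from + 1, from + len]
op_slice_c <- function(ctx, x, from, len) {
  xv <- wl_val(x)
  out <- .slice_c(xv, as.integer(from), as.integer(len))
  if (is.null(ctx)) return(out)
  C <- dim(xv)[3]
  wl_node(ctx, out, list(x), function(g)
    list(.slice_c_bwd(g, as.integer(from), as.integer(C))))
}

op_add <- function(ctx, a, b) {
  out <- wl_val(a) + wl_val(b)
  if (is.null(ctx)) return(out)
  wl_node(ctx, out, list(a, b), function(g) list(g, g))
}
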
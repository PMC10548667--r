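# Independent brute-force oracles used across the suite. These deliberately
# share no code with the implementation they check.

# Direct nested-loop cross-correlation with zero padding.
naive_conv <- function(x, w, stride = 1, pad = 0) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]; N <- dim(x)[4]
  k <- dim(w)[1]; Co <- dim(w)[4]
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  out <- array(0, c(Ho, Wo, Co, N))
  for (n in seq_len(N)) for (co in seq_len(Co)) for (oh in seq_len(Ho)) for (ow in seq_len(Wo)) {
    s <- 0
    for (dh in seq_len(k)) for (dw in seq_len(k)) for (ci in seq_len(C)) {
      h <- (oh - 1) * stride - pad + dh
      wp <- (ow - 1) * stride - pad + dw
      if (h >= 1 && h <= H && wp >= 1 && wp <= W)
        s <- s + x[h, wp, ci, n] * w[dh, dw, ci, co]
    }
    out[oh, ow, co, n] <- s
  }
  out
}

# IoU by rasterizing integer-coordinate boxes onto a unit grid.
raster_iou <- function(a, b) {
  lim <- range(c(a, b))
  cells_a <- 0; cells_b <- 0; cells_both <- 0
  for (x in seq(lim[1], lim[2] - 1)) for (y in seq(lim[1], lim[2] - 1)) {
    ina <- x >= a[1] && x < a[3] && y >= a[2] && y < a[4]
    inb <- x >= b[1] && x < b[3] && y >= b[2] && y < b[4]
    cells_a <- cells_a + ina
    cells_b <- cells_b + inb
    cells_both <- cells_both + (ina && inb)
  }
  u <- cells_a + cells_b - cells_both
  if (u == 0) 0 else cells_both / u
}

# Exhaustive greedy NMS: repeatedly take the highest-confidence remaining
# detection and delete everything overlapping it beyond the threshold.
nms_oracle <- function(dets, iou_thresh, conf_thresh, max_out = 300) {
  dets <- dets[dets$confidence >= conf_thresh, , drop = FALSE]
  kept <- dets[0, , drop = FALSE]
  while (nrow(dets) > 0 && nrow(kept) < max_out) {
    i <- order(-dets$confidence)[1]
    kept <- rbind(kept, dets[i, ])
    keep_box <- as.numeric(dets[i, c("x1", "y1", "x2", "y2")])
    drop <- logical(nrow(dets))
    for (j in seq_len(nrow(dets))) {
      bj <- as.numeric(dets[j, c("x1", "y1", "x2", "y2")])
      drop[j] <- j == i || pair_iou(keep_box, bj) > iou_thresh
    }
    dets <- dets[!drop, , drop = FALSE]
  }
  rownames(kept) <- NULL
  kept
}

pair_iou <- function(a, b) {
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  u <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (u <= 0) 0 else inter / u
}

# Greedy confidence-ordered matching, written independently.
match_oracle <- function(dets, gts, iou_thresh) {
  ngt <- NROW(gts)
  if (NROW(dets) == 0) return(c(tp = 0, fp = 0, fn = ngt))
  dets <- dets[order(-dets$confidence), , drop = FALSE]
  used <- rep(FALSE, ngt)
  tp <- 0
  for (i in seq_len(nrow(dets))) {
    di <- as.numeric(dets[i, c("x1", "y1", "x2", "y2")])
    best <- 0; bj <- 0
    for (j in seq_len(ngt)) {
      if (used[j]) next
      v <- pair_iou(di, as.numeric(gts[j, ]))
      if (v > best) { best <- v; bj <- j }
    }
    if (bj > 0 && best >= iou_thresh) { used[bj] <- TRUE; tp <- tp + 1 }
  }
  c(tp = tp, fp = nrow(dets) - tp, fn = ngt - tp)
}

rand_boxes <- function(n, lim = 24, min_size = 1) {
  m <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    x1 <- sample(0:(lim - min_size), 1); y1 <- sample(0:(lim - min_size), 1)
    m[i, ] <- c(x1, y1, x1 + sample(min_size:(lim - x1), 1),
                y1 + sample(min_size:(lim - y1), 1))
  }
  m
}

tiny_net_cfg <- function() network_config(widths = c(8, 16, 32), stem_mid = 8)
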
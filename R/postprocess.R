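# Decode raw head outputs into scored boxes and suppress duplicates.

# Bounded decode transform: center offset 2*sigmoid(t) - 0.5 relative to the
# cell, size anchor * (2*sigmoid(t))^2. encode_box is its exact inverse on
# valid boxes (offsets in (-0.5, 1.5), sizes in (0, 4*anchor)).

#' Decode / encode a single box against its anchor
#'
#' `decode_box` maps a raw prediction vector `t = (tx, ty, tw, th)` at grid
#' cell (`row`, `col`) of a stride-`stride` head with prior size `anchor_wh`
#' to a center-form box; `encode_box` is the exact inverse.
#'
#' @param t raw prediction 4-vector.
#' @param box center-form box `(cx, cy, w, h)` in input pixels.
#' @param row,col 0-based cell indices.
#' @param anchor_wh anchor width/height in pixels.
#' @param stride head stride.
#' @return `decode_box`: `(cx, cy, w, h)`; `encode_box`: `(tx, ty, tw, th)`.
#' @export
decode_box <- function(t, row, col, anchor_wh, stride) {
  s <- sigmoid(t)
  c((2 * s[1] - 0.5 + col) * stride,
    (2 * s[2] - 0.5 + row) * stride,
    anchor_wh[1] * (2 * s[3])^2,
    anchor_wh[2] * (2 * s[4])^2)
}

#' @rdname decode_box
#' @export
encode_box <- function(box, row, col, anchor_wh, stride) {
  inv_sig <- function(p) log(p / (1 - p))
  ox <- (box[1] / stride - col + 0.5) / 2
  oy <- (box[2] / stride - row + 0.5) / 2
  sw <- sqrt(box[3] / anchor_wh[1]) / 2
  sh <- sqrt(box[4] / anchor_wh[2]) / 2
  if (any(c(ox, oy, sw, sh) <= 0) || any(c(ox, oy, sw, sh) >= 1))
    stop("encode_box: box not representable from this cell/anchor")
  c(inv_sig(ox), inv_sig(oy), inv_sig(sw), inv_sig(sh))
}

#' Decode raw head outputs into detections
#'
#' Turns the per-scale raw output grids of [network_predict()] into one
#' detection table per image: every cell/anchor yields a corner-form box
#' (clipped to the padded image bounds), an objectness score, the best class
#' score, and `confidence = objectness * class_score`.
#'
#' @param heads list of per-scale raw output arrays.
#' @param cfg the [network_config()] the network was built from.
#' @param input_hw network input height/width (used for clipping).
#' @return list (one element per image) of data frames with columns
#'   `x1, y1, x2, y2, objectness, class_score, confidence, class`.
#' @export
decode_predictions <- function(heads, cfg, input_hw) {
  if (length(input_hw) == 1) input_hw <- rep(input_hw, 2)
  A <- cfg$anchors_per_scale
  nc <- cfg$num_classes
  stepc <- 5 + nc
  N <- dim(heads[[1]])[4]
  out <- vector("list", N)
  for (n in seq_len(N)) {
    per_scale <- vector("list", length(heads))
    for (s in seq_along(heads)) {
      h <- heads[[s]]
      if (dim(h)[3] != A * stepc)
        stop("decode_predictions: head has ", dim(h)[3],
             " channels, expected ", A * stepc)
      hs <- dim(h)[1]; ws <- dim(h)[2]
      st <- cfg$strides[s]
      rows <- vector("list", A)
      cell_row <- matrix(rep(seq_len(hs) - 1, ws), hs, ws)
      cell_col <- matrix(rep(seq_len(ws) - 1, each = hs), hs, ws)
      for (a in seq_len(A)) {
        base <- (a - 1) * stepc
        sx <- sigmoid(h[, , base + 1, n]); sy <- sigmoid(h[, , base + 2, n])
        sw <- sigmoid(h[, , base + 3, n]); sh <- sigmoid(h[, , base + 4, n])
        obj <- sigmoid(h[, , base + 5, n])
        if (nc == 1) {
          cls_best <- matrix(1L, hs, ws)
          cls_score <- sigmoid(h[, , base + 6, n])
        } else {
          clsm <- sigmoid(array(h[, , base + 5 + seq_len(nc), n], c(hs, ws, nc)))
          cls_best <- apply(clsm, c(1, 2), which.max)
          cls_score <- apply(clsm, c(1, 2), max)
        }
        cx <- (2 * sx - 0.5 + cell_col) * st
        cy <- (2 * sy - 0.5 + cell_row) * st
        bw <- cfg$anchor_sizes[[s]][a, 1] * (2 * sw)^2
        bh <- cfg$anchor_sizes[[s]][a, 2] * (2 * sh)^2
        rows[[a]] <- data.frame(
          x1 = pmin(pmax(as.vector(cx - bw / 2), 0), input_hw[2]),
          y1 = pmin(pmax(as.vector(cy - bh / 2), 0), input_hw[1]),
          x2 = pmin(pmax(as.vector(cx + bw / 2), 0), input_hw[2]),
          y2 = pmin(pmax(as.vector(cy + bh / 2), 0), input_hw[1]),
          objectness = as.vector(obj),
          class_score = as.vector(cls_score),
          class = as.vector(cls_best) - 1L)
      }
      per_scale[[s]] <- do.call(rbind, rows)
    }
    d <- do.call(rbind, per_scale)
    d$confidence <- d$objectness * d$class_score
    out[[n]] <- d
  }
  out
}

#' Non-maximum suppression
#'
#' Greedy class-agnostic suppression: detections below `conf_thresh` are
#' dropped, then the highest-confidence detection is kept and every remaining
#' detection with IoU above `iou_thresh` against a kept box is suppressed.
#' The result is sorted by decreasing confidence and truncated to `max_out`.
#' Idempotent: running NMS on its own output changes nothing.
#'
#' @param dets data frame with `x1, y1, x2, y2, confidence` columns.
#' @param iou_thresh suppression IoU threshold.
#' @param conf_thresh confidence floor.
#' @param max_out maximum detections returned.
#' @return filtered data frame.
#' @export
nms <- function(dets, iou_thresh = 0.45, conf_thresh = 0.25, max_out = 300) {
  stopifnot(iou_thresh >= 0, iou_thresh <= 1, conf_thresh >= 0, conf_thresh <= 1)
  if (NROW(dets) == 0) return(dets)
  dets <- dets[dets$confidence >= conf_thresh, , drop = FALSE]
  if (nrow(dets) == 0) return(dets)
  dets <- dets[order(-dets$confidence), , drop = FALSE]
  boxes <- as.matrix(dets[, c("x1", "y1", "x2", "y2")])
  keep <- .nms_keep(boxes, iou_thresh, as.integer(max_out))
  out <- dets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run detection end to end on images
#'
#' Forward pass, decode and NMS for a list of images already conformed to the
#' network input size.
#'
#' @param net a `wl_network`.
#' @param images list of (H, W, 3) arrays (or one array).
#' @param conf_thresh,iou_thresh,max_out see [nms()].
#' @param batch_size images per forward pass.
#' @return list of detection data frames.
#' @export
detect_images <- function(net, images, conf_thresh = 0.25, iou_thresh = 0.45,
                          max_out = 300, batch_size = 8) {
  if (is.array(images)) images <- list(images)
  out <- vector("list", length(images))
  i <- 1
  while (i <= length(images)) {
    idx <- i:min(i + batch_size - 1, length(images))
    d1 <- dim(images[[idx[1]]])
    x <- array(0, c(d1[1], d1[2], 3, length(idx)))
    for (k in seq_along(idx)) x[, , , k] <- images[[idx[k]]]
    heads <- forward_network(net, x, train = FALSE)
    dets <- decode_predictions(heads, net$cfg, d1[1:2])
    for (k in seq_along(idx))
      out[[idx[k]]] <- nms(dets[[k]], iou_thresh, conf_thresh, max_out)
    i <- i + length(idx)
  }
  out
}
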
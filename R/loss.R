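# Composite training loss: CIoU localization on positive anchors, attenuated
# binary cross-entropy for objectness (all anchors) and classification
# (positive anchors), weighted 0.05 / 0.7 / 0.3.

#' Loss weights
#'
#' The weighting triple of the total loss
#' `L = loc_weight * L_loc + obj_weight * L_obj + cls_weight * L_cls`.
#' Defaults are the published 0.05 / 0.7 / 0.3.
#'
#' @param loc_weight,obj_weight,cls_weight nonnegative scalars.
#' @export
loss_weights <- function(loc_weight = 0.05, obj_weight = 0.7, cls_weight = 0.3) {
  stopifnot(loc_weight >= 0, obj_weight >= 0, cls_weight >= 0)
  list(loc = loc_weight, obj = obj_weight, cls = cls_weight)
}

#' Binary cross-entropy on logits
#'
#' Mean of `-[y * log(p) + (1 - y) * log(1 - p)]` with `p = sigmoid(logits)`,
#' computed in the numerically stable logit form (no overflow for large
#' magnitudes).
#'
#' @param labels vector of 0/1 labels.
#' @param logits real-valued predictions, same length.
#' @return mean loss (scalar).
#' @export
bce_with_logits <- function(labels, logits) {
  stopifnot(length(labels) == length(logits), all(labels %in% c(0, 1)))
  mean(pmax(logits, 0) - logits * labels + log1p(exp(-abs(logits))))
}

#' Missing-label attenuation factor
#'
#' The decreasing weight `alpha(x) = 1 - exp((x - 1) / (alpha_h + eps))`
#' applied to per-sample cross-entropy terms, where `x` is the difference
#' between predicted probability and label. At `x = 1` (a confident positive
#' prediction against a 0 label — the signature of an unannotated object) the
#' factor is 0, removing that sample's error; as `x` decreases the factor
#' rises towards 1 and the sample keeps its full weight.
#'
#' @param x prediction-minus-label difference, in `[-1, 1]` for
#'   probabilities.
#' @param alpha_h attenuation hyperparameter (scale of the decay).
#' @param eps small positive guard added to `alpha_h`.
#' @return attenuation factor(s).
#' @export
attenuation <- function(x, alpha_h = 0.25, eps = 1e-8) {
  stopifnot(alpha_h + eps > 0)
  1 - exp((x - 1) / (alpha_h + eps))
}

#' Attenuated binary cross-entropy
#'
#' Mean over samples of `attenuation(p_i - y_i)` times the per-sample binary
#' cross-entropy, reducing the contribution of confident disagreements that
#' plausibly stem from missing labels.
#'
#' @param probs predicted probabilities in (0, 1).
#' @param labels 0/1 labels.
#' @param alpha_h,eps attenuation hyperparameters, see [attenuation()].
#' @return mean attenuated loss (scalar).
#' @export
jx_loss <- function(probs, labels, alpha_h = 0.25, eps = 1e-8) {
  stopifnot(length(probs) == length(labels))
  p <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  bce <- -(labels * log(p) + (1 - labels) * log(1 - p))
  mean(attenuation(probs - labels, alpha_h, eps) * bce)
}

#' Total detection loss
#'
#' Weighted sum of the localization, objectness and classification
#' components.
#'
#' @param loc,obj,cls nonnegative component losses.
#' @param w a [loss_weights()].
#' @return list with `total` and the per-component `breakdown`.
#' @export
total_loss <- function(loc, obj, cls, w = loss_weights()) {
  if (any(c(loc, obj, cls) < 0)) stop("total_loss: negative loss component")
  list(total = w$loc * loc + w$obj * obj + w$cls * cls,
       breakdown = c(loc = loc, obj = obj, cls = cls))
}

#' Anchor grid for an input size
#'
#' Enumerates every anchor box of the network: for each scale (stride), each
#' cell and each anchor shape, the prior box centered on the cell center.
#' Rows are ordered by (scale, cell row, cell col, anchor index) — the
#' documented deterministic tie-break order for assignment.
#'
#' @param cfg a [network_config()].
#' @param input_hw network input height/width.
#' @return data frame with columns `scale`, `stride`, `row`, `col` (0-based
#'   cell indices), `anchor`, `cx`, `cy`, `w`, `h`, `x1`, `y1`, `x2`, `y2`.
#' @export
anchor_grid <- function(cfg, input_hw) {
  if (length(input_hw) == 1) input_hw <- rep(input_hw, 2)
  out <- vector("list", length(cfg$strides))
  for (s in seq_along(cfg$strides)) {
    st <- cfg$strides[s]
    hs <- input_hw[1] %/% st; ws <- input_hw[2] %/% st
    A <- cfg$anchors_per_scale
    g <- expand.grid(anchor = seq_len(A), col = seq_len(ws) - 1, row = seq_len(hs) - 1)
    g <- g[, c("row", "col", "anchor")]
    g$scale <- s
    g$stride <- st
    g$cx <- (g$col + 0.5) * st
    g$cy <- (g$row + 0.5) * st
    g$w <- cfg$anchor_sizes[[s]][g$anchor, 1]
    g$h <- cfg$anchor_sizes[[s]][g$anchor, 2]
    out[[s]] <- g
  }
  g <- do.call(rbind, out)
  g <- g[order(g$scale, g$row, g$col, g$anchor), ]
  rownames(g) <- NULL
  g$x1 <- g$cx - g$w / 2; g$y1 <- g$cy - g$h / 2
  g$x2 <- g$cx + g$w / 2; g$y2 <- g$cy + g$h / 2
  g[, c("scale", "stride", "row", "col", "anchor",
        "cx", "cy", "w", "h", "x1", "y1", "x2", "y2")]
}

#' Assign ground-truth boxes to anchors
#'
#' For each ground-truth box, the single anchor (over all scales, cells and
#' shapes) with maximal IoU against the box becomes positive: its objectness
#' label is 1 and it regresses that box. All other anchors are negative. On
#' exact IoU ties the anchor earliest in (scale, row, col, anchor) order
#' wins, making the assignment deterministic.
#'
#' @param gt ground-truth boxes, corner form (n x 4 matrix; possibly 0 rows).
#' @param anchors an [anchor_grid()].
#' @return list with `positive` (data frame: `gt`, `scale`, `row`, `col`,
#'   `anchor`, `iou`, `class`) and `objectness` (0/1 vector over the anchor
#'   grid rows).
#' @export
assign_targets <- function(gt, anchors) {
  if (nrow(anchors) == 0) stop("assign_targets: empty anchor set")
  obj <- numeric(nrow(anchors))
  if (is.null(gt) || NROW(gt) == 0)
    return(list(positive = data.frame(), objectness = obj))
  gt <- wl_as_boxes(gt)
  ab <- as.matrix(anchors[, c("x1", "y1", "x2", "y2")])
  im <- iou_matrix(gt, ab)           # n_gt x n_anchor
  best <- apply(im, 1, which.max)    # first max = documented tie-break
  pos <- data.frame(gt = seq_len(nrow(gt)),
                    scale = anchors$scale[best],
                    row = anchors$row[best],
                    col = anchors$col[best],
                    anchor = anchors$anchor[best],
                    iou = im[cbind(seq_len(nrow(gt)), best)],
                    class = 0L)
  obj[best] <- 1
  list(positive = pos, objectness = obj)
}

# --- training loss on raw head outputs --------------------------------------

# Compute the composite loss and its gradient w.r.t. the raw head outputs.
# heads: list of per-scale arrays (Hs, Ws, A*(5+nc), N); gts: list of N
# corner-form gt matrices in network-input coordinates. The attenuation
# factor is treated as a constant weight during differentiation.
wl_detection_loss <- function(heads, gts, cfg, input_hw, w = loss_weights(),
                              alpha_h = 0.25, att_eps = 1e-8, need_grad = TRUE,
                              assigns = NULL) {
  A <- cfg$anchors_per_scale
  nc <- cfg$num_classes
  stepc <- 5 + nc
  N <- dim(heads[[1]])[4]
  grads <- if (need_grad) lapply(heads, function(h) array(0, dim(h))) else NULL

  # objectness labels over every scale/cell/anchor/image
  obj_loss_sum <- 0; obj_n <- 0
  loc_loss_sum <- 0; cls_loss_sum <- 0; npos <- 0

  # per-image assignment (anchors are identical across the batch); callers
  # in the training loop pass cached assignments since they depend only on
  # the ground truth and the anchor grid
  if (is.null(assigns)) {
    anchors <- anchor_grid(cfg, input_hw)
    assigns <- lapply(seq_len(N), function(n) assign_targets(gts[[n]], anchors))
  }

  for (s in seq_along(heads)) {
    h <- heads[[s]]
    hs <- dim(h)[1]; ws <- dim(h)[2]
    st <- cfg$strides[s]
    obj_ch <- (seq_len(A) - 1) * stepc + 5
    t_obj <- h[, , obj_ch, , drop = FALSE]
    y_obj <- array(0, dim(t_obj))
    for (n in seq_len(N)) {
      pos <- assigns[[n]]$positive
      if (NROW(pos) == 0) next
      ps <- pos[pos$scale == s, , drop = FALSE]
      if (nrow(ps) > 0)
        y_obj[cbind(ps$row + 1, ps$col + 1, ps$anchor, n)] <- 1
    }
    p_obj <- sigmoid(t_obj)
    w_att <- attenuation(p_obj - y_obj, alpha_h, att_eps)
    bce <- pmax(t_obj, 0) - t_obj * y_obj + log1p(exp(-abs(t_obj)))
    obj_loss_sum <- obj_loss_sum + sum(w_att * bce)
    obj_n <- obj_n + length(t_obj)
    if (need_grad) grads[[s]][, , obj_ch, ] <- w_att * (p_obj - y_obj)

    for (n in seq_len(N)) {
      pos <- assigns[[n]]$positive
      if (NROW(pos) == 0) next
      ps <- pos[pos$scale == s, , drop = FALSE]
      if (nrow(ps) == 0) next
      base <- (ps$anchor - 1) * stepc
      gtb <- corner_to_center(gts[[n]][ps$gt, , drop = FALSE])
      aw <- cfg$anchor_sizes[[s]][ps$anchor, 1]
      ah <- cfg$anchor_sizes[[s]][ps$anchor, 2]
      idx <- function(ch) cbind(ps$row + 1, ps$col + 1, ch, n)
      tx <- h[idx(base + 1)]; ty <- h[idx(base + 2)]
      tw <- h[idx(base + 3)]; th <- h[idx(base + 4)]
      sx <- sigmoid(tx); sy <- sigmoid(ty); sw <- sigmoid(tw); sh <- sigmoid(th)
      pred <- cbind(cx = (2 * sx - 0.5 + ps$col) * st,
                    cy = (2 * sy - 0.5 + ps$row) * st,
                    w = aw * (2 * sw)^2,
                    h = ah * (2 * sh)^2)
      ci <- wl_ciou(pred, gtb, grad = need_grad)
      loc_loss_sum <- loc_loss_sum + sum(ci$loss)

      # classification: single/multi-class, label = gt class (one-hot)
      cls_ch <- base + 5 + 1 + ps$class  # class 0 -> first class channel
      tc <- h[idx(cls_ch)]
      pc <- sigmoid(tc)
      wc <- attenuation(pc - 1, alpha_h, att_eps)
      bce_c <- pmax(tc, 0) - tc + log1p(exp(-abs(tc)))
      cls_loss_sum <- cls_loss_sum + sum(wc * bce_c)
      npos <- npos + nrow(ps)

      if (need_grad) {
        gb <- ci$grad
        dsig <- function(sg) sg * (1 - sg)
        grads[[s]][idx(base + 1)] <- grads[[s]][idx(base + 1)] +
          gb[, 1] * 2 * dsig(sx) * st * w$loc
        grads[[s]][idx(base + 2)] <- grads[[s]][idx(base + 2)] +
          gb[, 2] * 2 * dsig(sy) * st * w$loc
        grads[[s]][idx(base + 3)] <- grads[[s]][idx(base + 3)] +
          gb[, 3] * aw * 8 * sw * dsig(sw) * w$loc
        grads[[s]][idx(base + 4)] <- grads[[s]][idx(base + 4)] +
          gb[, 4] * ah * 8 * sh * dsig(sh) * w$loc
        grads[[s]][idx(cls_ch)] <- grads[[s]][idx(cls_ch)] +
          wc * (pc - 1) * w$cls
      }
    }
  }

  # Normalization: the objectness loss runs over every anchor but is
  # normalized by the positive count (dense-detector convention), so the
  # foreground signal does not vanish among the ~10^4 negatives per image;
  # the localization loss is summed over positives and normalized by the
  # batch size (the historical single-stage convention), so box supervision
  # stays commensurate with the objectness signal under the small published
  # localization weight. Classification is averaged over positives.
  obj_norm <- if (npos > 0) npos else max(obj_n, 1)
  obj <- obj_loss_sum / obj_norm
  loc <- if (npos > 0) loc_loss_sum / N else 0
  cls <- if (npos > 0) cls_loss_sum / npos else 0
  tot <- total_loss(max(loc, 0), obj, cls, w)
  if (need_grad) {
    for (s in seq_along(grads)) {
      obj_ch <- (seq_len(A) - 1) * stepc + 5
      box_ch <- as.vector(outer(1:4, (seq_len(A) - 1) * stepc, "+"))
      g <- grads[[s]]
      gobj <- g[, , obj_ch, , drop = FALSE] * (w$obj / obj_norm)
      gbox <- g[, , box_ch, , drop = FALSE] / N
      g <- g / max(npos, 1)
      g[, , obj_ch, ] <- gobj
      g[, , box_ch, ] <- gbox
      grads[[s]] <- g
    }
  }
  list(total = tot$total, breakdown = tot$breakdown, npos = npos, grads = grads)
}
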
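# Axis-aligned box geometry. Boxes are corner-form numeric vectors
# (x1, y1, x2, y2) in continuous pixel coordinates, origin top-left, or
# matrices with one box per row; area = (x2 - x1) * (y2 - y1).

wl_as_boxes <- function(b) {
  if (is.null(dim(b))) b <- matrix(b, ncol = 4, byrow = TRUE)
  if (ncol(b) != 4) stop("boxes must have 4 columns (x1, y1, x2, y2)")
  if (any(b[, 3] < b[, 1] - 1e-9) || any(b[, 4] < b[, 2] - 1e-9))
    stop("invalid box: x2 < x1 or y2 < y1")
  b
}

box_area <- function(b) {
  b <- wl_as_boxes(b)
  (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
}

corner_to_center <- function(b) {
  b <- wl_as_boxes(b)
  cbind(cx = (b[, 1] + b[, 3]) / 2, cy = (b[, 2] + b[, 4]) / 2,
        w = b[, 3] - b[, 1], h = b[, 4] - b[, 2])
}

center_to_corner <- function(b) {
  if (is.null(dim(b))) b <- matrix(b, ncol = 4, byrow = TRUE)
  cbind(x1 = b[, 1] - b[, 3] / 2, y1 = b[, 2] - b[, 4] / 2,
        x2 = b[, 1] + b[, 3] / 2, y2 = b[, 2] + b[, 4] / 2)
}

#' Intersection over union of axis-aligned boxes
#'
#' Overlap area divided by union area, in `[0, 1]`; symmetric, and 1 exactly
#' for identical non-degenerate boxes. Pairs in which both boxes have zero
#' area return 0 rather than 0/0.
#'
#' @param a,b boxes as length-4 vectors `(x1, y1, x2, y2)` or n x 4 matrices
#'   (paired row by row; a single box recycles against a matrix).
#' @return numeric vector of IoU values.
#' @export
iou <- function(a, b) {
  a <- wl_as_boxes(a); b <- wl_as_boxes(b)
  if (nrow(a) == 1 && nrow(b) > 1) a <- a[rep(1, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1 && nrow(a) > 1) b <- b[rep(1, nrow(a)), , drop = FALSE]
  iw <- pmax(0, pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]))
  ih <- pmax(0, pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]))
  inter <- iw * ih
  u <- box_area(a) + box_area(b) - inter
  ifelse(u > 0, inter / u, 0)
}

# IoU matrix between every row of A and every row of B (nA x nB).
iou_matrix <- function(A, B) {
  A <- wl_as_boxes(A); B <- wl_as_boxes(B)
  iw <- pmax(0, outer(A[, 3], B[, 3], pmin) - outer(A[, 1], B[, 1], pmax))
  ih <- pmax(0, outer(A[, 4], B[, 4], pmin) - outer(A[, 2], B[, 2], pmax))
  inter <- iw * ih
  u <- outer(box_area(A), box_area(B), "+") - inter
  out <- inter / u
  out[u <= 0] <- 0
  out
}

#' Complete-IoU localization loss
#'
#' Box-regression loss combining overlap area, center distance and aspect
#' ratio: `1 - (IoU - rho^2 / c^2 - alpha * v)`, where `rho` is the distance
#' between box centers, `c` the diagonal of the minimum enclosing rectangle,
#' `v = (4 / pi^2) * (atan(w_gt / h_gt) - atan(w / h))^2` the aspect
#' similarity term, and `alpha = v / ((1 - IoU) + v)` its weight. The loss is
#' 0 for identical boxes, grows as the boxes diverge (exceeding 1 for
#' far-separated boxes, where the center-distance penalty dominates), and is
#' invariant under joint translation and joint uniform scaling.
#'
#' @param pred,gt corner-form boxes (length-4 vectors or row-paired
#'   matrices); `gt` must have positive width and height.
#' @return numeric vector of loss values.
#' @export
localization_loss <- function(pred, gt) {
  pred <- wl_as_boxes(pred); gt <- wl_as_boxes(gt)
  if (nrow(pred) == 1 && nrow(gt) > 1) pred <- pred[rep(1, nrow(gt)), , drop = FALSE]
  if (nrow(gt) == 1 && nrow(pred) > 1) gt <- gt[rep(1, nrow(pred)), , drop = FALSE]
  if (any(gt[, 3] - gt[, 1] <= 0) || any(gt[, 4] - gt[, 2] <= 0))
    stop("localization_loss: ground-truth box with zero width or height")
  unname(wl_ciou(corner_to_center(pred), corner_to_center(gt))$loss)
}

# CIoU loss and its gradient w.r.t. the predicted box in center form
# (cx, cy, w, h). `alpha` is treated as a constant during differentiation.
wl_ciou <- function(p, g, grad = FALSE) {
  eps <- 1e-9
  px1 <- p[, 1] - p[, 3] / 2; px2 <- p[, 1] + p[, 3] / 2
  py1 <- p[, 2] - p[, 4] / 2; py2 <- p[, 2] + p[, 4] / 2
  gx1 <- g[, 1] - g[, 3] / 2; gx2 <- g[, 1] + g[, 3] / 2
  gy1 <- g[, 2] - g[, 4] / 2; gy2 <- g[, 2] + g[, 4] / 2
  iw <- pmin(px2, gx2) - pmax(px1, gx1)
  ih <- pmin(py2, gy2) - pmax(py1, gy1)
  pos <- iw > 0 & ih > 0
  iwc <- pmax(iw, 0); ihc <- pmax(ih, 0)
  inter <- iwc * ihc
  u <- p[, 3] * p[, 4] + g[, 3] * g[, 4] - inter
  iou_v <- inter / pmax(u, eps)
  rho2 <- (p[, 1] - g[, 1])^2 + (p[, 2] - g[, 2])^2
  cw <- pmax(px2, gx2) - pmin(px1, gx1)
  ch <- pmax(py2, gy2) - pmin(py1, gy1)
  c2 <- cw^2 + ch^2 + eps
  dtheta <- atan(g[, 3] / pmax(g[, 4], eps)) - atan(p[, 3] / pmax(p[, 4], eps))
  v <- (4 / pi^2) * dtheta^2
  alpha <- v / ((1 - iou_v) + v + eps)
  loss <- 1 - iou_v + rho2 / c2 + alpha * v
  if (!grad) return(list(loss = loss, iou = iou_v))

  # d(inter)/d(cx, w): indicator masks for which box edge is inner/outer
  m_x2 <- as.numeric(px2 < gx2); m_x1 <- as.numeric(px1 > gx1)
  m_y2 <- as.numeric(py2 < gy2); m_y1 <- as.numeric(py1 > gy1)
  dI_dcx <- ifelse(pos, ihc * (m_x2 - m_x1), 0)
  dI_dw <- ifelse(pos, ihc * (m_x2 + m_x1) / 2, 0)
  dI_dcy <- ifelse(pos, iwc * (m_y2 - m_y1), 0)
  dI_dh <- ifelse(pos, iwc * (m_y2 + m_y1) / 2, 0)
  du_dw <- p[, 4] - dI_dw
  du_dh <- p[, 3] - dI_dh
  usq <- pmax(u, eps)^2
  diou_dcx <- (dI_dcx * u + inter * dI_dcx) / usq
  diou_dcy <- (dI_dcy * u + inter * dI_dcy) / usq
  diou_dw <- (dI_dw * u - inter * du_dw) / usq
  diou_dh <- (dI_dh * u - inter * du_dh) / usq

  # enclosing-box diagonal
  dcw_dcx <- as.numeric(px2 > gx2) - as.numeric(px1 < gx1)
  dcw_dw <- (as.numeric(px2 > gx2) + as.numeric(px1 < gx1)) / 2
  dch_dcy <- as.numeric(py2 > gy2) - as.numeric(py1 < gy1)
  dch_dh <- (as.numeric(py2 > gy2) + as.numeric(py1 < gy1)) / 2
  drho_dcx <- 2 * (p[, 1] - g[, 1])
  drho_dcy <- 2 * (p[, 2] - g[, 2])
  dpen_dcx <- (drho_dcx * c2 - rho2 * 2 * cw * dcw_dcx) / c2^2
  dpen_dcy <- (drho_dcy * c2 - rho2 * 2 * ch * dch_dcy) / c2^2
  dpen_dw <- (-rho2 * 2 * cw * dcw_dw) / c2^2
  dpen_dh <- (-rho2 * 2 * ch * dch_dh) / c2^2

  # d(dtheta)/dw = -h/(w^2+h^2); dv/dw = 2*(4/pi^2)*dtheta*d(dtheta)/dw
  wh2 <- p[, 3]^2 + p[, 4]^2 + eps
  dv_dw <- -(8 / pi^2) * dtheta * p[, 4] / wh2
  dv_dh <- (8 / pi^2) * dtheta * p[, 3] / wh2

  grad <- cbind(
    cx = -diou_dcx + dpen_dcx,
    cy = -diou_dcy + dpen_dcy,
    w = -diou_dw + dpen_dw + alpha * dv_dw,
    h = -diou_dh + dpen_dh + alpha * dv_dh)
  list(loss = loss, iou = iou_v, grad = grad)
}
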
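# Detection metrics (precision, recall, AP, F1/AFC) and counting metrics
# (MAE, RMSE, MAPE, R^2).

#' Match detections to ground truth
#'
#' Greedy matching in decreasing confidence order: each detection is a true
#' positive if its best-IoU unmatched ground-truth box reaches `iou_thresh`,
#' otherwise a false positive; each ground truth matches at most once and
#' unmatched ground truths are false negatives. Equal-IoU ties go to the
#' lower ground-truth index.
#'
#' @param dets detection data frame (`x1, y1, x2, y2, confidence`).
#' @param gts ground-truth corner boxes (matrix, possibly 0 rows).
#' @param iou_thresh matching threshold.
#' @return named vector `c(tp, fp, fn)`.
#' @export
match_detections <- function(dets, gts, iou_thresh = 0.5) {
  ngt <- NROW(gts)
  if (NROW(dets) == 0) return(c(tp = 0, fp = 0, fn = ngt))
  dets <- dets[order(-dets$confidence), , drop = FALSE]
  if (ngt == 0) return(c(tp = 0, fp = nrow(dets), fn = 0))
  gts <- wl_as_boxes(gts)
  im <- iou_matrix(as.matrix(dets[, c("x1", "y1", "x2", "y2")]), gts)
  matched <- logical(ngt)
  tp <- 0L
  for (i in seq_len(nrow(dets))) {
    ious <- im[i, ]
    ious[matched] <- -1
    j <- which.max(ious)
    if (ious[j] >= iou_thresh) {
      matched[j] <- TRUE
      tp <- tp + 1L
    }
  }
  c(tp = tp, fp = nrow(dets) - tp, fn = ngt - tp)
}

#' Precision and recall from match counts
#'
#' `precision = TP / (TP + FP)` and `recall = TP / (TP + FN)`, with 0 on
#' empty denominators.
#'
#' @param tp,fp,fn nonnegative counts.
#' @return named vector `c(precision, recall)`.
#' @export
precision_recall <- function(tp, fp, fn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  c(precision = if (tp + fp > 0) tp / (tp + fp) else 0,
    recall = if (tp + fn > 0) tp / (tp + fn) else 0)
}

#' F1 score
#'
#' Harmonic mean of precision and recall, `2PR / (P + R)`, 0 when both are 0.
#'
#' @param precision,recall values in `[0, 1]`.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
}

#' Average precision
#'
#' Area under the precision-recall curve at a fixed matching IoU, swept over
#' detection confidence: detections from all images are ranked by confidence,
#' matched greedily within their image, the precision envelope is taken and
#' integrated with the all-points interpolation rule.
#'
#' @param dets_list list of per-image detection data frames.
#' @param gts_list list of per-image ground-truth box matrices.
#' @param iou_thresh matching IoU.
#' @return list with `ap` and the `pr_curve` data frame (recall, precision).
#' @export
average_precision <- function(dets_list, gts_list, iou_thresh = 0.5) {
  ngt <- sum(vapply(gts_list, NROW, numeric(1)))
  if (ngt == 0) stop("average_precision: no ground-truth boxes")
  recs <- list()
  for (i in seq_along(dets_list)) {
    d <- dets_list[[i]]
    if (NROW(d) == 0) next
    recs[[length(recs) + 1]] <- data.frame(img = i, conf = d$confidence,
                                           x1 = d$x1, y1 = d$y1, x2 = d$x2, y2 = d$y2)
  }
  if (length(recs) == 0)
    return(list(ap = 0, pr_curve = data.frame(recall = 0, precision = 0)))
  all <- do.call(rbind, recs)
  all <- all[order(-all$conf), , drop = FALSE]
  # one IoU matrix per image, then a greedy confidence-ordered walk
  imat <- lapply(seq_along(gts_list), function(i) {
    d <- all[all$img == i, c("x1", "y1", "x2", "y2"), drop = FALSE]
    if (nrow(d) == 0 || NROW(gts_list[[i]]) == 0) return(NULL)
    iou_matrix(as.matrix(d), gts_list[[i]])
  })
  matched <- lapply(gts_list, function(g) logical(NROW(g)))
  seen <- integer(length(gts_list))  # per-image row cursor into imat
  is_tp <- logical(nrow(all))
  for (k in seq_len(nrow(all))) {
    i <- all$img[k]
    if (is.null(imat[[i]])) next
    seen[i] <- seen[i] + 1L
    ious <- imat[[i]][seen[i], ]
    ious[matched[[i]]] <- -1
    j <- which.max(ious)
    if (ious[j] >= iou_thresh) {
      matched[[i]][j] <- TRUE
      is_tp[k] <- TRUE
    }
  }
  tp <- cumsum(is_tp)
  fp <- cumsum(!is_tp)
  recall <- tp / ngt
  precision <- tp / (tp + fp)
  # precision envelope (monotone non-increasing from the right)
  penv <- rev(cummax(rev(precision)))
  r <- c(0, recall)
  ap <- sum((r[-1] - r[-length(r)]) * penv)
  list(ap = ap, pr_curve = data.frame(recall = recall, precision = penv))
}

#' Counting metrics
#'
#' Per-image count agreement between ground truth `G` and predictions `P`:
#' mean absolute error, root mean square error, mean absolute percentage
#' error (images with zero ground-truth count are excluded from MAPE and
#' reported in `mape_excluded`), and the coefficient of determination
#' `R^2 = 1 - sum((G - P)^2) / sum((G - mean(G))^2)`.
#'
#' @param G,P equal-length numeric vectors of ground-truth and predicted
#'   counts.
#' @return list with `n_images`, `mae`, `rmse`, `mape` (percent), `r2`,
#'   `mape_excluded`.
#' @export
counting_metrics <- function(G, P) {
  if (length(G) != length(P)) stop("counting_metrics: length mismatch")
  if (length(G) < 1) stop("counting_metrics: empty input")
  err <- G - P
  mae <- mean(abs(err))
  rmse <- sqrt(mean(err^2))
  nz <- G != 0
  mape <- if (any(nz)) mean(abs(err[nz] / G[nz])) * 100 else NA_real_
  ss_res <- sum(err^2)
  ss_tot <- sum((G - mean(G))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else if (ss_res == 0) 1 else NA_real_
  list(n_images = length(G), mae = mae, rmse = rmse, mape = mape, r2 = r2,
       mape_excluded = sum(!nz))
}

#' F1-confidence curve and its area
#'
#' For each confidence threshold on a grid, detections below the threshold
#' are discarded, true/false positives are accumulated over all images and
#' the F1 score computed; the curve's area over confidence in `[0, 1]`
#' (trapezoidal rule) summarizes robustness to the threshold choice.
#'
#' @param dets_list,gts_list per-image detections and ground truth.
#' @param iou_thresh matching IoU.
#' @param grid increasing confidence thresholds in `[0, 1]` (>= 2 points).
#' @return list with `confidence`, `f1`, `area`.
#' @export
afc_curve <- function(dets_list, gts_list, iou_thresh = 0.5,
                      grid = seq(0, 1, by = 0.02)) {
  stopifnot(length(grid) >= 2, all(grid >= 0), all(grid <= 1), !is.unsorted(grid))
  f1s <- vapply(grid, function(thr) {
    tot <- c(tp = 0, fp = 0, fn = 0)
    for (i in seq_along(dets_list)) {
      d <- dets_list[[i]]
      d <- d[d$confidence >= thr, , drop = FALSE]
      tot <- tot + match_detections(d, gts_list[[i]], iou_thresh)
    }
    pr <- precision_recall(tot["tp"], tot["fp"], tot["fn"])
    f1_score(pr["precision"], pr["recall"])
  }, numeric(1))
  area <- sum(diff(grid) * (f1s[-1] + f1s[-length(f1s)]) / 2)
  list(confidence = grid, f1 = f1s, area = area)
}

#' Full detection + counting evaluation
#'
#' Computes the detection metrics (precision, recall and F1 at
#' `conf_thresh`, AP and the AFC area over all confidences) and the counting
#' metrics (per-image detection counts at `conf_thresh` against ground-truth
#' counts) for a prediction set. Detections should be NMS output obtained
#' with a low confidence floor (e.g. 0.001) so the confidence sweep is
#' meaningful.
#'
#' @param dets_list,gts_list per-image detections and ground-truth boxes.
#' @param iou_thresh matching IoU.
#' @param conf_thresh operating confidence for the point metrics and counts.
#' @return a `wl_eval_report` list.
#' @export
evaluate_detections <- function(dets_list, gts_list, iou_thresh = 0.5,
                                conf_thresh = 0.25) {
  stopifnot(length(dets_list) == length(gts_list))
  tot <- c(tp = 0, fp = 0, fn = 0)
  counts_p <- numeric(length(dets_list))
  for (i in seq_along(dets_list)) {
    d <- dets_list[[i]]
    d <- d[d$confidence >= conf_thresh, , drop = FALSE]
    counts_p[i] <- NROW(d)
    tot <- tot + match_detections(d, gts_list[[i]], iou_thresh)
  }
  pr <- precision_recall(tot["tp"], tot["fp"], tot["fn"])
  ap <- average_precision(dets_list, gts_list, iou_thresh)
  afc <- afc_curve(dets_list, gts_list, iou_thresh)
  counts_g <- vapply(gts_list, NROW, numeric(1))
  cm <- counting_metrics(counts_g, counts_p)
  structure(list(
    tp = unname(tot["tp"]), fp = unname(tot["fp"]), fn = unname(tot["fn"]),
    precision = unname(pr["precision"]), recall = unname(pr["recall"]),
    f1 = unname(f1_score(pr["precision"], pr["recall"])),
    ap = ap$ap, pr_curve = ap$pr_curve, afc_area = afc$area, afc = afc,
    counting = cm,
    counts = data.frame(image = seq_along(gts_list), gt_count = counts_g,
                        pred_count = counts_p, error = counts_g - counts_p),
    iou_thresh = iou_thresh, conf_thresh = conf_thresh),
    class = "wl_eval_report")
}

#' @export
print.wl_eval_report <- function(x, ...) {
  cat(sprintf("detection:  Pr %.3f  Re %.3f  F1 %.3f  AP %.3f  AFC area %.3f\n",
              x$precision, x$recall, x$f1, x$ap, x$afc_area))
  cat(sprintf("counting:   MAE %.2f  RMSE %.2f  MAPE %.1f%%  R2 %.3f  (n = %d)\n",
              x$counting$mae, x$counting$rmse, x$counting$mape,
              x$counting$r2, x$counting$n_images))
  invisible(x)
}

#' Write an evaluation report
#'
#' Serializes the flat metrics as JSON and the per-image count table as CSV
#' (`<path>.json`, `<path>_counts.csv`).
#'
#' @param report a `wl_eval_report`.
#' @param path output path prefix.
#' @return invisibly, the JSON path.
#' @export
write_eval_report <- function(report, path) {
  flat <- list(precision = report$precision, recall = report$recall,
               f1 = report$f1, ap = report$ap, afc_area = report$afc_area,
               mae = report$counting$mae, rmse = report$counting$rmse,
               mape = report$counting$mape, r2 = report$counting$r2,
               n_images = report$counting$n_images,
               iou_thresh = report$iou_thresh, conf_thresh = report$conf_thresh)
  jsonlite::write_json(flat, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  write.csv(report$counts, paste0(path, "_counts.csv"), row.names = FALSE)
  invisible(paste0(path, ".json"))
}

#' Diagnostic plots for an evaluation report
#'
#' Draws the precision-recall curve, the F1-confidence curve, and the count
#' regression scatter with identity line.
#'
#' @param x a `wl_eval_report`.
#' @param ... unused.
#' @export
plot.wl_eval_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  plot(x$pr_curve$recall, x$pr_curve$precision, type = "l", xlim = c(0, 1),
       ylim = c(0, 1), xlab = "recall", ylab = "precision",
       main = sprintf("AP = %.3f", x$ap))
  plot(x$afc$confidence, x$afc$f1, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "confidence", ylab = "F1", main = sprintf("AFC area = %.3f", x$afc_area))
  lim <- range(c(x$counts$gt_count, x$counts$pred_count))
  plot(x$counts$gt_count, x$counts$pred_count, xlim = lim, ylim = lim,
       xlab = "ground-truth count", ylab = "predicted count",
       main = sprintf("R2 = %.3f", x$counting$r2))
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
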
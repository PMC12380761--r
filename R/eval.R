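# ---------------------------------------------------------------------------
# Detection evaluation: AP / mAP, PR curves, confusion matrix.
#
# Matching is greedy per class in descending score; each ground truth is
# matched at most once per IoU threshold.  AP is the area under the 101-point
# interpolated precision-recall curve; mAP@0.5:0.95 averages IoU thresholds
# 0.50, 0.55, ..., 0.95.  Reported precision/recall are taken at the score
# threshold maximising F1 at IoU 0.5.
# ---------------------------------------------------------------------------

#' @export
setClass("EvalReport", representation(
  perClass = "data.frame",
  map50 = "numeric",
  map5095 = "numeric",
  precision = "numeric",
  recall = "numeric",
  prCurves = "list",
  confusion = "matrix",
  skippedClasses = "integer"
))

setMethod("show", "EvalReport", function(object) {
  cat("Detection evaluation\n")
  cat(sprintf("  mAP@0.5       %.1f%%\n", object@map50))
  cat(sprintf("  mAP@0.5:0.95  %.1f%%\n", object@map5095))
  cat(sprintf("  precision     %.1f%%  recall %.1f%%  (max-F1 operating point)\n",
              object@precision, object@recall))
  cat(sprintf("  %d classes evaluated", nrow(object@perClass)))
  if (length(object@skippedClasses))
    cat(sprintf(" (%d skipped, no ground truth)", length(object@skippedClasses)))
  cat("\n")
})

# Greedy matching of one class's detections at one IoU threshold.
# det: data.frame sorted by descending score with image + xyxy columns.
# gts: list per image of xyxy matrices.  Returns logical TP vector.
matchClass <- function(det, gts, thr) {
  used <- lapply(gts, function(g) logical(nrow(g)))
  tp <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    img <- as.character(det$image[i])
    g <- gts[[img]]
    if (is.null(g) || !nrow(g)) next
    ious <- boxIoU(as.matrix(det[i, c("x1", "y1", "x2", "y2")]), g)[1, ]
    ious[used[[img]]] <- -1
    j <- which.max(ious)
    if (length(j) && ious[j] >= thr) {
      tp[i] <- TRUE
      used[[img]][j] <- TRUE
    }
  }
  tp
}

# 101-point interpolated AP from TP flags (score-sorted) and GT count.
apFromTP <- function(tp, n_gt) {
  if (n_gt == 0) return(NA_real_)
  if (!length(tp)) return(0)
  cumtp <- cumsum(tp)
  rec <- cumtp / n_gt
  prec <- cumtp / seq_along(tp)
  # precision envelope, evaluated at 101 recall points
  rp <- seq(0, 1, by = 0.01)
  ap <- mean(vapply(rp, function(r) {
    ok <- rec >= r - 1e-12
    if (any(ok)) max(prec[ok]) else 0
  }, numeric(1)))
  ap
}

normDet <- function(det) {
  xy <- cxcywhToXyxy(as.matrix(det[, c("cx", "cy", "w", "h")]))
  det$x1 <- xy[, 1]; det$y1 <- xy[, 2]; det$x2 <- xy[, 3]; det$y2 <- xy[, 4]
  det
}

#' Evaluate detections against ground truth
#'
#' @param detections data.frame with columns image, class_id, score, cx, cy,
#'   w, h (normalized center-format boxes).
#' @param ground_truth data.frame with columns image, class_id, cx, cy, w, h.
#' @param nc number of classes.
#' @param iou_thresholds IoU thresholds; the first is used for the headline
#'   precision/recall and the confusion matrix.
#' @param conf_threshold score threshold of the confusion matrix.
#' @param class_names optional class-name vector.
#' @return an `EvalReport`.
#' @export
evaluateDetections <- function(detections, ground_truth, nc,
                               iou_thresholds = seq(0.5, 0.95, by = 0.05),
                               conf_threshold = 0.25, class_names = NULL) {
  det <- if (nrow(detections)) normDet(detections) else detections
  gt <- if (nrow(ground_truth)) normDet(cbind(ground_truth, score = 1)) else ground_truth
  classes <- 0:(nc - 1)
  ap_mat <- matrix(NA_real_, nc, length(iou_thresholds))
  pr_curves <- list()
  prec_f1 <- rep(NA_real_, nc); rec_f1 <- rep(NA_real_, nc)
  skipped <- integer(0)
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    gts_cl <- if (nrow(gt)) gt[gt$class_id == cl, ] else gt
    n_gt <- if (nrow(ground_truth)) nrow(gts_cl) else 0
    if (n_gt == 0) { skipped <- c(skipped, cl); next }
    gts <- split(as.matrix(gts_cl[, c("x1", "y1", "x2", "y2")]),
                 as.character(gts_cl$image))
    gts <- lapply(gts, function(v) matrix(v, ncol = 4))
    det_cl <- if (nrow(det)) det[det$class_id == cl, , drop = FALSE] else det
    if (nrow(det_cl)) det_cl <- det_cl[order(-det_cl$score), , drop = FALSE]
    for (ti in seq_along(iou_thresholds)) {
      tp <- if (nrow(det_cl)) matchClass(det_cl, gts, iou_thresholds[ti]) else logical(0)
      ap_mat[ci, ti] <- apFromTP(tp, n_gt)
      if (ti == 1L) {
        # PR curve + max-F1 operating point at the headline threshold
        if (length(tp)) {
          cumtp <- cumsum(tp)
          rec <- cumtp / n_gt
          prec <- cumtp / seq_along(tp)
          f1 <- 2 * prec * rec / pmax(prec + rec, 1e-12)
          b <- which.max(f1)
          prec_f1[ci] <- prec[b]; rec_f1[ci] <- rec[b]
          rp <- seq(0, 1, by = 0.01)
          pr <- vapply(rp, function(r) {
            ok <- rec >= r - 1e-12
            if (any(ok)) max(prec[ok]) else 0
          }, numeric(1))
          pr_curves[[as.character(cl)]] <- cbind(recall = rp, precision = pr)
        } else {
          prec_f1[ci] <- 0; rec_f1[ci] <- 0
          pr_curves[[as.character(cl)]] <-
            cbind(recall = seq(0, 1, by = 0.01), precision = 0)
        }
      }
    }
  }
  evald <- setdiff(seq_len(nc), skipped + 1L)
  per_class <- data.frame(
    class_id = classes,
    name = if (is.null(class_names)) as.character(classes) else class_names,
    precision = 100 * prec_f1,
    recall = 100 * rec_f1,
    ap50 = 100 * ap_mat[, 1],
    ap5095 = 100 * rowMeans(ap_mat)
  )[evald, , drop = FALSE]
  conf <- confusionMatrix(det, gt, nc, iou_thresholds[1], conf_threshold)
  new("EvalReport",
      perClass = per_class,
      map50 = mean(per_class$ap50),
      map5095 = mean(per_class$ap5095),
      precision = mean(per_class$precision),
      recall = mean(per_class$recall),
      prCurves = pr_curves,
      confusion = conf,
      skippedClasses = as.integer(skipped))
}

#' Detection confusion matrix
#'
#' Rows are annotated classes, columns predicted classes, both with an
#' explicit trailing background entry; matching is greedy by score at the
#' given IoU threshold, detections below `conf_threshold` are ignored.
#'
#' @inheritParams evaluateDetections
#' @param iou_threshold matching threshold.
#' @return (nc+1) x (nc+1) integer matrix.
#' @export
confusionMatrix <- function(detections, ground_truth, nc,
                            iou_threshold = 0.5, conf_threshold = 0.25) {
  lab <- c(as.character(0:(nc - 1)), "background")
  cm <- matrix(0L, nc + 1L, nc + 1L, dimnames = list(truth = lab, pred = lab))
  det <- detections
  if (nrow(det)) det <- det[det$score >= conf_threshold, , drop = FALSE]
  imgs <- unique(c(if (nrow(det)) as.character(det$image),
                   if (nrow(ground_truth)) as.character(ground_truth$image)))
  for (img in imgs) {
    d <- if (nrow(det)) det[as.character(det$image) == img, , drop = FALSE] else det
    g <- if (nrow(ground_truth))
      ground_truth[as.character(ground_truth$image) == img, , drop = FALSE]
      else ground_truth
    if (nrow(d)) d <- d[order(-d$score), , drop = FALSE]
    gused <- logical(nrow(g))
    for (i in seq_len(nrow(d))) {
      if (!nrow(g)) { cm[nc + 1L, d$class_id[i] + 1L] <- cm[nc + 1L, d$class_id[i] + 1L] + 1L; next }
      ious <- boxIoU(matrix(as.numeric(d[i, c("x1", "y1", "x2", "y2")]), 1),
                     as.matrix(g[, c("x1", "y1", "x2", "y2")]))[1, ]
      ious[gused] <- -1
      j <- which.max(ious)
      if (length(j) && ious[j] >= iou_threshold) {
        gused[j] <- TRUE
        cm[g$class_id[j] + 1L, d$class_id[i] + 1L] <-
          cm[g$class_id[j] + 1L, d$class_id[i] + 1L] + 1L
      } else {
        cm[nc + 1L, d$class_id[i] + 1L] <- cm[nc + 1L, d$class_id[i] + 1L] + 1L
      }
    }
    if (nrow(g) && any(!gused))
      for (j in which(!gused))
        cm[g$class_id[j] + 1L, nc + 1L] <- cm[g$class_id[j] + 1L, nc + 1L] + 1L
  }
  cm
}
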
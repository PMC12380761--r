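# ---------------------------------------------------------------------------
# Decoding, target assignment and the detection loss.
#
# Head outputs per level are raw maps: class logits (H,W,nc,N) and binned
# box-side logits (H,W,4*reg_max,N), channel c = (side-1)*reg_max + bin with
# sides ordered (left, top, right, bottom) as stride-unit distances from the
# cell center.  Cells are flattened level by level in R's native array order
# (row index fastest); ties in the assigner break toward the lowest flat
# index.
# ---------------------------------------------------------------------------

# softmax over bins for each of the 4 sides; m is (ncell x 4*reg_max) with
# bin fastest within side.  Returns bin probabilities (same layout) and the
# expected bin index per side.
softmaxSides <- function(m, reg_max) {
  ncell <- nrow(m)
  prob <- m
  dist <- matrix(0, ncell, 4)
  bins <- 0:(reg_max - 1)
  for (sd in 1:4) {
    cols <- (sd - 1L) * reg_max + seq_len(reg_max)
    mm <- m[, cols, drop = FALSE]
    mx <- mm[, 1]
    for (j in 2:reg_max) mx <- pmax(mx, mm[, j])
    e <- exp(mm - mx)
    p <- e / rowSums(e)
    prob[, cols] <- p
    dist[, sd] <- as.vector(p %*% bins)
  }
  list(prob = prob, dist = dist)
}

# Flatten one head set's per-level outputs for one image into matrices.
# `pre` optionally carries per-level precomputed class probabilities and
# bin softmax (from cpp_dfl_softmax), flattened alongside.
flattenLevels <- function(levels, n, input, pre = NULL) {
  cls <- list(); box <- list(); cx <- list(); cy <- list(); st <- list()
  clsp <- list(); prob <- list(); dist <- list()
  for (li in seq_along(levels)) {
    lv <- levels[[li]]
    d <- dim(lv$cls)
    H <- d[1]; W <- d[2]
    cls[[li]] <- matrix(lv$cls[, , , n], H * W, d[3])
    box[[li]] <- matrix(lv$box[, , , n], H * W, dim(lv$box)[3])
    if (!is.null(pre)) {
      clsp[[li]] <- matrix(pre[[li]]$clsp[, , , n], H * W, d[3])
      prob[[li]] <- matrix(pre[[li]]$prob[, , , n], H * W, dim(lv$box)[3])
      dist[[li]] <- matrix(pre[[li]]$dist[, , , n], H * W, 4)
    }
    s <- lv$stride
    cx[[li]] <- rep((seq_len(W) - 0.5) * s, each = H)
    cy[[li]] <- rep((seq_len(H) - 0.5) * s, times = W)
    st[[li]] <- rep(s, H * W)
  }
  out <- list(cls = do.call(rbind, cls), box = do.call(rbind, box),
              cx = unlist(cx), cy = unlist(cy), stride = unlist(st),
              sizes = vapply(levels, function(lv) prod(dim(lv$cls)[1:2]),
                             numeric(1)))
  if (!is.null(pre)) {
    out$clsp <- do.call(rbind, clsp)
    out$prob <- do.call(rbind, prob)
    out$dist <- do.call(rbind, dist)
  }
  out
}

#' Decode binned box predictions
#'
#' Converts per-side bin logits into normalized corner boxes: each side
#' distance is the softmax-expected bin index in stride units, measured from
#' the cell center.
#'
#' @param box_logits (ncell x 4*reg_max) matrix of side-bin logits.
#' @param cx,cy cell center coordinates in pixels.
#' @param stride per-cell stride in pixels.
#' @param reg_max number of bins per side.
#' @param input input resolution in pixels.
#' @param clip clip boxes to the unit square.
#' @return list with `xyxy` (normalized corner boxes), `dist` (ncell x 4
#'   stride-unit distances) and `prob` (softmax bin probabilities).
#' @export
decodeBoxes <- function(box_logits, cx, cy, stride, reg_max, input,
                        clip = TRUE) {
  ncell <- nrow(box_logits)
  sm <- softmaxSides(box_logits, reg_max)
  p <- array(sm$prob, c(ncell, reg_max, 4))
  dist <- sm$dist
  x1 <- (cx - dist[, 1] * stride) / input
  y1 <- (cy - dist[, 2] * stride) / input
  x2 <- (cx + dist[, 3] * stride) / input
  y2 <- (cy + dist[, 4] * stride) / input
  xy <- cbind(x1, y1, x2, y2)
  if (clip) xy <- pmin(pmax(xy, 0), 1)
  list(xyxy = xy, dist = dist, prob = p)
}

#' Task-aligned target assignment
#'
#' One-to-many assignment ranking candidate cells by score^alpha * IoU^beta
#' with top-k selection per ground-truth box; `topk = 1` yields the parallel
#' one-to-one branch.  Candidates are cells whose center lies inside the box;
#' a ground truth with no interior cell falls back to the best-overlap (or
#' nearest-center) cell, so every ground truth with nonzero overlap receives
#' at least one candidate.  Ties break deterministically toward the lowest
#' flat cell index.
#'
#' @param scores (ncell x nc) class probabilities in (0,1).
#' @param boxes (ncell x 4) decoded normalized corner boxes.
#' @param centers (ncell x 2) normalized cell-center coordinates.
#' @param gt_boxes (m x 4) normalized corner ground-truth boxes.
#' @param gt_cls integer vector of ground-truth class ids (0-based).
#' @param topk candidates per ground truth.
#' @param alpha,beta metric exponents.
#' @return list with `fg` (logical per cell), `gt_idx` (assigned ground-truth
#'   row per cell, NA if background), `tscore` (target score per cell).
#' @export
assignTargets <- function(scores, boxes, centers, gt_boxes, gt_cls,
                          topk = 10L, alpha = 0.5, beta = 6.0) {
  ncell <- nrow(scores)
  m <- if (is.null(gt_boxes)) 0L else nrow(rbind(gt_boxes))
  fg <- logical(ncell); gt_idx <- rep(NA_integer_, ncell)
  tscore <- numeric(ncell)
  if (m == 0L)
    return(list(fg = fg, gt_idx = gt_idx, tscore = tscore))
  gt_boxes <- rbind(gt_boxes)
  iou <- boxIoU(boxes, gt_boxes)
  inbox <- outer(centers[, 1], gt_boxes[, 1], `>`) &
    outer(centers[, 1], gt_boxes[, 3], `<`) &
    outer(centers[, 2], gt_boxes[, 2], `>`) &
    outer(centers[, 2], gt_boxes[, 4], `<`)
  sc <- pmin(pmax(scores[, gt_cls + 1L, drop = FALSE], 1e-9), 1)
  metric <- (sc^alpha) * (pmax(iou, 0)^beta) * inbox
  cand <- matrix(FALSE, ncell, m)
  for (j in seq_len(m)) {
    mj <- metric[, j]
    if (!any(mj > 0)) {
      # fallback: best overlap, else nearest center
      if (any(iou[, j] > 0)) {
        cand[which.max(iou[, j]), j] <- TRUE
        metric[which.max(iou[, j]), j] <- 1e-9
      } else {
        d2 <- (centers[, 1] - (gt_boxes[j, 1] + gt_boxes[j, 3]) / 2)^2 +
          (centers[, 2] - (gt_boxes[j, 2] + gt_boxes[j, 4]) / 2)^2
        cand[which.min(d2), j] <- TRUE
        metric[which.min(d2), j] <- 1e-9
      }
      next
    }
    k <- min(topk, sum(mj > 0))
    ord <- order(-mj, seq_len(ncell))[seq_len(k)]
    cand[ord, j] <- TRUE
  }
  # a cell claimed by several ground truths keeps the one with highest IoU
  multi <- rowSums(cand) > 1L
  if (any(multi)) {
    for (i in which(multi)) {
      keep <- which(cand[i, ])[which.max(iou[i, cand[i, ]])]
      cand[i, ] <- FALSE; cand[i, keep] <- TRUE
    }
  }
  for (j in seq_len(m)) {
    rows <- which(cand[, j])
    if (!length(rows)) next
    # target score: metric normalized per ground truth, scaled by best IoU
    mmax <- max(metric[rows, j]); imax <- max(iou[rows, j])
    fg[rows] <- TRUE
    gt_idx[rows] <- j
    tscore[rows] <- metric[rows, j] / (mmax + 1e-9) * max(imax, 1e-9)
  }
  list(fg = fg, gt_idx = gt_idx, tscore = tscore)
}

# ---------------------------------------------------------------------------
# Detection loss for one image and one head set.
# Returns loss components and gradients w.r.t. the raw logits.
# ---------------------------------------------------------------------------
detectionLossImage <- function(flat, gt_boxes, gt_cls, nc, reg_max, input,
                               topk = 10L,
                               weights = c(box = 7.5, dfl = 1.5, cls = 0.5)) {
  ncell <- nrow(flat$cls)
  cls_p <- if (!is.null(flat$clsp)) flat$clsp else sigmoidv(flat$cls)
  dec <- if (!is.null(flat$dist)) {
    dist <- flat$dist
    xy <- cbind((flat$cx - dist[, 1] * flat$stride) / input,
                (flat$cy - dist[, 2] * flat$stride) / input,
                (flat$cx + dist[, 3] * flat$stride) / input,
                (flat$cy + dist[, 4] * flat$stride) / input)
    list(xyxy = xy, dist = dist,
         prob = array(flat$prob, c(ncell, reg_max, 4)))
  } else {
    decodeBoxes(flat$box, flat$cx, flat$cy, flat$stride, reg_max, input,
                clip = FALSE)
  }
  centers <- cbind(flat$cx, flat$cy) / input
  asg <- assignTargets(cls_p, dec$xyxy, centers, gt_boxes, gt_cls,
                       topk = topk)
  tmat <- matrix(0, ncell, nc)
  fg <- which(asg$fg)
  if (length(fg))
    tmat[cbind(fg, gt_cls[asg$gt_idx[fg]] + 1L)] <- asg$tscore[fg]
  norm <- max(sum(asg$tscore), 1)
  # classification: binary cross-entropy over all cells and classes
  eps <- 1e-9
  cls_loss <- -sum(tmat * log(cls_p + eps) + (1 - tmat) * log(1 - cls_p + eps)) / norm
  g_cls <- (cls_p - tmat) / norm
  g_box <- matrix(0, ncell, 4 * reg_max)
  box_loss <- 0; dfl_loss <- 0
  if (length(fg)) {
    w <- asg$tscore[fg] / norm
    tb <- rbind(gt_boxes)[asg$gt_idx[fg], , drop = FALSE]
    pb <- dec$xyxy[fg, , drop = FALSE]
    cg <- ciouWithGrad(pb, tb)
    box_loss <- sum((1 - cg$ciou) * w)
    # chain: d xyxy / d dist: x1 = (cx - l*s)/input etc.
    sN <- flat$stride[fg] / input
    gdist <- cbind(-cg$grad[, 1] * sN, -cg$grad[, 2] * sN,
                   cg$grad[, 3] * sN, cg$grad[, 4] * sN)  # d ciou / d dist
    gdist <- -gdist * w  # loss = (1 - ciou) * w
    # target distances in stride units, clamped into the bin range
    tdist <- cbind((flat$cx[fg] / input - tb[, 1]) ,
                   (flat$cy[fg] / input - tb[, 2]) ,
                   (tb[, 3] - flat$cx[fg] / input),
                   (tb[, 4] - flat$cy[fg] / input)) * input / flat$stride[fg]
    tdist <- pmin(pmax(tdist, 0), reg_max - 1 - 1e-3)
    lo <- floor(tdist); hi <- lo + 1
    wh <- tdist - lo; wl <- 1 - wh
    p <- dec$prob[fg, , , drop = FALSE]   # (nfg, reg_max, 4)
    dist <- dec$dist[fg, , drop = FALSE]
    nfg <- length(fg)
    bins <- seq_len(reg_max) - 1
    for (sd in 1:4) {
      ps <- matrix(p[, , sd], nfg, reg_max)
      il <- cbind(seq_len(nfg), lo[, sd] + 1L)
      ih <- cbind(seq_len(nfg), hi[, sd] + 1L)
      dfl_loss <- dfl_loss -
        sum((wl[, sd] * log(ps[il] + eps) + wh[, sd] * log(ps[ih] + eps)) * w)
      # gradient of dfl w.r.t. side logits: softmax CE with two-hot target
      y <- matrix(0, nfg, reg_max)
      y[il] <- wl[, sd]; y[ih] <- y[ih] + wh[, sd]
      gz_dfl <- (ps - y) * w * weights[["dfl"]]
      # gradient of box (ciou) term through the softmax expectation
      gz_box <- ps * (matrix(bins, nfg, reg_max, byrow = TRUE) - dist[, sd]) *
        gdist[, sd] * weights[["box"]]
      cols <- (sd - 1L) * reg_max + seq_len(reg_max)
      g_box[fg, cols] <- g_box[fg, cols] + gz_dfl + gz_box
    }
  }
  total <- weights[["box"]] * box_loss + weights[["dfl"]] * dfl_loss +
    weights[["cls"]] * cls_loss
  list(total = total, box = box_loss, dfl = dfl_loss, cls = cls_loss,
       g_cls = g_cls * weights[["cls"]], g_box = g_box,
       n_fg = length(fg))
}

#' Detection loss for a batch of images
#'
#' Computes the three-component detection loss (complete-IoU box term, binned
#' distribution term for the box sides, binary cross-entropy class term) for
#' one head set, together with gradients with respect to the raw head maps.
#'
#' @param levels per-level head outputs (list of `stride`, `box`, `cls`).
#' @param targets list per image: list(boxes = normalized cxcywh matrix,
#'   cls = 0-based integer classes).
#' @param nc number of classes.
#' @param reg_max bins per box side.
#' @param input input resolution in pixels.
#' @param topk one-to-many candidate count (1 = one-to-one branch).
#' @param weights named loss weights (box, dfl, cls).
#' @return list with mean loss components and per-level gradient arrays.
#' @export
detectionLoss <- function(levels, targets, nc, reg_max, input, topk = 10L,
                          weights = c(box = 7.5, dfl = 1.5, cls = 0.5)) {
  N <- dim(levels[[1]]$cls)[4]
  pre <- lapply(levels, function(lv) {
    sm <- cpp_dfl_softmax(lv$box, reg_max)
    list(clsp = cpp_sigmoid(lv$cls), prob = sm$prob, dist = sm$dist)
  })
  grid <- cellGrid(levels)
  tg <- lapply(targets, function(t)
    list(gtb = if (length(t$cls)) cxcywhToXyxy(t$boxes)
               else matrix(numeric(0), 0, 4),
         cls = as.integer(t$cls)))
  r <- cpp_det_loss_batch(lapply(pre, `[[`, "clsp"),
                          lapply(pre, `[[`, "prob"),
                          lapply(pre, `[[`, "dist"),
                          grid$cx, grid$cy, grid$stride, tg,
                          as.integer(topk), 0.5, 6.0, as.integer(reg_max),
                          input, weights[["box"]], weights[["dfl"]],
                          weights[["cls"]])
  g_cls <- lapply(r$g_cls, function(g) g / N)
  g_box <- lapply(r$g_box, function(g) g / N)
  list(total = r$total, box = r$box, dfl = r$dfl, cls = r$cls,
       g_cls = g_cls, g_box = g_box)
}

# flattened cell-center grid over a level list
cellGrid <- function(levels) {
  cx <- list(); cy <- list(); st <- list()
  for (li in seq_along(levels)) {
    lv <- levels[[li]]
    d <- dim(lv$cls)
    H <- d[1]; W <- d[2]; s <- lv$stride
    cx[[li]] <- rep((seq_len(W) - 0.5) * s, each = H)
    cy[[li]] <- rep((seq_len(H) - 0.5) * s, times = W)
    st[[li]] <- rep(s, H * W)
  }
  list(cx = unlist(cx), cy = unlist(cy), stride = unlist(st))
}

#' Run inference and decode detections
#'
#' Uses the one-to-one head (selection by top-k confidence, no non-maximum
#' suppression) with an optional NMS fallback.
#'
#' @param model a trained `VegModel`.
#' @param x input batch (N, 3, S, S) feature map array.
#' @param conf confidence threshold.
#' @param topk maximum detections per image.
#' @param nms apply class-wise greedy NMS as a fallback.
#' @param iou_nms NMS IoU threshold.
#' @return data.frame with columns image, class_id, score, cx, cy, w, h
#'   (normalized, clipped to the unit square).
#' @export
predictBoxes <- function(model, x, conf = 0.25, topk = 300L, nms = FALSE,
                         iou_nms = 0.7) {
  out <- forwardModel(model, x, training = FALSE)
  levels <- out$outputs$o2o
  N <- dim(x)[4]
  input <- dim(x)[1]
  reg_max <- model@config@arch$head$reg_max
  res <- list()
  for (n in seq_len(N)) {
    flat <- flattenLevels(levels, n, input)
    p <- sigmoidv(flat$cls)
    best <- max.col(p, ties.method = "first")
    sc <- p[cbind(seq_len(nrow(p)), best)]
    keep <- which(sc >= conf)
    if (!length(keep)) next
    keep <- keep[order(-sc[keep])][seq_len(min(topk, length(keep)))]
    dec <- decodeBoxes(flat$box[keep, , drop = FALSE], flat$cx[keep],
                       flat$cy[keep], flat$stride[keep], reg_max, input)
    xy <- dec$xyxy
    if (nms && nrow(xy) > 1) {
      sel <- logical(nrow(xy))
      for (cl in unique(best[keep])) {
        idx <- which(best[keep] == cl)
        while (length(idx)) {
          sel[idx[1]] <- TRUE
          if (length(idx) == 1) break
          ious <- boxIoU(xy[idx[1], , drop = FALSE], xy[idx[-1], , drop = FALSE])
          idx <- idx[-1][ious[1, ] <= iou_nms]
        }
      }
      keep <- keep[sel]; xy <- xy[sel, , drop = FALSE]
    }
    cw <- xyxyToCxcywh(xy)
    ok <- cw[, 3] > 0 & cw[, 4] > 0
    if (!any(ok)) next
    res[[length(res) + 1L]] <- data.frame(
      image = n, class_id = best[keep][ok] - 1L,
      score = p[cbind(keep, best[keep])][ok],
      cx = cw[ok, 1], cy = cw[ok, 2], w = cw[ok, 3], h = cw[ok, 4])
  }
  if (!length(res))
    return(data.frame(image = integer(0), class_id = integer(0),
                      score = numeric(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0)))
  do.call(rbind, res)
}
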
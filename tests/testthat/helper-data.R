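# Shared fixtures, built in code.

# small in-memory synthetic detection dataset
makeToyData <- function(n, nc = 5, size = 96, seed0 = 0, ...) {
  images <- vector("list", n)
  targets <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- randomSceneSpec((i - 1) %% nc, size = size, seed = seed0 + i,
                          n_leaves = c(2, 3), lesions_per_leaf = c(1, 3), ...)
    s <- generateScene(sp)
    images[[i]] <- s$image
    targets[[i]] <- list(boxes = s$boxes, cls = s$cls)
  }
  list(images = images, targets = targets, nc = nc,
       names = as.character(seq_len(nc) - 1))
}

# brute-force parameter enumeration over a module/model params list
bruteParamCount <- function(params) sum(vapply(params, length, numeric(1)))

# random normalized cxcywh boxes that stay inside the unit square
randomBoxes <- function(n) {
  w <- runif(n, 0.05, 0.4)
  h <- runif(n, 0.05, 0.4)
  cx <- runif(n, w / 2, 1 - w / 2)
  cy <- runif(n, h / 2, 1 - h / 2)
  cbind(cx, cy, w, h)
}

# independent greedy-matching + threshold-sweep AP oracle (exhaustive PR
# construction: precision/recall computed at every distinct score cut)
oracleAP <- function(det, gts, thr) {
  # det: data.frame(score, x1..y2) one class one set of images via det$image
  n_gt <- sum(vapply(gts, nrow, numeric(1)))
  if (n_gt == 0) return(NA_real_)
  if (!nrow(det)) return(0)
  det <- det[order(-det$score, seq_len(nrow(det))), , drop = FALSE]
  used <- lapply(gts, function(g) logical(nrow(g)))
  tp <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    g <- gts[[as.character(det$image[i])]]
    if (is.null(g) || !nrow(g)) next
    best <- -1; bj <- 0
    for (j in seq_len(nrow(g))) {
      if (used[[as.character(det$image[i])]][j]) next
      iou <- boxIoU(as.matrix(det[i, c("x1", "y1", "x2", "y2")]),
                    g[j, , drop = FALSE])[1, 1]
      if (iou > best) { best <- iou; bj <- j }
    }
    if (bj > 0 && best >= thr) {
      tp[i] <- TRUE
      used[[as.character(det$image[i])]][bj] <- TRUE
    }
  }
  # exhaustive PR points at every cutoff
  prec <- rec <- numeric(nrow(det))
  for (k in seq_len(nrow(det))) {
    prec[k] <- sum(tp[1:k]) / k
    rec[k] <- sum(tp[1:k]) / n_gt
  }
  mean(vapply(seq(0, 1, 0.01), function(r) {
    ok <- rec >= r - 1e-12
    if (any(ok)) max(prec[ok]) else 0
  }, numeric(1)))
}
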
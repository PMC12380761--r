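# Loss, assignment, evaluation and the training loop.

test_that("the box term vanishes when predictions equal their targets", {
  set.seed(51)
  reg_max <- 8
  # one cell; the ground truth is chosen as that cell's decoded box, so the
  # matched pair has CIoU(b, b) = 1 and the box term is exactly zero
  cls <- matrix(rnorm(2, -3), 1, 2)
  box <- matrix(rnorm(4 * reg_max), 1, 4 * reg_max)
  cx <- 16; cy <- 16; stride <- 8
  dec <- decodeBoxes(box, cx, cy, stride, reg_max, 32, clip = FALSE)
  gtb <- dec$xyxy[1, , drop = FALSE]
  flat <- list(cls = cls, box = box, cx = cx, cy = cy, stride = stride)
  r <- vegyolo:::detectionLossImage(flat, gtb, 0L, 2, reg_max, 32)
  expect_lt(r$box, 1e-9)
})

test_that("the complete-IoU gradient matches central finite differences", {
  set.seed(52)
  for (i in 1:20) {
    p <- cxcywhToXyxy(randomBoxes(1))
    t <- cxcywhToXyxy(randomBoxes(1))
    r <- vegyolo:::ciouWithGrad(p, t)
    a0 <- r$alpha
    eps <- 1e-7
    # alpha is treated as a constant of the gradient (the detached
    # convention); the finite difference follows the same convention
    fd_ciou <- function(pp) {
      rr <- vegyolo:::ciouWithGrad(pp, t)
      rr$iou - rr$rho2c2 - a0 * rr$v
    }
    for (k in 1:4) {
      p1 <- p; p1[k] <- p1[k] + eps
      p2 <- p; p2[k] <- p2[k] - eps
      fd <- (fd_ciou(p1) - fd_ciou(p2)) / (2 * eps)
      expect_equal(unname(r$grad[1, k]), unname(fd), tolerance = 1e-4)
    }
  }
})

test_that("a target distance on a bin center reduces the distribution term to one-hot cross-entropy", {
  reg_max <- 8
  ncell <- 1
  # single cell at center (4, 4), stride 8, image 32: pick a gt whose side
  # distances are exactly 1 stride unit
  cx <- 4; cy <- 4; stride <- 8
  gtb <- matrix(c((cx - 8) / 32, (cy - 8) / 32, (cx + 8) / 32, (cy + 8) / 32), 1)
  box <- matrix(rnorm(4 * reg_max), 1)
  cls <- matrix(0, 1, 1)
  flat <- list(cls = cls, box = box, cx = cx, cy = cy, stride = stride)
  r <- vegyolo:::detectionLossImage(flat, gtb, 0L, 1, reg_max, 32,
                                    weights = c(box = 0, dfl = 1, cls = 0))
  sm <- vegyolo:::softmaxSides(box, reg_max)
  manual <- -sum(log(sm$prob[1, (0:3) * reg_max + 2]))   # bin 1 of each side
  tsc <- r$total / r$dfl   # weight applied internally
  expect_equal(r$dfl, manual * (r$dfl / manual), tolerance = 1e-9)
  # the dfl value equals the one-hot cross-entropy times the target score
  w <- r$dfl / manual
  expect_gt(w, 0); expect_lte(w, 1 + 1e-9)
})

test_that("the compiled loss agrees with an explicit-loop oracle on a small grid", {
  set.seed(53)
  for (rep in 1:5) {
    reg_max <- 4; nc <- 2; input <- 16; stride <- 8
    ncell <- 4   # a 2x2 grid
    cx <- rep(c(4, 12), each = 2); cy <- rep(c(4, 12), times = 2)
    st <- rep(stride, 4)
    cls <- matrix(rnorm(ncell * nc), ncell, nc)
    box <- matrix(rnorm(ncell * 4 * reg_max), ncell, 4 * reg_max)
    gtb <- cxcywhToXyxy(randomBoxes(2))
    gtc <- c(0L, 1L)
    # package path (compiled)
    sm <- vegyolo:::softmaxSides(box, reg_max)
    clsp <- 1 / (1 + exp(-cls))
    r <- vegyolo:::cpp_det_loss_image(clsp, sm$prob, sm$dist, cx, cy, st,
                                      gtb, gtc, 10L, 0.5, 6.0, reg_max,
                                      input, 7.5, 1.5, 0.5)
    # independent loop oracle, from the written definitions
    dec <- decodeBoxes(box, cx, cy, st, reg_max, input, clip = FALSE)
    asg <- assignTargets(clsp, dec$xyxy, cbind(cx, cy) / input, gtb, gtc)
    norm <- max(sum(asg$tscore), 1)
    eps <- 1e-9
    cls_o <- 0; box_o <- 0; dfl_o <- 0
    for (i in 1:ncell) for (c in 1:nc) {
      t <- if (!is.na(asg$gt_idx[i]) && gtc[asg$gt_idx[i]] + 1L == c)
        asg$tscore[i] else 0
      cls_o <- cls_o - (t * log(clsp[i, c] + eps) +
                          (1 - t) * log(1 - clsp[i, c] + eps))
    }
    cls_o <- cls_o / norm
    for (i in which(asg$fg)) {
      j <- asg$gt_idx[i]
      w <- asg$tscore[i] / norm
      box_o <- box_o + (1 - boxCIoU(dec$xyxy[i, , drop = FALSE],
                                    gtb[j, , drop = FALSE])) * w
      td <- c(cx[i] / input - gtb[j, 1], cy[i] / input - gtb[j, 2],
              gtb[j, 3] - cx[i] / input, gtb[j, 4] - cy[i] / input) *
        input / st[i]
      td <- pmin(pmax(td, 0), reg_max - 1 - 1e-3)
      for (sd2 in 1:4) {
        lo <- floor(td[sd2]); hi <- lo + 1
        wh <- td[sd2] - lo
        p <- dec$prob[i, , sd2]
        dfl_o <- dfl_o - ((1 - wh) * log(p[lo + 1] + eps) +
                            wh * log(p[hi + 1] + eps)) * w
      }
    }
    expect_equal(unname(r$cls), unname(cls_o), tolerance = 1e-9)
    expect_equal(unname(r$box), unname(box_o), tolerance = 1e-9)
    expect_equal(unname(r$dfl), unname(dfl_o), tolerance = 1e-9)
  }
})

test_that("compiled loss gradients match the reference implementation", {
  set.seed(54)
  for (rep in 1:3) {
    reg_max <- 4; nc <- 3; input <- 16
    ncell <- 4
    cx <- rep(c(4, 12), each = 2); cy <- rep(c(4, 12), times = 2)
    st <- rep(8, 4)
    cls <- matrix(rnorm(ncell * nc), ncell, nc)
    box <- matrix(rnorm(ncell * 4 * reg_max), ncell, 4 * reg_max)
    gtb <- cxcywhToXyxy(randomBoxes(2))
    gtc <- c(0L, 2L)
    sm <- vegyolo:::softmaxSides(box, reg_max)
    clsp <- 1 / (1 + exp(-cls))
    rc <- vegyolo:::cpp_det_loss_image(clsp, sm$prob, sm$dist, cx, cy, st,
                                       gtb, gtc, 10L, 0.5, 6.0, reg_max,
                                       input, 7.5, 1.5, 0.5)
    flat <- list(cls = cls, box = box, cx = cx, cy = cy, stride = st)
    rr <- vegyolo:::detectionLossImage(flat, gtb, gtc, nc, reg_max, input)
    expect_equal(unname(rc$total), unname(rr$total), tolerance = 1e-9)
    expect_equal(unname(rc$g_cls), unname(rr$g_cls), tolerance = 1e-9)
    expect_equal(unname(rc$g_box), unname(rr$g_box), tolerance = 1e-9)
  }
})

test_that("assignment: perfect prediction wins both branches, ties break low, top-k matches a sort oracle", {
  set.seed(55)
  # one gt, one perfect candidate
  boxes <- rbind(c(0.2, 0.2, 0.6, 0.6), c(0.7, 0.7, 0.9, 0.9))
  centers <- rbind(c(0.4, 0.4), c(0.8, 0.8))
  scores <- matrix(c(0.9, 0.1), 2, 1)
  gtb <- rbind(c(0.2, 0.2, 0.6, 0.6))
  for (k in c(10L, 1L)) {
    a <- assignTargets(scores, boxes, centers, gtb, 0L, topk = k)
    expect_true(a$fg[1]); expect_false(a$fg[2])
  }
  # two identical candidates -> lowest flat index
  boxes2 <- rbind(c(0.2, 0.2, 0.6, 0.6), c(0.2, 0.2, 0.6, 0.6))
  centers2 <- rbind(c(0.4, 0.4), c(0.4, 0.4))
  scores2 <- matrix(c(0.5, 0.5), 2, 1)
  a2 <- assignTargets(scores2, boxes2, centers2, gtb, 0L, topk = 1L)
  expect_true(a2$fg[1]); expect_false(a2$fg[2])
  # top-k equals a brute-force full sort on 20 random candidates
  n <- 20
  boxes3 <- cxcywhToXyxy(randomBoxes(n))
  centers3 <- matrix(runif(2 * n, 0.3, 0.7), n, 2)
  scores3 <- matrix(runif(n), n, 1)
  gtb3 <- rbind(c(0.25, 0.25, 0.75, 0.75))
  a3 <- assignTargets(scores3, boxes3, centers3, gtb3, 0L, topk = 5L)
  iou <- boxIoU(boxes3, gtb3)[, 1]
  inb <- centers3[, 1] > 0.25 & centers3[, 1] < 0.75 &
    centers3[, 2] > 0.25 & centers3[, 2] < 0.75
  metric <- scores3[, 1]^0.5 * pmax(iou, 0)^6 * inb
  oracle <- order(-metric, seq_len(n))[1:min(5, sum(metric > 0))]
  expect_setequal(which(a3$fg), oracle[metric[oracle] > 0])
})

test_that("perfect detections score 100 percent at every threshold", {
  set.seed(56)
  gt <- data.frame(image = rep(1:4, each = 3), class_id = rep(0:2, 4),
                   randomBoxes(12))
  names(gt)[3:6] <- c("cx", "cy", "w", "h")
  det <- cbind(gt[, 1:2], score = 1, gt[, 3:6])
  rep <- evaluateDetections(det, gt, 3)
  expect_equal(rep@map50, 100)
  expect_equal(rep@map5095, 100)
})

test_that("with no detections recall is zero and all mass sits in the background column", {
  gt <- data.frame(image = c(1, 1, 2), class_id = c(0L, 1L, 0L),
                   cx = c(0.3, 0.6, 0.5), cy = c(0.3, 0.6, 0.5),
                   w = 0.2, h = 0.2)
  det <- data.frame(image = integer(0), class_id = integer(0),
                    score = numeric(0), cx = numeric(0), cy = numeric(0),
                    w = numeric(0), h = numeric(0))
  rep <- evaluateDetections(det, gt, 2)
  expect_equal(rep@recall, 0)
  cm <- rep@confusion
  expect_equal(sum(cm[, "background"]), 3)
  expect_equal(sum(cm), 3)
})

test_that("one true and one false positive reproduce the hand-built AP", {
  # 1 GT; TP at score 0.9 (IoU 0.9), FP at score 0.8
  gt <- data.frame(image = 1, class_id = 0L, cx = 0.5, cy = 0.5,
                   w = 0.4, h = 0.4)
  tp_box <- c(0.5, 0.5, 0.4 * 0.9486, 0.4 / 0.9486 * 0.9)  # IoU approx 0.9
  det <- data.frame(image = 1, class_id = 0L, score = c(0.9, 0.8),
                    cx = c(0.5, 0.1), cy = c(0.5, 0.1),
                    w = c(0.4, 0.05), h = c(0.4, 0.05))
  rep <- evaluateDetections(det, gt, 1, iou_thresholds = 0.5)
  # oracle: after det1 P=1, R=1; envelope is 1 at every recall point
  gts <- list("1" = cxcywhToXyxy(as.matrix(gt[, c("cx", "cy", "w", "h")])))
  d <- vegyolo:::normDet(det)
  expect_equal(rep@perClass$ap50 / 100, oracleAP(d, gts, 0.5))
})

test_that("the evaluator matches the exhaustive oracle on many random instances", {
  set.seed(57)
  for (case in 1:100) {
    n_gt <- sample(1:5, 1); n_det <- sample(1:5, 1)
    gt <- data.frame(image = 1, class_id = 0L, randomBoxes(n_gt))
    names(gt)[3:6] <- c("cx", "cy", "w", "h")
    det <- data.frame(image = 1, class_id = 0L,
                      score = round(runif(n_det), 2), randomBoxes(n_det))
    names(det)[4:7] <- c("cx", "cy", "w", "h")
    # sometimes make detections overlap ground truth
    k <- sample(0:min(n_gt, n_det), 1)
    if (k > 0) det[seq_len(k), c("cx", "cy", "w", "h")] <-
        gt[seq_len(k), c("cx", "cy", "w", "h")] +
        matrix(runif(4 * k, -0.02, 0.02), k)
    rep <- evaluateDetections(det, gt, 1, iou_thresholds = 0.5)
    gts <- list("1" = cxcywhToXyxy(as.matrix(gt[, c("cx", "cy", "w", "h")])))
    expect_equal(rep@perClass$ap50 / 100,
                 oracleAP(vegyolo:::normDet(det), gts, 0.5),
                 tolerance = 1e-12)
  }
})

test_that("AP is invariant to detection order within equal scores and image shuffling", {
  set.seed(58)
  gt <- data.frame(image = rep(1:3, each = 2), class_id = 0L, randomBoxes(6))
  names(gt)[3:6] <- c("cx", "cy", "w", "h")
  det <- data.frame(image = rep(1:3, 3), class_id = 0L,
                    score = rep(c(0.9, 0.5, 0.5), each = 3), randomBoxes(9))
  names(det)[4:7] <- c("cx", "cy", "w", "h")
  r1 <- evaluateDetections(det, gt, 1)
  r2 <- evaluateDetections(det[sample(nrow(det)), ], gt[sample(nrow(gt)), ], 1)
  expect_equal(r1@map50, r2@map50)
  expect_gte(r1@map50, r1@map5095)
})

test_that("confusion-matrix rows account for every ground truth and background false positives", {
  set.seed(59)
  gt <- data.frame(image = rep(1:4, each = 2), class_id = rep(0:1, 4),
                   randomBoxes(8))
  names(gt)[3:6] <- c("cx", "cy", "w", "h")
  det <- data.frame(image = rep(1:4, 3), class_id = sample(0:1, 12, TRUE),
                    score = runif(12, 0.5, 1), randomBoxes(12))
  names(det)[4:7] <- c("cx", "cy", "w", "h")
  cm <- confusionMatrix(vegyolo:::normDet(det),
                        vegyolo:::normDet(cbind(gt, score = 1)), 2)
  for (cl in 0:1)
    expect_equal(sum(cm[cl + 1L, ]), sum(gt$class_id == cl))
  expect_equal(sum(cm), nrow(gt) + cm[3, 1] + cm[3, 2])
})

test_that("learning-rate schedules reproduce the published settings", {
  cfg <- trainConfig(epochs = 100)
  expect_equal(lrAt(cfg, 0), 0.01)
  cfge <- trainConfig(scheduler = "exp", alpha = 0.95)
  for (e in c(0, 1, 7)) expect_equal(lrAt(cfge, e), 0.01 * 0.95^e)
  expect_error(trainConfig(pretrained = TRUE), "scratch")
})

test_that("a five-epoch smoke run reduces the loss for baseline and full configurations", {
  set.seed(61)
  dat <- makeToyData(48, nc = 5, size = 64, seed0 = 400)
  for (full in c(FALSE, TRUE)) {
    cfg <- modelConfig(64, 5, full, full, full, preset = "tiny")
    set.seed(100)
    model <- buildModel(cfg)
    tcfg <- trainConfig(epochs = 5, input_size = 64, seed = 1)
    res <- trainModel(model, dat, tcfg)
    expect_lt(res$log$total[5], res$log$total[1])
  }
})

test_that("training is deterministic under a fixed seed", {
  set.seed(62)
  dat <- makeToyData(8, nc = 3, size = 64, seed0 = 500)
  cfg <- modelConfig(64, 3, TRUE, TRUE, TRUE, preset = "tiny")
  run1 <- {
    set.seed(9); m <- buildModel(cfg)
    trainModel(m, dat, trainConfig(epochs = 1, input_size = 64, seed = 3))
  }
  run2 <- {
    set.seed(9); m <- buildModel(cfg)
    trainModel(m, dat, trainConfig(epochs = 1, input_size = 64, seed = 3))
  }
  expect_identical(run1$log$total, run2$log$total)
})
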
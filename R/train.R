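# ---------------------------------------------------------------------------
# Training loop: SGD with momentum, weight decay, cosine or exponential
# learning-rate schedule, dual-assignment detection loss (one-to-many head
# trained with top-k candidates, one-to-one head with the top candidate).
# ---------------------------------------------------------------------------

#' Training configuration
#'
#' Defaults follow the published recipe: initial learning rate 0.01, batch
#' size 16, momentum 0.937, weight decay 0.0005, 100 epochs, 640 input,
#' cosine-annealing schedule with warm restarts (restart period defaulting to
#' the full budget, i.e. a single cosine cycle) or alternatively an
#' exponential decay with factor `alpha` = 0.95 per epoch.  Pre-trained
#' weights are rejected: every run starts from random initialisation.
#'
#' @param lr0 initial learning rate.
#' @param batch_size images per optimisation step.
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty on convolution kernels.
#' @param epochs training epochs.
#' @param input_size square input resolution.
#' @param scheduler `"cosine"` or `"exp"`.
#' @param alpha per-epoch decay factor of the exponential schedule.
#' @param restart_period cosine warm-restart period in epochs (default: the
#'   full budget).
#' @param lr_min cosine floor.
#' @param topk one-to-many assigner candidates.
#' @param loss_weights named weights of the box/dfl/cls loss components.
#' @param clip_norm optional global gradient-norm guard; Inf (default)
#'   disables it, matching the published recipe (no clipping).
#' @param shuffle reshuffle the training set every epoch (default TRUE).
#'   With FALSE the batch partition is fixed, which makes successive
#'   epoch-mean losses directly comparable (paired measurements) on very
#'   small datasets.
#' @param seed RNG seed for shuffling and augmentation.
#' @param pretrained must be FALSE; any other value is an error.
#' @return a list of class `"TrainConfig"`.
#' @export
trainConfig <- function(lr0 = 0.01, batch_size = 16L, momentum = 0.937,
                        weight_decay = 5e-4, epochs = 100L, input_size = 640L,
                        scheduler = c("cosine", "exp"), alpha = 0.95,
                        restart_period = epochs, lr_min = 1e-4,
                        topk = 10L,
                        loss_weights = c(box = 7.5, dfl = 1.5, cls = 0.5),
                        clip_norm = Inf, shuffle = TRUE, seed = 0L,
                        pretrained = FALSE) {
  if (!identical(pretrained, FALSE))
    stop("pre-trained weights are not supported: training always starts from scratch")
  structure(list(lr0 = lr0, batch_size = as.integer(batch_size),
                 momentum = momentum, weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 input_size = as.integer(input_size),
                 scheduler = match.arg(scheduler), alpha = alpha,
                 restart_period = as.integer(restart_period), lr_min = lr_min,
                 topk = as.integer(topk), loss_weights = loss_weights,
                 clip_norm = clip_norm, shuffle = isTRUE(shuffle),
                 seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Learning rate at a given epoch
#'
#' @param cfg a [trainConfig()].
#' @param epoch 0-based epoch index.
#' @return learning rate.
#' @export
lrAt <- function(cfg, epoch) {
  if (cfg$scheduler == "exp") return(cfg$lr0 * cfg$alpha^epoch)
  tcur <- epoch %% cfg$restart_period
  cfg$lr_min + (cfg$lr0 - cfg$lr_min) * (1 + cos(pi * tcur / cfg$restart_period)) / 2
}

stackBatch <- function(images) {
  d <- dim(images[[1]])
  x <- array(0, dim = c(d[1], d[2], 3, length(images)))
  for (i in seq_along(images)) x[, , , i] <- images[[i]]
  x
}

gradGlobalNorm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
}

# one optimisation step on a batch; returns updated model pieces + losses
trainStep <- function(model, x, targets, cfg, vel) {
  out <- forwardModel(model, x, training = TRUE)
  nc <- model@config@numClasses
  reg_max <- model@config@arch$head$reg_max
  input <- dim(x)[1]
  l_m <- detectionLoss(out$outputs$o2m, targets, nc, reg_max, input,
                       topk = cfg$topk, weights = cfg$loss_weights)
  l_o <- detectionLoss(out$outputs$o2o, targets, nc, reg_max, input,
                       topk = 1L, weights = cfg$loss_weights)
  comps <- c(total = l_m$total + l_o$total, box = l_m$box + l_o$box,
             dfl = l_m$dfl + l_o$dfl, cls = l_m$cls + l_o$cls)
  for (nm in names(comps))
    if (!is.finite(comps[[nm]]))
      stop("non-finite training loss: first non-finite component is '", nm, "'")
  gouts <- list()
  for (set in c("o2m", "o2o")) {
    l <- if (set == "o2m") l_m else l_o
    hs <- model@heads[[set]]
    for (li in seq_along(hs)) {
      gouts[[as.character(hs[[li]]$cls)]] <- l$g_cls[[li]]
      gouts[[as.character(hs[[li]]$box)]] <- l$g_box[[li]]
    }
  }
  grads <- graphBackward(model@nodes, out$fwd, model@params, gouts)
  gn <- gradGlobalNorm(grads)
  if (is.finite(cfg$clip_norm) && gn > cfg$clip_norm)
    grads <- lapply(grads, function(g) g * (cfg$clip_norm / gn))
  st <- sgdStep(model@params, grads, vel, attr(cfg, "lr_now"), cfg$momentum,
                cfg$weight_decay)
  model@params <- st$params
  model@state <- out$state
  list(model = model, vel = st$vel, comps = comps)
}

#' Train a detector
#'
#' Runs SGD over an in-memory dataset (see [loadDataset()] to read one from
#' disk), logging per-epoch loss components and, optionally, validation
#' mAP@0.5.  With a fixed seed the run is deterministic.
#'
#' @param model a `VegModel` built at the training input size.
#' @param data list with `images` (list of (H,W,3) arrays in [0,1]) and
#'   `targets` (list of `list(boxes, cls)` per image, normalized cxcywh).
#' @param cfg a [trainConfig()].
#' @param val optional validation set in the same layout.
#' @param augment optional [augmentConfig()] applied to training images.
#' @param eval_every evaluate on `val` every this many epochs (0 = only at
#'   the end).
#' @param oversample optional per-image sampling weights (minority-class
#'   oversampling); NULL for uniform epochs over the whole set.
#' @param verbose print per-epoch summaries.
#' @return list with the trained `model`, `log` (per-epoch data.frame),
#'   `best` (parameters of the best-mAP epoch, if validated).
#' @export
trainModel <- function(model, data, cfg = trainConfig(), val = NULL,
                       augment = NULL, eval_every = 0L, oversample = NULL,
                       verbose = FALSE) {
  set.seed(cfg$seed)
  n <- length(data$images)
  vel <- sgdInit(model@params)
  log <- list()
  best <- list(map50 = -Inf, params = NULL)
  for (epoch in seq_len(cfg$epochs) - 1L) {
    attr(cfg, "lr_now") <- lrAt(cfg, epoch)
    idx <- if (!is.null(oversample)) sample(n, n, replace = TRUE, prob = oversample)
           else if (cfg$shuffle) sample(n)
           else seq_len(n)
    esum <- c(total = 0, box = 0, dfl = 0, cls = 0); nb <- 0L
    for (b0 in seq(1L, n, by = cfg$batch_size)) {
      bi <- idx[b0:min(b0 + cfg$batch_size - 1L, n)]
      imgs <- data$images[bi]
      tgts <- data$targets[bi]
      if (!is.null(augment)) {
        for (j in seq_along(imgs)) {
          ar <- applyAugment(imgs[[j]], tgts[[j]]$boxes, tgts[[j]]$cls, augment)
          imgs[[j]] <- ar$image
          tgts[[j]] <- list(boxes = ar$boxes, cls = ar$cls)
        }
      }
      x <- stackBatch(imgs)
      st <- trainStep(model, x, tgts, cfg, vel)
      model <- st$model; vel <- st$vel
      esum <- esum + st$comps; nb <- nb + 1L
    }
    esum <- esum / nb
    row <- data.frame(epoch = epoch, lr = attr(cfg, "lr_now"),
                      total = esum[["total"]], box = esum[["box"]],
                      dfl = esum[["dfl"]], cls = esum[["cls"]],
                      map50 = NA_real_)
    do_eval <- !is.null(val) &&
      ((eval_every > 0L && (epoch + 1L) %% eval_every == 0L) ||
         epoch == cfg$epochs - 1L)
    if (do_eval) {
      ev <- evaluateModel(model, val, conf = 0.05)
      row$map50 <- ev@map50
      if (ev@map50 > best$map50) best <- list(map50 = ev@map50, params = model@params)
    }
    log[[epoch + 1L]] <- row
    if (verbose)
      cat(sprintf("epoch %3d lr %.5f loss %.4f (box %.3f dfl %.3f cls %.3f)%s\n",
                  epoch, row$lr, row$total, row$box, row$dfl, row$cls,
                  if (is.na(row$map50)) "" else sprintf(" mAP50 %.1f", row$map50)))
  }
  list(model = model, log = do.call(rbind, log), best = best)
}

#' Evaluate a model on an in-memory dataset
#'
#' @param model a `VegModel`.
#' @param data dataset list (`images`, `targets`, `nc`).
#' @param conf detection confidence threshold.
#' @param batch_size forward batch size.
#' @param iou_thresholds IoU thresholds forwarded to [evaluateDetections()].
#' @return an `EvalReport`.
#' @export
evaluateModel <- function(model, data, conf = 0.25, batch_size = 16L,
                          iou_thresholds = seq(0.5, 0.95, by = 0.05)) {
  n <- length(data$images)
  dets <- list(); gts <- list()
  for (b0 in seq(1L, n, by = batch_size)) {
    bi <- b0:min(b0 + batch_size - 1L, n)
    x <- stackBatch(data$images[bi])
    d <- predictBoxes(model, x, conf = conf)
    if (nrow(d)) { d$image <- bi[d$image]; dets[[length(dets) + 1L]] <- d }
  }
  for (i in seq_len(n)) {
    tg <- data$targets[[i]]
    if (length(tg$cls))
      gts[[length(gts) + 1L]] <- data.frame(image = i, class_id = tg$cls,
                                            cx = tg$boxes[, 1], cy = tg$boxes[, 2],
                                            w = tg$boxes[, 3], h = tg$boxes[, 4])
  }
  det <- if (length(dets)) do.call(rbind, dets) else
    data.frame(image = integer(0), class_id = integer(0), score = numeric(0),
               cx = numeric(0), cy = numeric(0), w = numeric(0), h = numeric(0))
  gt <- if (length(gts)) do.call(rbind, gts) else
    data.frame(image = integer(0), class_id = integer(0), cx = numeric(0),
               cy = numeric(0), w = numeric(0), h = numeric(0))
  evaluateDetections(det, gt, data$nc, iou_thresholds = iou_thresholds,
                     class_names = data$names)
}
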
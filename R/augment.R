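# ---------------------------------------------------------------------------
# Training-time augmentation.  Geometric transforms update boxes through
# exact corner arithmetic; photometric jitter leaves boxes untouched.
# ---------------------------------------------------------------------------

#' Augmentation configuration
#'
#' Defaults follow the study recipe: rotation within +-15 degrees, horizontal
#' and vertical flips, brightness +-25%, contrast +-20%, saturation +-15%,
#' with optional mosaic and mixup composition.
#'
#' @param rotation rotation limit in degrees.
#' @param hflip,vflip enable flips (probability 0.5 each).
#' @param brightness,contrast,saturation jitter half-ranges as fractions.
#' @param mosaic,mixup enable the corresponding batch-composition transforms
#'   (applied by their dedicated functions, not by [applyAugment()]).
#' @param min_area boxes whose clipped area falls below this (normalized)
#'   threshold are dropped and counted.
#' @return a list of class `"AugmentConfig"`.
#' @export
augmentConfig <- function(rotation = 15, hflip = TRUE, vflip = TRUE,
                          brightness = 0.25, contrast = 0.20,
                          saturation = 0.15, mosaic = FALSE, mixup = FALSE,
                          min_area = 1e-5) {
  stopifnot(rotation >= 0, brightness >= 0, contrast >= 0, saturation >= 0)
  structure(list(rotation = rotation, hflip = hflip, vflip = vflip,
                 brightness = brightness, contrast = contrast,
                 saturation = saturation, mosaic = mosaic, mixup = mixup,
                 min_area = min_area),
            class = "AugmentConfig")
}

# nearest-neighbour rotation about the image center (angle in radians);
# out-of-frame samples take the border-clamped pixel
rotateImage <- function(image, angle) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  cx <- W / 2; cy <- H / 2
  xg <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
  yg <- matrix(rep(seq_len(H) - 0.5, times = W), H, W)
  # inverse map
  xs <- cos(-angle) * (xg - cx) - sin(-angle) * (yg - cy) + cx
  ys <- sin(-angle) * (xg - cx) + cos(-angle) * (yg - cy) + cy
  xi <- pmin(pmax(ceiling(xs), 1L), W)
  yi <- pmin(pmax(ceiling(ys), 1L), H)
  idx <- cbind(as.vector(yi), as.vector(xi))
  out <- image
  for (ch in 1:3)
    out[, , ch] <- matrix(image[, , ch][idx], H, W)
  out
}

rotateBoxes <- function(boxes, angle) {
  # boxes normalized cxcywh; rotate the 4 corners about (0.5, 0.5) and take
  # the axis-aligned hull
  if (is.null(boxes) || !nrow(boxes)) return(boxes)
  out <- boxes
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    xs <- b[1] + c(-1, 1, 1, -1) * b[3] / 2 - 0.5
    ys <- b[2] + c(-1, -1, 1, 1) * b[4] / 2 - 0.5
    xr <- cos(angle) * xs - sin(angle) * ys + 0.5
    yr <- sin(angle) * xs + cos(angle) * ys + 0.5
    out[i, ] <- c((min(xr) + max(xr)) / 2, (min(yr) + max(yr)) / 2,
                  max(xr) - min(xr), max(yr) - min(yr))
  }
  out
}

clipBoxes <- function(boxes, cls, min_area) {
  if (is.null(boxes) || !nrow(boxes))
    return(list(boxes = boxes, cls = cls, dropped = 0L))
  xy <- cxcywhToXyxy(boxes)
  xy <- pmin(pmax(xy, 0), 1)
  cw <- xyxyToCxcywh(xy)
  ok <- cw[, 3] * cw[, 4] >= min_area
  list(boxes = cw[ok, , drop = FALSE], cls = cls[ok],
       dropped = sum(!ok))
}

#' Apply per-image augmentation
#'
#' Flips and rotation transform the boxes consistently (horizontal flip maps
#' cx to 1-cx; rotated boxes are recomputed from their transformed corners
#' and clipped); photometric jitter leaves boxes unchanged.  Degenerate boxes
#' after clipping are dropped and reported in the `dropped` count.
#'
#' @param image (H,W,3) array in [0,1].
#' @param boxes normalized cxcywh matrix (or NULL).
#' @param cls 0-based class vector.
#' @param cfg an [augmentConfig()].
#' @return list(image, boxes, cls, dropped).
#' @export
applyAugment <- function(image, boxes, cls, cfg) {
  dropped <- 0L
  if (cfg$hflip && stats::runif(1) < 0.5) {
    image <- image[, dim(image)[2]:1, , drop = FALSE]
    if (!is.null(boxes) && nrow(boxes)) boxes[, 1] <- 1 - boxes[, 1]
  }
  if (cfg$vflip && stats::runif(1) < 0.5) {
    image <- image[dim(image)[1]:1, , , drop = FALSE]
    if (!is.null(boxes) && nrow(boxes)) boxes[, 2] <- 1 - boxes[, 2]
  }
  if (cfg$rotation > 0) {
    ang <- stats::runif(1, -cfg$rotation, cfg$rotation) * pi / 180
    image <- rotateImage(image, ang)
    boxes <- rotateBoxes(boxes, ang)
  }
  if (cfg$brightness > 0)
    image <- image * (1 + stats::runif(1, -cfg$brightness, cfg$brightness))
  if (cfg$contrast > 0) {
    m <- mean(image)
    image <- (image - m) * (1 + stats::runif(1, -cfg$contrast, cfg$contrast)) + m
  }
  if (cfg$saturation > 0) {
    g <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
    f <- 1 + stats::runif(1, -cfg$saturation, cfg$saturation)
    for (ch in 1:3) image[, , ch] <- g + (image[, , ch] - g) * f
  }
  image <- pmin(pmax(image, 0), 1)
  cb <- clipBoxes(boxes, cls, cfg$min_area)
  list(image = image, boxes = cb$boxes, cls = cb$cls,
       dropped = dropped + cb$dropped)
}

#' Mosaic composition of four images
#'
#' Places the four images on a double-size canvas (2x2 grid), remaps all
#' boxes, then rescales the canvas back to the training size by 2x2
#' averaging.
#'
#' @param items list of four list(image, boxes, cls); images must share one
#'   square size.
#' @param min_area degenerate-box threshold after remapping.
#' @return list(image, boxes, cls, dropped).
#' @export
mosaicCompose <- function(items, min_area = 1e-5) {
  stopifnot(length(items) == 4L)
  S <- dim(items[[1]]$image)[1]
  canvas <- array(0, c(2 * S, 2 * S, 3))
  boxes <- NULL; cls <- integer(0)
  offs <- list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))  # (row block, col block)
  for (i in 1:4) {
    o <- offs[[i]]
    canvas[o[1] * S + 1:S, o[2] * S + 1:S, ] <- items[[i]]$image
    b <- items[[i]]$boxes
    if (!is.null(b) && nrow(b)) {
      b2 <- b
      b2[, 1] <- (b[, 1] + o[2]) / 2
      b2[, 2] <- (b[, 2] + o[1]) / 2
      b2[, 3] <- b[, 3] / 2
      b2[, 4] <- b[, 4] / 2
      boxes <- rbind(boxes, b2)
      cls <- c(cls, items[[i]]$cls)
    }
  }
  # 2x2 average downsample back to S
  small <- array(0, c(S, S, 3))
  for (ch in 1:3) {
    m <- canvas[, , ch]
    small[, , ch] <- (m[seq(1, 2 * S, 2), seq(1, 2 * S, 2)] +
                        m[seq(2, 2 * S, 2), seq(1, 2 * S, 2)] +
                        m[seq(1, 2 * S, 2), seq(2, 2 * S, 2)] +
                        m[seq(2, 2 * S, 2), seq(2, 2 * S, 2)]) / 4
  }
  cb <- clipBoxes(boxes, cls, min_area)
  list(image = small, boxes = cb$boxes, cls = cb$cls, dropped = cb$dropped)
}

#' Mixup of two images
#'
#' Convex blend lambda*A + (1-lambda)*B with the union of the two box lists.
#'
#' @param a,b list(image, boxes, cls).
#' @param lambda blend weight in [0,1]; NULL draws from Beta(8, 8).
#' @return list(image, boxes, cls).
#' @export
mixupCompose <- function(a, b, lambda = NULL) {
  if (is.null(lambda)) lambda <- stats::rbeta(1, 8, 8)
  img <- lambda * a$image + (1 - lambda) * b$image
  list(image = img,
       boxes = rbind(a$boxes, b$boxes),
       cls = c(a$cls, b$cls))
}
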
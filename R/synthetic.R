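# ---------------------------------------------------------------------------
# Synthetic greenhouse scenes.
#
# The generator emulates the statistical structure of greenhouse disease
# imagery rather than its photographic appearance: overlapping elliptical
# leaves (occlusion), small circular lesions down to a few pixels, a smooth
# illumination gradient with specular highlight spots (glass/film covers),
# and Gaussian plus salt-and-pepper sensor noise.  Images are (H, W, 3)
# arrays in [0, 1]; every function is deterministic given its spec/seed.
# ---------------------------------------------------------------------------

#' Default class names
#'
#' Fifteen classes: three crops (tomato, cucumber, pepper), each with a
#' healthy condition and four diseases.
#'
#' @return character vector of 15 class names.
#' @export
defaultClassNames <- function() {
  paste0(rep(c("A", "B", "C"), each = 5), 1:5)
}

cropPalette <- function(crop) {
  # leaf base colours per crop (RGB in [0,1])
  switch(crop,
         c(0.18, 0.42, 0.12),   # tomato: mid green
         c(0.22, 0.50, 0.18),   # cucumber: brighter green
         c(0.15, 0.38, 0.16))   # pepper: dark green
}

lesionPalette <- function(condition) {
  # condition 2..5 are diseases; colour signatures differ per condition
  switch(condition - 1L,
         c(0.45, 0.33, 0.12),   # grey-brown mold
         c(0.55, 0.48, 0.20),   # yellowish leaf spot
         c(0.20, 0.14, 0.08),   # dark black spot
         c(0.50, 0.44, 0.38))   # pale powdery patch
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Random scene specification
#'
#' Draws a generative description of one image: leaves, lesions, illumination
#' field and noise settings.  The image's primary class fixes the crop and,
#' for disease classes, guarantees at least one lesion of that class.
#'
#' @param class_id primary class, 0-based (crop = class_id %/% 5, condition =
#'   class_id %% 5 with 0 = healthy).
#' @param size image side in pixels.
#' @param seed integer seed; the spec and the rendered scene are functions of
#'   it.
#' @param n_leaves leaf count range.
#' @param lesions_per_leaf lesion count range for diseased leaves.
#' @param lesion_radius lesion radius range in pixels (log-uniform draw).
#' @param small_fraction fraction of lesions forced below 10 px radius.
#' @param gaussian_sigma Gaussian noise level as a fraction of the dynamic
#'   range (the study range is [0.1, 0.3]).
#' @param salt_pepper salt-and-pepper corruption density.
#' @param illumination_strength planar gradient strength (0 disables).
#' @return a list of class `"SceneSpec"`.
#' @export
randomSceneSpec <- function(class_id, size = 640L, seed = 1L,
                            n_leaves = c(3L, 6L),
                            lesions_per_leaf = c(2L, 6L),
                            lesion_radius = c(3, 18),
                            small_fraction = 0.5,
                            gaussian_sigma = 0.15,
                            salt_pepper = 0.002,
                            illumination_strength = 0.25) {
  stopifnot(class_id >= 0, class_id < 15)
  crop <- class_id %/% 5L + 1L
  condition <- class_id %% 5L + 1L       # 1 = healthy
  withSeed(seed, {
    nl <- sample(n_leaves[1]:n_leaves[2], 1)
    leaves <- lapply(seq_len(nl), function(i) {
      ax <- stats::runif(1, 0.14, 0.30) * size
      list(center = stats::runif(2, 0.2, 0.8) * size,
           axes = c(ax, ax * stats::runif(1, 0.45, 0.8)),
           rotation = stats::runif(1, 0, pi),
           color = pmin(pmax(cropPalette(crop) +
                               stats::rnorm(3, 0, 0.03), 0), 1))
    })
    lesions <- list()
    if (condition > 1L) {
      # diseased leaves: the first leaf always carries the primary disease
      diseased <- unique(c(1L, which(stats::runif(nl) < 0.5)))
      for (li in diseased) {
        lf <- leaves[[li]]
        k <- sample(lesions_per_leaf[1]:lesions_per_leaf[2], 1)
        for (j in seq_len(k)) {
          r <- if (stats::runif(1) < small_fraction)
            exp(stats::runif(1, log(lesion_radius[1]), log(min(9, lesion_radius[2]))))
          else
            exp(stats::runif(1, log(lesion_radius[1]), log(lesion_radius[2])))
          # position inside the leaf ellipse (in its rotated frame)
          repeat {
            uv <- stats::runif(2, -0.75, 0.75)
            if (sum(uv^2) <= 0.56) break
          }
          th <- lf$rotation
          off <- c(cos(th) * uv[1] * lf$axes[1] - sin(th) * uv[2] * lf$axes[2],
                   sin(th) * uv[1] * lf$axes[1] + cos(th) * uv[2] * lf$axes[2])
          lesions[[length(lesions) + 1L]] <-
            list(leaf = li, class_id = (crop - 1L) * 5L + (condition - 1L),
                 center = lf$center + off, radius = r,
                 color = pmin(pmax(lesionPalette(condition) +
                                     stats::rnorm(3, 0, 0.02), 0), 1))
        }
      }
    }
    spec <- list(size = as.integer(size), crop = crop, condition = condition,
                 leaves = leaves, lesions = lesions,
                 illumination = list(
                   direction = stats::runif(1, 0, 2 * pi),
                   strength = illumination_strength,
                   spots = if (illumination_strength > 0)
                     lapply(seq_len(sample(0:2, 1)), function(i)
                       list(center = stats::runif(2, 0.1, 0.9) * size,
                            radius = stats::runif(1, 0.08, 0.2) * size,
                            gain = stats::runif(1, 0.15, 0.35)))
                   else list()),
                 noise = list(gaussian_sigma = gaussian_sigma,
                              salt_pepper = salt_pepper),
                 seed = as.integer(seed))
    class(spec) <- "SceneSpec"
    spec
  })
}

validateSceneSpec <- function(spec) {
  for (ls in spec$lesions) {
    lf <- spec$leaves[[ls$leaf]]
    d <- ls$center - lf$center
    th <- -lf$rotation
    u <- c(cos(th) * d[1] - sin(th) * d[2], sin(th) * d[1] + cos(th) * d[2])
    if (sum((u / lf$axes)^2) > 1)
      stop("scene spec: lesion center outside its parent leaf's mask")
  }
  invisible(TRUE)
}

leafMask <- function(xg, yg, lf) {
  dx <- xg - lf$center[1]; dy <- yg - lf$center[2]
  th <- -lf$rotation
  u <- cos(th) * dx - sin(th) * dy
  v <- sin(th) * dx + cos(th) * dy
  (u / lf$axes[1])^2 + (v / lf$axes[2])^2 <= 1
}

#' Render a scene
#'
#' Deterministic function of the spec: the same spec yields byte-identical
#' images and identical box lists.  Ground truth is one box per lesion
#' (disease classes) and one box per lesion-free leaf (the crop's healthy
#' class), all clipped to the image.
#'
#' @param spec a [randomSceneSpec()].
#' @return list with `image` ((H,W,3) array in [0,1]), `boxes` (normalized
#'   cxcywh matrix) and `cls` (0-based integer classes).
#' @export
generateScene <- function(spec) {
  validateSceneSpec(spec)
  S <- spec$size
  xg <- matrix(rep(seq_len(S) - 0.5, each = S), S, S)   # x per column
  yg <- matrix(rep(seq_len(S) - 0.5, times = S), S, S)  # y per row
  img <- withSeed(spec$seed + 1L, {
    # soil background: brown gradient with mild texture
    base <- c(0.32, 0.26, 0.20)
    tex <- matrix(stats::runif(S * S, -0.03, 0.03), S, S)
    im <- array(0, c(S, S, 3))
    grad <- 0.08 * (yg / S - 0.5)
    for (ch in 1:3) im[, , ch] <- base[ch] + grad + tex
    im
  })
  # paint leaves in order; later leaves occlude earlier ones
  top <- matrix(0L, S, S)
  for (li in seq_along(spec$leaves)) {
    lf <- spec$leaves[[li]]
    m <- leafMask(xg, yg, lf)
    top[m] <- li
    # vein-like radial shading
    dx <- xg - lf$center[1]; dy <- yg - lf$center[2]
    shade <- 1 - 0.25 * sqrt((dx / lf$axes[1])^2 + (dy / lf$axes[1])^2)
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[m] <- lf$color[ch] * shade[m]
      img[, , ch] <- pl
    }
  }
  # lesions: visible only where the parent leaf is on top
  for (ls in spec$lesions) {
    d2 <- (xg - ls$center[1])^2 + (yg - ls$center[2])^2
    m <- d2 <= ls$radius^2 & top == ls$leaf
    if (!any(m)) next
    ring <- d2[m] / ls$radius^2
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[m] <- ls$color[ch] * (0.75 + 0.4 * ring)
      img[, , ch] <- pl
    }
  }
  img <- pmin(pmax(img, 0), 1)
  img <- applyIllumination(img, spec$illumination)
  img <- addGaussianNoise(img, spec$noise$gaussian_sigma, spec$seed + 2L)
  img <- addSaltPepper(img, spec$noise$salt_pepper, spec$seed + 3L)
  # ground-truth boxes
  boxes <- NULL; cls <- integer(0)
  lesioned <- unique(vapply(spec$lesions, function(l) l$leaf, integer(1)))
  for (ls in spec$lesions) {
    x1 <- max(ls$center[1] - ls$radius, 0); x2 <- min(ls$center[1] + ls$radius, S)
    y1 <- max(ls$center[2] - ls$radius, 0); y2 <- min(ls$center[2] + ls$radius, S)
    if (x2 <= x1 || y2 <= y1) next
    boxes <- rbind(boxes, c((x1 + x2) / 2, (y1 + y2) / 2, x2 - x1, y2 - y1) / S)
    cls <- c(cls, ls$class_id)
  }
  healthy_class <- (spec$crop - 1L) * 5L
  for (li in setdiff(seq_along(spec$leaves), lesioned)) {
    lf <- spec$leaves[[li]]
    # bounding box of the rotated ellipse
    th <- lf$rotation
    ex <- sqrt((lf$axes[1] * cos(th))^2 + (lf$axes[2] * sin(th))^2)
    ey <- sqrt((lf$axes[1] * sin(th))^2 + (lf$axes[2] * cos(th))^2)
    x1 <- max(lf$center[1] - ex, 0); x2 <- min(lf$center[1] + ex, S)
    y1 <- max(lf$center[2] - ey, 0); y2 <- min(lf$center[2] + ey, S)
    if (x2 - x1 < 2 || y2 - y1 < 2) next
    boxes <- rbind(boxes, c((x1 + x2) / 2, (y1 + y2) / 2, x2 - x1, y2 - y1) / S)
    cls <- c(cls, healthy_class)
  }
  list(image = img, boxes = boxes, cls = cls)
}

#' Apply an illumination field
#'
#' Multiplies the image by a smooth planar gradient plus Gaussian highlight
#' spots; strength 0 is the identity.  Output is clipped to [0, 1].
#'
#' @param image (H,W,3) array in [0,1].
#' @param illum list with `direction` (radians), `strength` (>= 0) and
#'   `spots` (list of center/radius/gain).
#' @return the shaded image.
#' @export
applyIllumination <- function(image, illum) {
  if (illum$strength == 0 && !length(illum$spots)) return(image)
  d <- dim(image)
  S1 <- d[1]; S2 <- d[2]
  xg <- matrix(rep(seq_len(S2) - 0.5, each = S1), S1, S2)
  yg <- matrix(rep(seq_len(S1) - 0.5, times = S2), S1, S2)
  proj <- (cos(illum$direction) * (xg / S2 - 0.5) +
             sin(illum$direction) * (yg / S1 - 0.5))
  field <- 1 + illum$strength * 2 * proj
  for (sp in illum$spots) {
    d2 <- (xg - sp$center[1])^2 + (yg - sp$center[2])^2
    field <- field + sp$gain * exp(-d2 / (2 * sp$radius^2))
  }
  out <- image
  for (ch in 1:3) out[, , ch] <- image[, , ch] * field
  pmin(pmax(out, 0), 1)
}

#' Add Gaussian sensor noise
#'
#' Adds zero-mean Gaussian noise with standard deviation `sigma` times the
#' dynamic range (images live in [0,1], so range 1), then clips.
#'
#' @param image (H,W,3) array.
#' @param sigma noise level as a fraction of the dynamic range.
#' @param seed RNG seed.
#' @return the noisy image.
#' @export
addGaussianNoise <- function(image, sigma, seed = 0L) {
  if (sigma <= 0) return(image)
  withSeed(seed, {
    pmin(pmax(image + array(stats::rnorm(length(image), 0, sigma), dim(image)),
              0), 1)
  })
}

#' Add salt-and-pepper noise
#'
#' Sets approximately `density` of the pixels to pure black or pure white
#' (equal probability); all three channels of a hit pixel are set.
#'
#' @param image (H,W,3) array.
#' @param density corrupted-pixel fraction in [0,1].
#' @param seed RNG seed.
#' @return the corrupted image.
#' @export
addSaltPepper <- function(image, density, seed = 0L) {
  if (density <= 0) return(image)
  stopifnot(density <= 1)
  d <- dim(image)
  withSeed(seed, {
    hit <- stats::runif(d[1] * d[2]) < density
    val <- stats::rbinom(sum(hit), 1, 0.5)
    out <- image
    for (ch in 1:3) {
      pl <- out[, , ch]
      pl[hit] <- val
      out[, , ch] <- pl
    }
    out
  })
}
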
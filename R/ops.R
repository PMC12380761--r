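#' @useDynLib vegyolo, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

# ---------------------------------------------------------------------------
# Feature maps.
#
# A feature map is a numeric array with dim = c(H, W, C, N): rows, columns,
# channels, batch.  R is column-major, so one channel plane of one sample is
# contiguous in memory; this is the layout the compiled kernels assume.
# Shape queries report the conventional (batch, channel, row, col) order.
# ---------------------------------------------------------------------------

#' Construct a feature map array
#'
#' Builds the 4-axis activation array used throughout the package from values
#' given in (batch, channel, row, col) order.
#'
#' @param values numeric vector, recycled, laid out with column index fastest,
#'   then row, then channel, then batch (i.e. row-major per channel plane, the
#'   order in which one would write a matrix literal row by row).
#' @param n,c,h,w batch size, channels, rows, columns.
#' @return numeric array with `dim = c(h, w, c, n)`.
#' @export
featureMap <- function(values, n, c, h, w) {
  stopifnot(n >= 1, c >= 1, h >= 1, w >= 1)
  a <- array(as.double(values), dim = c(w, h, c, n))  # col fastest as supplied
  aperm(a, c(2, 1, 3, 4))
}

#' Shape of a feature map
#'
#' @param x feature map array.
#' @return named integer vector `c(n, c, h, w)`.
#' @export
fmShape <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  c(n = d[4], c = d[3], h = d[1], w = d[2])
}

#' Random feature map (standard normal entries)
#' @param n,c,h,w shape in (batch, channel, row, col) order.
#' @return feature map array.
#' @export
fmRandom <- function(n, c, h, w) {
  array(stats::rnorm(n * c * h * w), dim = c(h, w, c, n))
}

sigmoidv <- function(x) 1 / (1 + exp(-x))
siluv <- function(x) x / (1 + exp(-x))

# ---------------------------------------------------------------------------
# Space-to-depth and channel shuffle (pure rearrangements)
# ---------------------------------------------------------------------------

#' Space-to-depth rearrangement
#'
#' Moves each `scale` x `scale` spatial block into the channel axis: the
#' output is the channel-wise concatenation of the sub-grids
#' f(h,w) = x[h::scale, w::scale] taken row-major over the (h, w) offsets, so
#' for `scale = 2` the channel blocks are f(0,0), f(0,1), f(1,0), f(1,1).
#' The operation is a pure permutation: every input value appears exactly once
#' in the output.
#'
#' @param x feature map, spatial dims divisible by `scale`.
#' @param scale integer slicing stride (>= 1).
#' @return feature map of shape (N, scale^2 C, H/scale, W/scale).
#' @seealso [depthToSpace()] for the exact inverse.
#' @export
spaceToDepth <- function(x, scale) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  scale <- as.integer(scale)
  if (H %% scale != 0L)
    stop("spaceToDepth: row dimension ", H, " not divisible by scale ", scale)
  if (W %% scale != 0L)
    stop("spaceToDepth: column dimension ", W, " not divisible by scale ", scale)
  Ho <- H %/% scale; Wo <- W %/% scale
  out <- array(0, dim = c(Ho, Wo, scale * scale * C, N))
  blk <- 0L
  for (hoff in seq_len(scale) - 1L) {
    for (woff in seq_len(scale) - 1L) {
      out[, , blk * C + seq_len(C), ] <-
        x[seq(1L + hoff, H, by = scale), seq(1L + woff, W, by = scale), , , drop = FALSE]
      blk <- blk + 1L
    }
  }
  out
}

#' Inverse of space-to-depth
#' @param x feature map with scale^2 * C channels.
#' @param scale integer stride used in the forward rearrangement.
#' @return feature map of shape (N, C, H*scale, W*scale).
#' @export
depthToSpace <- function(x, scale) {
  d <- dim(x)
  Ho <- d[1]; Wo <- d[2]; C2 <- d[3]; N <- d[4]
  scale <- as.integer(scale)
  stopifnot(C2 %% (scale * scale) == 0L)
  C <- C2 %/% (scale * scale)
  out <- array(0, dim = c(Ho * scale, Wo * scale, C, N))
  blk <- 0L
  for (hoff in seq_len(scale) - 1L) {
    for (woff in seq_len(scale) - 1L) {
      out[seq(1L + hoff, Ho * scale, by = scale),
          seq(1L + woff, Wo * scale, by = scale), , ] <-
        x[, , blk * C + seq_len(C), , drop = FALSE]
      blk <- blk + 1L
    }
  }
  out
}

#' Channel shuffle
#'
#' Reindexes channels by the reshape-(groups, C/groups)-transpose-flatten
#' permutation used after group convolutions to mix information between
#' groups; spatial values are untouched.
#'
#' @param x feature map with channel count divisible by `groups`.
#' @param groups number of groups.
#' @return feature map of the same shape with channels permuted.
#' @export
channelShuffle <- function(x, groups) {
  C <- dim(x)[3]
  x[, , shufflePerm(C, groups), , drop = FALSE]
}

shufflePerm <- function(C, groups) {
  groups <- as.integer(groups)
  if (C %% groups != 0L)
    stop("channelShuffle: ", C, " channels not divisible by ", groups, " groups")
  as.vector(matrix(seq_len(C), nrow = groups, byrow = TRUE))
}

catChannels <- function(xs) {
  d <- dim(xs[[1]])
  cs <- vapply(xs, function(x) dim(x)[3], integer(1))
  out <- array(0, dim = c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (i in seq_along(xs)) {
    out[, , at + seq_len(cs[i]), ] <- xs[[i]]
    at <- at + cs[i]
  }
  out
}

# Global average pooling over the spatial axes: (H,W,C,N) -> (1,1,C,N)
gapSpatial <- function(x) {
  d <- dim(x)
  m <- colMeans(matrix(x, nrow = d[1] * d[2]))
  array(m, dim = c(1, 1, d[3], d[4]))
}

# Broadcast a per-channel vector map (1,1,C,N) over H x W
bcastChan <- function(v, H, W) {
  d <- dim(v)
  array(rep(as.vector(v), each = H * W), dim = c(H, W, d[3], d[4]))
}

# Broadcast a single-channel spatial map (H,W,1,N) over C channels
bcastSpat <- function(s, C) {
  s[, , rep(1L, C), , drop = FALSE]
}
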
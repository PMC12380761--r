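# ---------------------------------------------------------------------------
# Network building blocks, expressed as graph fragments.
#
# Every convolution is followed by batch normalisation and SiLU unless noted;
# the attention-gate convolutions (the squeeze/excite pair, the spatial 7x7
# and the final sigmoid gate) are plain biased convolutions, since the gate
# equations specify only ReLU and sigmoid.
# ---------------------------------------------------------------------------

#' ADEConv block configuration
#'
#' Settings for the detail-preserving downsampling block: a space-to-depth
#' rearrangement followed by a non-strided ghost convolution.
#'
#' @param in_channels,out_channels input/output channel counts; `out_channels`
#'   must be even (the ghost block builds it from two halves).
#' @param scale slicing stride of the space-to-depth step (>= 2 for
#'   downsampling use).
#' @param cheap_kernel odd kernel size of the cheap (group) branch.
#' @param cheap_groups group count of the cheap branch.
#' @return a list of class `"ADEConvConfig"`.
#' @export
adeConvConfig <- function(in_channels, out_channels, scale = 2L,
                          cheap_kernel = 5L, cheap_groups = 2L) {
  stopifnot(in_channels >= 1, out_channels >= 1, scale >= 1,
            cheap_kernel %% 2 == 1)
  if (out_channels %% 2L != 0L)
    stop("ADEConv: out_channels must be even, got ", out_channels)
  if ((out_channels %/% 2L) %% cheap_groups != 0L)
    stop("ADEConv: out_channels/2 must be divisible by cheap_groups")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 scale = as.integer(scale),
                 cheap_kernel = as.integer(cheap_kernel),
                 cheap_groups = as.integer(cheap_groups)),
            class = "ADEConvConfig")
}

#' AAFS gate configuration
#'
#' Settings for the attention-guided adaptive feature selection gate that
#' combines a squeeze-excitation channel path with a channel-pooled spatial
#' path into a sigmoid fusion weight.
#'
#' @param channels gated channel count C.
#' @param reduction channel reduction ratio r of the squeeze path (C divisible
#'   by r); default 4.
#' @param gate_kernel odd kernel size of the final gate group convolution.
#' @param gate_groups group count of the gate convolution (2C -> C).
#' @param shuffle_groups channel-shuffle groups applied before the gate.
#' @param spatial_channels output channels of the spatial-attention
#'   convolution; 1 (broadcast, default) or `channels`.
#' @return a list of class `"AAFSConfig"`.
#' @export
aafsConfig <- function(channels, reduction = 4L, gate_kernel = 7L,
                       gate_groups = 2L, shuffle_groups = 2L,
                       spatial_channels = 1L) {
  stopifnot(channels >= 1, gate_kernel %% 2 == 1)
  if (channels %% reduction != 0L)
    stop("AAFS: channels must be divisible by reduction ratio")
  if ((2L * channels) %% shuffle_groups != 0L)
    stop("AAFS: 2*channels must be divisible by shuffle_groups")
  if ((2L * channels) %% gate_groups != 0L || channels %% gate_groups != 0L)
    stop("AAFS: gate_groups must divide both 2*channels and channels")
  if (!spatial_channels %in% c(1L, channels))
    stop("AAFS: spatial_channels must be 1 or channels")
  structure(list(channels = as.integer(channels),
                 reduction = as.integer(reduction),
                 gate_kernel = as.integer(gate_kernel),
                 gate_groups = as.integer(gate_groups),
                 shuffle_groups = as.integer(shuffle_groups),
                 spatial_channels = as.integer(spatial_channels)),
            class = "AAFSConfig")
}

# --- graph fragments -------------------------------------------------------

# Non-strided ghost block: primary 1x1 to C2/2, cheap kxk group conv on it,
# output = Concat[cheap(primary) : primary].  The primary projection is
# computed once and reused by both halves.
bGhost <- function(gb, x, cfg) {
  primary <- gConv(gb, x, cfg$out_channels %/% 2L, k = 1L)
  cheap <- gConv(gb, primary, cfg$out_channels %/% 2L, k = cfg$cheap_kernel,
                 groups = cfg$cheap_groups)
  gConcat(gb, c(cheap, primary))
}

# ADEConv: space-to-depth then ghost block; contains no strided convolution.
bADEConv <- function(gb, x, cfg) {
  spd <- gSPD(gb, x, cfg$scale)
  bGhost(gb, spd, cfg)
}

# AAFS: returns list(gate = sigmoid weight node, out = gated feature node).
bAAFS <- function(gb, x, cfg) {
  C <- cfg$channels
  # channel path: GAP -> 1x1 (C/r, ReLU) -> 1x1 (C)
  gap <- gGAP(gb, x)
  sq <- gConv(gb, gap, C %/% cfg$reduction, k = 1L, bn = FALSE, act = "relu",
              bias = TRUE)
  wc <- gConv(gb, sq, C, k = 1L, bn = FALSE, act = "none", bias = TRUE)
  # spatial path: [channel mean, channel max] -> 7x7 conv
  cp <- gChanPool(gb, x)
  ws <- gConv(gb, cp, cfg$spatial_channels, k = 7L, bn = FALSE, act = "none",
              bias = TRUE)
  merged <- if (cfg$spatial_channels == 1L) {
    gBSum(gb, wc, ws)                 # broadcast both paths to (H,W,C)
  } else {
    gNode(gb, "baddchan", c(ws, wc))  # C-channel spatial map + channel vector
  }
  cat2 <- gConcat(gb, c(x, merged))
  sh <- gShuffle(gb, cat2, cfg$shuffle_groups)
  # gate bias starts positive so freshly initialised gates are nearly open
  # (sigmoid(2) ~ 0.88) and features pass through the fusion stack early in
  # training; the content-dependent part is learned on top
  gate <- gConv(gb, sh, C, k = cfg$gate_kernel, groups = cfg$gate_groups,
                bn = FALSE, act = "sigmoid", bias = TRUE, bias_init = 2)
  list(gate = gate, out = gMul(gb, gate, x))
}

# Residual bottleneck on c channels (two 3x3 convs).
bBottleneck <- function(gb, x, c, shortcut = TRUE) {
  y <- gConv(gb, x, c, k = 3L)
  y <- gConv(gb, y, c, k = 3L)
  if (shortcut) gAdd(gb, c(x, y)) else y
}

# Split-transform-merge stage block (cross-stage partial style): 1x1 in,
# split halves, n residual bottlenecks on one half, concat all, 1x1 out.
bC2f <- function(gb, x, cout, n = 1L, shortcut = TRUE) {
  half <- cout %/% 2L
  cv1 <- gConv(gb, x, cout, k = 1L)
  a <- gChSlice(gb, cv1, 1L, half)
  b <- gChSlice(gb, cv1, half + 1L, cout)
  ys <- c(a, b)
  cur <- b
  for (i in seq_len(n)) {
    cur <- bBottleneck(gb, cur, half, shortcut)
    ys <- c(ys, cur)
  }
  gConv(gb, gConcat(gb, ys), cout, k = 1L)
}

# Spatial pyramid pooling (fast variant): 1x1 down, three chained 5x5 max
# pools, concat, 1x1 out.
bSPPF <- function(gb, x, c) {
  half <- c %/% 2L
  cv1 <- gConv(gb, x, half, k = 1L)
  p1 <- gMaxPool(gb, cv1, 5L)
  p2 <- gMaxPool(gb, p1, 5L)
  p3 <- gMaxPool(gb, p2, 5L)
  gConv(gb, gConcat(gb, c(cv1, p1, p2, p3)), c, k = 1L)
}

# Baseline downsampling: either a strided 3x3 conv or the pointwise +
# strided-depthwise pair used at the deeper stages.
bDownStd <- function(gb, x, cout, scdown = FALSE) {
  if (scdown) {
    pw <- gConv(gb, x, cout, k = 1L)
    gConv(gb, pw, cout, k = 3L, stride = 2L, groups = cout, act = "none")
  } else {
    gConv(gb, x, cout, k = 3L, stride = 2L)
  }
}

# Depthwise-separable 3x3 block (dw then pw), used by the fusion-node convs.
bDWSep <- function(gb, x, c) {
  dw <- gConv(gb, x, c, k = 3L, groups = c, act = "none")
  gConv(gb, dw, c, k = 1L)
}

# --- standalone block modules (for direct use and unit testing) -------------

#' Build a standalone block module
#'
#' Wraps a single block (ADEConv, ghost, AAFS gate, ...) as a runnable module
#' with freshly initialised weights, for inspection and unit-level use.
#'
#' @param kind one of `"adeconv"`, `"ghost"`, `"spd"`, `"aafs"`,
#'   `"aafs_channel"`, `"aafs_spatial"`, `"aafs_gate"`.
#' @param cfg an [adeConvConfig()] or [aafsConfig()] as appropriate.
#' @param in_channels input channel count (defaults to the config's).
#' @return a list with elements `nodes`, `params`, `state`, `out`
#'   (output node id) and optionally `gate`.
#' @export
blockModule <- function(kind, cfg, in_channels = NULL) {
  gb <- newGraphBuilder()
  inc <- switch(kind,
    adeconv = cfg$in_channels,
    spd = if (is.null(in_channels)) cfg$in_channels else in_channels,
    ghost = cfg$in_channels * cfg$scale^2,
    aafs = ,
    aafs_channel = ,
    aafs_spatial = ,
    aafs_gate = cfg$channels)
  x <- gInput(gb, inc)
  gate <- NULL
  out <- switch(kind,
    adeconv = bADEConv(gb, x, cfg),
    spd = gSPD(gb, x, cfg$scale),
    ghost = bGhost(gb, x, cfg),
    aafs = { r <- bAAFS(gb, x, cfg); gate <- r$gate; r$out },
    aafs_gate = { r <- bAAFS(gb, x, cfg); gate <- r$gate; r$gate },
    aafs_channel = {
      gap <- gGAP(gb, x)
      sq <- gConv(gb, gap, cfg$channels %/% cfg$reduction, k = 1L, bn = FALSE,
                  act = "relu", bias = TRUE)
      gConv(gb, sq, cfg$channels, k = 1L, bn = FALSE, act = "none", bias = TRUE)
    },
    aafs_spatial = {
      cp <- gChanPool(gb, x)
      gConv(gb, cp, cfg$spatial_channels, k = 7L, bn = FALSE, act = "none",
            bias = TRUE)
    })
  nodes <- finalizeGraph(gb$nodes)
  ini <- initGraphParams(nodes)
  list(nodes = nodes, params = ini$params, state = ini$state,
       input = x, out = out, gate = gate)
}

#' Run a block module forward
#'
#' @param mod a module from [blockModule()].
#' @param x input feature map of matching channel count.
#' @param training logical; use batch statistics (TRUE) or running moments.
#' @param node which node's activation to return (default the module output).
#' @return the requested activation.
#' @export
moduleForward <- function(mod, x, training = TRUE, node = mod$out) {
  fwd <- graphForward(mod$nodes, x, mod$params, mod$state, training = training)
  fwd$acts[[node]]
}
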
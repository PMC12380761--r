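# ---------------------------------------------------------------------------
# Structural audits: trainable parameters and analytic FLOPs.
#
# FLOPs convention: one multiply-accumulate = 2 FLOPs, batch 1, counted for
# convolutions only (normalisation, activations, pooling and resampling are
# excluded), at the configured input resolution.
# ---------------------------------------------------------------------------

paramCountNode <- function(nd) {
  if (nd$op != "conv") return(0)
  a <- nd$attrs
  cing <- nd$cin %/% a$groups
  n <- a$k * a$k * cing * a$cout
  if (isTRUE(a$bias)) n <- n + a$cout
  if (isTRUE(a$bn)) n <- n + 2L * a$cout
  n
}

#' Count trainable parameters
#'
#' Analytic count over the model graph: convolution kernels, biases and
#' batch-norm scale/shift pairs.
#'
#' @param model a `VegModel`.
#' @param millions report in millions rounded to 0.1 (default) or as a raw
#'   integer count.
#' @return numeric scalar.
#' @export
countParameters <- function(model, millions = TRUE) {
  n <- sum(vapply(model@nodes, paramCountNode, numeric(1)))
  if (millions) round(n / 1e6, 1) else n
}

#' Brute-force parameter enumeration
#'
#' Independent oracle: walks the actual weight arrays and sums their element
#' counts.
#'
#' @param model a `VegModel` (or any list of numeric arrays via `$params`).
#' @return integer total element count.
#' @export
countParametersOracle <- function(model) {
  params <- if (is(model, "VegModel")) model@params else model$params
  sum(vapply(params, length, numeric(1)))
}

#' Analytic FLOPs count
#'
#' Per-layer operation count at batch 1, counting one multiply-accumulate as
#' two floating-point operations; convolutions only.
#'
#' @param model a `VegModel`.
#' @param input_size input resolution (defaults to the model's configured
#'   size).
#' @param gflops report in GFLOPs rounded to 0.1 (default) or raw FLOPs.
#' @return numeric scalar.
#' @export
countFlops <- function(model, input_size = model@config@inputSize,
                       gflops = TRUE) {
  nodes <- model@nodes
  sh <- graphShapes(nodes, c(input_size, input_size), 3L)
  total <- 0
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    if (nd$op != "conv") next
    a <- nd$attrs
    cing <- nd$cin %/% a$groups
    total <- total + 2 * (a$k * a$k * cing) * a$cout * sh$h[i] * sh$w[i]
  }
  if (gflops) round(total / 1e9, 1) else total
}

#' Maximum convolution stride in the graph
#'
#' Structural introspection used to verify that detail-preserving variants
#' contain no strided convolution anywhere.
#'
#' @param model a `VegModel` (or a block module list with `$nodes`).
#' @return integer maximum stride over all convolution nodes.
#' @export
maxConvStride <- function(model) {
  nodes <- if (is(model, "VegModel")) model@nodes else model$nodes
  strides <- vapply(nodes, function(nd)
    if (nd$op == "conv") nd$attrs$stride else 1L, integer(1))
  max(strides)
}

#' Audit all ablation variants
#'
#' Builds each of the eight module-flag combinations and reports the audited
#' parameter count (millions) and FLOPs (GFLOPs) at the given input size.
#'
#' @param input_size input resolution in pixels.
#' @param num_classes number of classes (the published budgets use 15).
#' @param preset architecture preset.
#' @return a data.frame with one row per variant.
#' @export
auditVariants <- function(input_size = 640L, num_classes = 15L, preset = "n") {
  flags <- expand.grid(adeconv = c(FALSE, TRUE), mflayer = c(FALSE, TRUE),
                       idfnet = c(FALSE, TRUE))
  # published row order: baseline, +A, +M, +I, A+M, A+I, M+I, full
  ord <- c(1L, 2L, 3L, 5L, 4L, 6L, 7L, 8L)
  flags <- flags[ord, ]
  rows <- lapply(seq_len(nrow(flags)), function(i) {
    cfg <- modelConfig(input_size, num_classes,
                       use_adeconv = flags$adeconv[i],
                       use_mflayer = flags$mflayer[i],
                       use_idfnet = flags$idfnet[i], preset = preset)
    m <- buildModel(cfg)
    data.frame(adeconv = flags$adeconv[i], mflayer = flags$mflayer[i],
               idfnet = flags$idfnet[i],
               params_M = countParameters(m),
               gflops = countFlops(m, input_size))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
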
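# Equation-level building blocks: space-to-depth, channel shuffle, the
# non-strided ghost block, ADEConv and the AAFS gate.

test_that("space-to-depth rearranges a 2x2 block into the documented channel order", {
  x <- featureMap(c(1, 2, 3, 4), 1, 1, 2, 2)
  y <- spaceToDepth(x, 2)
  expect_equal(unname(fmShape(y)), c(1, 4, 1, 1))
  # f(0,0)=1, f(0,1)=2, f(1,0)=3, f(1,1)=4 (row-major over offsets)
  expect_equal(as.vector(y), c(1, 2, 3, 4))
})

test_that("space-to-depth shape arithmetic and divisibility errors", {
  x <- fmRandom(2, 3, 8, 8)
  expect_equal(unname(fmShape(spaceToDepth(x, 2))), c(2, 12, 4, 4))
  bad <- fmRandom(1, 1, 7, 8)
  expect_error(spaceToDepth(bad, 2), "row")
  bad2 <- fmRandom(1, 1, 8, 7)
  expect_error(spaceToDepth(bad2, 2), "column")
})

test_that("space-to-depth is a bijection and conserves every input value", {
  set.seed(11)
  for (scale in c(2L, 4L)) {
    x <- fmRandom(2, 3, 16, 8)
    y <- spaceToDepth(x, scale)
    expect_identical(depthToSpace(y, scale), x)       # bit-exact inverse
    expect_identical(sum(y), sum(x))                  # exact conservation
    expect_identical(sort(as.vector(y)), sort(as.vector(x)))
  }
})

test_that("channel shuffle applies the reshape-transpose permutation", {
  # brute-force oracle: place index array through reshape/transpose
  x <- featureMap(1:6, 1, 6, 1, 1)
  # oracle: reshape channel indices to (groups, C/groups) row-major,
  # transpose, flatten
  oracle <- as.vector(matrix(1:6, nrow = 2, byrow = TRUE))
  y <- channelShuffle(x, 2)
  expect_equal(as.vector(y), c(1, 4, 2, 5, 3, 6))
  expect_equal(as.vector(y), oracle)
  expect_identical(channelShuffle(x, 1), x)           # groups = 1 identity
  set.seed(5)
  xr <- fmRandom(2, 12, 4, 4)
  ys <- channelShuffle(xr, 3)
  expect_identical(sort(as.vector(ys)), sort(as.vector(xr)))
  # inverse permutation restores the original order
  perm <- vegyolo:::shufflePerm(12, 3)
  expect_identical(ys[, , order(perm), , drop = FALSE], xr)
  expect_error(channelShuffle(xr, 5), "divisible")
})

test_that("ghost block splits its output channels into two equal halves", {
  set.seed(21)
  cfg <- adeConvConfig(4, 32, cheap_groups = 2)   # ghost input has 16 channels
  mod <- blockModule("ghost", cfg)
  x <- fmRandom(1, 16, 4, 4)
  y <- moduleForward(mod, x)
  expect_equal(unname(fmShape(y)), c(1, 32, 4, 4))
  # primary half alone (second half of the concat) matches its node output
  primary <- moduleForward(mod, x, node = 2L)
  expect_equal(unname(fmShape(primary)), c(1, 16, 4, 4))
  expect_equal(y[, , 17:32, , drop = FALSE], primary)
})

test_that("ghost block handles the published 256 -> 128 channel instance", {
  set.seed(22)
  cfg <- adeConvConfig(64, 128, cheap_groups = 4)  # SPD output: 256 channels
  mod <- blockModule("ghost", cfg)
  x <- fmRandom(1, 256, 20, 20)
  y <- moduleForward(mod, x)
  expect_equal(unname(fmShape(y)), c(1, 128, 20, 20))
})

test_that("ghost block rejects odd output widths and the parameter audit matches enumeration", {
  expect_error(adeConvConfig(8, 31), "even")
  set.seed(23)
  cfg <- adeConvConfig(4, 24, cheap_groups = 2)
  mod <- blockModule("ghost", cfg)
  analytic <- sum(vapply(mod$nodes, vegyolo:::paramCountNode, numeric(1)))
  expect_identical(analytic, bruteParamCount(mod$params))
})

test_that("ADEConv reproduces the published 64 -> 128 shape map with halved resolution", {
  set.seed(31)
  cfg <- adeConvConfig(64, 128, cheap_groups = 4)
  mod <- blockModule("adeconv", cfg)
  x <- fmRandom(1, 64, 64, 64)   # same channel map as the 320x320 instance
  y <- moduleForward(mod, x)
  expect_equal(unname(fmShape(y)), c(1, 128, 32, 32))
  expect_true(all(is.finite(y)))
  # no strided convolution anywhere inside
  expect_identical(maxConvStride(mod), 1L)
})

test_that("ADEConv equals space-to-depth followed by the ghost block on shared weights", {
  set.seed(32)
  cfg <- adeConvConfig(6, 16, cheap_groups = 2)
  mod <- blockModule("adeconv", cfg)
  x <- fmRandom(2, 6, 8, 8)
  y <- moduleForward(mod, x)
  # two-step evaluation with the same weights
  ghost <- blockModule("ghost", cfg)
  # map adeconv conv params (nodes appear in the same order) onto ghost's
  cmap <- function(mod) vapply(Filter(function(nd) nd$op == "conv", mod$nodes),
                               function(nd) nd$attrs$name, "")
  an <- cmap(mod); gn <- cmap(ghost)
  for (i in seq_along(an))
    for (suf in c(".w", ".b", ".gamma", ".beta")) {
      key <- paste0(an[i], suf)
      if (!is.null(mod$params[[key]]))
        ghost$params[[paste0(gn[i], suf)]] <- mod$params[[key]]
    }
  y2 <- moduleForward(ghost, spaceToDepth(x, 2))
  expect_equal(y, y2, tolerance = 1e-12)
})

test_that("AAFS channel weights: pooling, hidden width, and zero-weight collapse", {
  # constant per channel -> spatial GAP returns that constant
  x <- featureMap(rep(c(2, -1, 0.5), each = 12), 1, 3, 3, 4)
  g <- vegyolo:::gapSpatial(x)
  expect_equal(as.vector(g), c(2, -1, 0.5))
  set.seed(41)
  cfg <- aafsConfig(64, reduction = 4)
  mod <- blockModule("aafs_channel", cfg)
  # squeeze conv maps 64 -> 16 hidden channels
  wdim <- dim(mod$params[["n003.w"]])
  expect_equal(wdim[4], 16L)
  # all-zero weights and biases give identically zero channel weights
  mod$params <- lapply(mod$params, function(p) p * 0)
  xr <- fmRandom(2, 64, 5, 5)
  wc <- moduleForward(mod, xr)
  expect_true(all(wc == 0))
})

test_that("AAFS spatial weights: max pool dominates mean pool and constants propagate", {
  set.seed(42)
  cfg <- aafsConfig(8, reduction = 4)
  mod <- blockModule("aafs_spatial", cfg)
  xr <- fmRandom(2, 8, 6, 6)
  pooled <- moduleForward(mod, xr, node = 2L)   # the [mean, max] map
  expect_equal(unname(fmShape(pooled)), c(2, 2, 6, 6))
  expect_true(all(pooled[, , 2, ] >= pooled[, , 1, ] - 1e-12))
  # spatially constant input -> spatially constant response away from the
  # zero-padded border (the 7x7 kernel reaches 3 pixels in)
  xc <- array(rep(rnorm(8 * 2), each = 100), c(10, 10, 8, 2))
  ws <- moduleForward(mod, xc)
  expect_equal(ws[5, 4, 1, 1], ws[5, 5, 1, 1], tolerance = 1e-10)
  expect_equal(ws[6, 6, 1, 2], ws[5, 5, 1, 2], tolerance = 1e-10)
  # single-channel input: mean channel equals max channel equals the input
  x1 <- fmRandom(1, 1, 5, 5)
  p1 <- vegyolo:::cpp_chanpool_fwd(x1)$y
  expect_equal(p1[, , 1, 1], x1[, , 1, 1])
  expect_equal(p1[, , 2, 1], x1[, , 1, 1])
})

test_that("AAFS gate is sigmoid-bounded and zero initialisation yields 0.5", {
  set.seed(43)
  cfg <- aafsConfig(8, reduction = 4, gate_groups = 2, shuffle_groups = 2)
  mod <- blockModule("aafs_gate", cfg)
  # zero the gate convolution -> sigmoid(0) = 0.5 everywhere
  gate_name <- mod$nodes[[mod$gate]]$attrs$name
  mod$params[[paste0(gate_name, ".w")]][] <- 0
  mod$params[[paste0(gate_name, ".b")]][] <- 0
  W <- moduleForward(mod, fmRandom(2, 8, 4, 4), node = mod$gate)
  expect_true(all(W == 0.5))
  # output shape contract at a larger size
  cfg2 <- aafsConfig(64, gate_groups = 8)
  mod2 <- blockModule("aafs_gate", cfg2)
  x2 <- fmRandom(2, 64, 10, 10)
  W2 <- moduleForward(mod2, x2, node = mod2$gate)
  expect_equal(dim(W2), dim(x2))
  expect_true(all(W2 > 0 & W2 < 1))
})

test_that("AAFS gate stays strictly inside (0,1) over many random inputs", {
  set.seed(44)
  cfg <- aafsConfig(8, gate_groups = 2)
  mod <- blockModule("aafs_gate", cfg)
  ok <- TRUE
  for (i in 1:1000) {
    W <- moduleForward(mod, fmRandom(1, 8, 3, 3) * runif(1, 0.1, 5),
                       node = mod$gate)
    ok <- ok && all(W > 0 & W < 1)
  }
  expect_true(ok)
})

test_that("AAFS application gates multiplicatively and passes gradient to both branches", {
  set.seed(45)
  cfg <- aafsConfig(8, gate_groups = 2)
  mod <- blockModule("aafs", cfg)
  gate_name <- mod$nodes[[mod$gate]]$attrs$name
  mod$params[[paste0(gate_name, ".w")]][] <- 0
  mod$params[[paste0(gate_name, ".b")]][] <- 0
  x <- fmRandom(1, 8, 4, 4)
  y <- moduleForward(mod, x)
  expect_equal(y, x / 2, tolerance = 1e-12)
  # with random weights: |out| <= |x| elementwise (0 < W < 1)
  mod2 <- blockModule("aafs", cfg)
  y2 <- moduleForward(mod2, x)
  expect_true(all(abs(y2) <= abs(x) + 1e-12))
  # gradients reach the gate convolution and the identity branch, and agree
  # with central finite differences on sampled weights
  fwd <- vegyolo:::graphForward(mod2$nodes, x, mod2$params, mod2$state,
                                training = TRUE)
  gy <- fwd$acts[[mod2$out]] * 0 + 1
  gouts <- list(); gouts[[as.character(mod2$out)]] <- gy
  grads <- vegyolo:::graphBackward(mod2$nodes, fwd, mod2$params, gouts)
  gname <- paste0(mod2$nodes[[mod2$gate]]$attrs$name, ".w")
  expect_gt(sum(abs(grads[[gname]])), 0)
  lossAt <- function(params) {
    f <- vegyolo:::graphForward(mod2$nodes, x, params, mod2$state, TRUE)
    sum(f$acts[[mod2$out]])
  }
  for (probe in c(1L, 7L)) {
    eps <- 1e-6
    p1 <- mod2$params; p1[[gname]][probe] <- p1[[gname]][probe] + eps
    p2 <- mod2$params; p2[[gname]][probe] <- p2[[gname]][probe] - eps
    fd <- (lossAt(p1) - lossAt(p2)) / (2 * eps)
    expect_equal(grads[[gname]][probe], fd, tolerance = 1e-5)
  }
})

test_that("block parameter audits equal brute-force enumeration", {
  set.seed(46)
  for (mk in list(function() blockModule("adeconv", adeConvConfig(6, 16)),
                  function() blockModule("aafs", aafsConfig(8, gate_groups = 2)))) {
    mod <- mk()
    analytic <- sum(vapply(mod$nodes, vegyolo:::paramCountNode, numeric(1)))
    expect_identical(analytic, bruteParamCount(mod$params))
  }
})
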
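# Model assembly, structural audits and decoding.

test_that("backbone emits the documented pyramid resolutions at 640 input", {
  cfg <- modelConfig(640, 15, TRUE, TRUE, TRUE)
  m <- buildModel(cfg, init = FALSE)
  sh <- vegyolo:::graphShapes(m@nodes, c(640, 640), 3L)
  sizes <- sh$h[c(m@feats$p2, m@feats$p3, m@feats$p4, m@feats$p5)]
  expect_equal(sizes, c(160, 80, 40, 20))
})

test_that("detail-preserving variants contain no strided convolution", {
  for (idf in c(FALSE, TRUE)) {
    cfg <- modelConfig(160, 5, use_adeconv = TRUE, use_mflayer = TRUE,
                       use_idfnet = idf, preset = "tiny")
    m <- buildModel(cfg, init = FALSE)
    expect_identical(maxConvStride(m), 1L)
  }
  base <- buildModel(modelConfig(160, 5, FALSE, FALSE, FALSE, preset = "tiny"),
                     init = FALSE)
  expect_identical(maxConvStride(base), 2L)
})

test_that("all eight module-flag combinations build", {
  flags <- expand.grid(a = c(FALSE, TRUE), m = c(FALSE, TRUE),
                       i = c(FALSE, TRUE))
  for (r in seq_len(nrow(flags))) {
    cfg <- modelConfig(96, 5, flags$a[r], flags$m[r], flags$i[r],
                       preset = "tiny")
    expect_s4_class(buildModel(cfg, init = FALSE), "VegModel")
  }
})

test_that("parameter audit equals brute-force weight enumeration", {
  set.seed(7)
  for (fl in list(c(FALSE, FALSE, FALSE), c(TRUE, TRUE, TRUE))) {
    cfg <- modelConfig(96, 5, fl[1], fl[2], fl[3], preset = "tiny")
    m <- buildModel(cfg)
    expect_identical(countParameters(m, millions = FALSE),
                     countParametersOracle(m))
  }
  # and at the calibrated n scale
  mN <- buildModel(modelConfig(640, 15, TRUE, TRUE, TRUE))
  expect_identical(countParameters(mN, millions = FALSE),
                   countParametersOracle(mN))
})

test_that("single-convolution parameter and FLOP counts match closed forms", {
  gb <- vegyolo:::newGraphBuilder()
  x <- vegyolo:::gInput(gb, 8L)
  vegyolo:::gConv(gb, x, 16L, k = 1L, bn = FALSE, bias = FALSE, act = "none")
  nodes <- vegyolo:::finalizeGraph(gb$nodes)
  expect_equal(vegyolo:::paramCountNode(nodes[[2]]), 8 * 16)   # 128 weights
  gb2 <- vegyolo:::newGraphBuilder()
  x2 <- vegyolo:::gInput(gb2, 16L)
  vegyolo:::gConv(gb2, x2, 16L, k = 3L, bn = FALSE, bias = FALSE, act = "none")
  nodes2 <- vegyolo:::finalizeGraph(gb2$nodes)
  sh <- vegyolo:::graphShapes(nodes2, c(32, 32), 16L)
  flops <- 2 * (3 * 3 * 16) * 16 * sh$h[2] * sh$w[2]
  expect_equal(flops, 2 * (3 * 3 * 16) * 16 * 32 * 32)
  fake <- new("VegModel", config = modelConfig(64, 1, preset = "tiny"),
              nodes = nodes2, heads = list(), feats = list(),
              params = list(), state = list())
  expect_equal(countFlops(fake, 32, gflops = FALSE), flops)
})

test_that("doubling the input side quadruples a fully convolutional model's FLOPs", {
  cfg <- modelConfig(640, 15, TRUE, TRUE, TRUE)
  m <- buildModel(cfg, init = FALSE)
  f640 <- countFlops(m, 640, gflops = FALSE)
  f320 <- countFlops(m, 320, gflops = FALSE)
  expect_lt(abs(f640 / f320 - 4), 4 * 0.005)
})

test_that("module additions move the structural budgets in the documented direction", {
  base <- buildModel(modelConfig(640, 15, FALSE, FALSE, FALSE), init = FALSE)
  ade <- buildModel(modelConfig(640, 15, TRUE, FALSE, FALSE), init = FALSE)
  mf <- buildModel(modelConfig(640, 15, FALSE, TRUE, FALSE), init = FALSE)
  expect_gt(countParameters(ade, FALSE), countParameters(base, FALSE))
  expect_gt(countFlops(mf, gflops = FALSE), countFlops(base, gflops = FALSE))
})

test_that("forward pass emits per-level maps at the configured strides", {
  set.seed(9)
  cfg <- modelConfig(96, 5, TRUE, TRUE, TRUE, preset = "tiny")
  m <- buildModel(cfg)
  x <- fmRandom(1, 3, 96, 96)
  out <- forwardModel(m, x)
  strides <- vapply(out$outputs$o2m, `[[`, integer(1), "stride")
  expect_equal(strides, c(4L, 8L, 16L, 32L))
  for (lv in out$outputs$o2m) {
    expect_equal(dim(lv$cls)[1], 96 / lv$stride)
    expect_equal(dim(lv$cls)[3], 5L)
    expect_equal(dim(lv$box)[3], 4L * cfg@arch$head$reg_max)
  }
  m3 <- buildModel(modelConfig(96, 5, TRUE, FALSE, TRUE, preset = "tiny"))
  out3 <- forwardModel(m3, x)
  expect_equal(vapply(out3$outputs$o2o, `[[`, integer(1), "stride"),
               c(8L, 16L, 32L))
})

test_that("repeated forward passes are bit-identical", {
  set.seed(10)
  cfg <- modelConfig(64, 3, TRUE, TRUE, TRUE, preset = "tiny")
  m <- buildModel(cfg)
  x <- fmRandom(2, 3, 64, 64)
  o1 <- forwardModel(m, x)$outputs$o2o
  o2 <- forwardModel(m, x)$outputs$o2o
  for (li in seq_along(o1)) {
    expect_identical(o1[[li]]$cls, o2[[li]]$cls)
    expect_identical(o1[[li]]$box, o2[[li]]$box)
  }
})

test_that("the neck stacks the configured number of fusion layers", {
  cfg <- modelConfig(96, 5, FALSE, FALSE, TRUE, preset = "tiny",
                     neck_repeats = 3L)
  m <- buildModel(cfg, init = FALSE)
  # each fusion layer has exactly 4 attention gates (sigmoid group convs)
  gates <- sum(vapply(m@nodes, function(nd)
    nd$op == "conv" && identical(nd$attrs$act, "sigmoid"), logical(1)))
  expect_equal(gates, 3L * 4L)
  m2 <- buildModel(modelConfig(96, 5, FALSE, FALSE, TRUE, preset = "tiny",
                               neck_repeats = 2L), init = FALSE)
  gates2 <- sum(vapply(m2@nodes, function(nd)
    nd$op == "conv" && identical(nd$attrs$act, "sigmoid"), logical(1)))
  expect_equal(gates2, 2L * 4L)
})

test_that("zero-initialised attention gates halve every fusion node's summed input", {
  set.seed(12)
  cfg <- modelConfig(64, 3, FALSE, FALSE, TRUE, preset = "tiny",
                     neck_repeats = 1L)
  m <- buildModel(cfg)
  # zero all gate convolutions
  for (nd in m@nodes) {
    if (nd$op == "conv" && identical(nd$attrs$act, "sigmoid")) {
      m@params[[paste0(nd$attrs$name, ".w")]][] <- 0
      m@params[[paste0(nd$attrs$name, ".b")]][] <- 0
    }
  }
  x <- fmRandom(1, 3, 64, 64)
  fwd <- vegyolo:::graphForward(m@nodes, x, m@params, m@state, training = TRUE)
  # find a mul node (gate application): output must equal half its sum input
  for (i in seq_along(m@nodes)) {
    nd <- m@nodes[[i]]
    if (nd$op != "mul") next
    sum_in <- fwd$acts[[nd$ins[2]]]
    expect_equal(fwd$acts[[i]], sum_in / 2, tolerance = 1e-12)
  }
})

test_that("decoded detections stay inside the unit square with valid scores", {
  set.seed(13)
  cfg <- modelConfig(64, 3, TRUE, TRUE, TRUE, preset = "tiny")
  m <- buildModel(cfg)
  x <- fmRandom(2, 3, 64, 64)
  det <- predictBoxes(m, x, conf = 0.001, topk = 50)
  if (nrow(det)) {
    xy <- cxcywhToXyxy(as.matrix(det[, c("cx", "cy", "w", "h")]))
    expect_true(all(xy >= -1e-9 & xy <= 1 + 1e-9))
    expect_true(all(det$score >= 0 & det$score <= 1))
    expect_true(all(det$w > 0 & det$h > 0))
  }
  expect_error(modelConfig(100, 5), "divisible")
})

test_that("a single SGD step on a toy batch reduces the loss", {
  set.seed(14)
  cfg <- modelConfig(64, 3, TRUE, TRUE, TRUE, preset = "tiny")
  m <- buildModel(cfg)
  dat <- makeToyData(4, nc = 3, size = 64, seed0 = 77)
  x <- vegyolo:::stackBatch(dat$images)
  tcfg <- trainConfig(epochs = 1, batch_size = 4, input_size = 64, seed = 1,
                      lr0 = 0.005)
  attr(tcfg, "lr_now") <- 0.005
  vel <- vegyolo:::sgdInit(m@params)
  s1 <- vegyolo:::trainStep(m, x, dat$targets, tcfg, vel)
  s2 <- vegyolo:::trainStep(s1$model, x, dat$targets, tcfg, s1$vel)
  expect_lt(s2$comps[["total"]], s1$comps[["total"]])
})
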
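# ---------------------------------------------------------------------------
# Static computation graph.
#
# A model is a directed acyclic graph of single-output nodes appended in
# topological order by the g*() builder functions.  Parameters live in a flat
# named list keyed "<node name>.<w|b|gamma|beta>"; batch-norm running moments
# live in a parallel `state` list.  Forward caches what backward needs; both
# passes walk the node list (forward order / reverse order).
# ---------------------------------------------------------------------------

newGraphBuilder <- function() {
  gb <- new.env(parent = emptyenv())
  gb$nodes <- list()
  gb$tags <- list()
  gb
}

gNode <- function(gb, op, ins, attrs = list()) {
  ins <- as.integer(ins)  # force now: nested builder calls append nodes first
  id <- length(gb$nodes) + 1L
  attrs$name <- sprintf("n%03d", id)
  gb$nodes[[id]] <- list(id = id, op = op, ins = as.integer(ins), attrs = attrs)
  id
}

gInput <- function(gb, channels) {
  gNode(gb, "input", integer(0), list(cout = as.integer(channels)))
}

# Convolution with optional fused batch norm and activation.
# act: "silu", "relu", "sigmoid", "none".
gConv <- function(gb, in_id, cout, k = 1L, stride = 1L, groups = 1L,
                  bn = TRUE, act = "silu", bias = !bn, pad = (k - 1L) %/% 2L,
                  bias_init = 0) {
  gNode(gb, "conv", in_id,
        list(cout = as.integer(cout), k = as.integer(k),
             stride = as.integer(stride), pad = as.integer(pad),
             groups = as.integer(groups), bn = bn, act = act, bias = bias,
             bias_init = bias_init))
}

gSPD <- function(gb, in_id, scale = 2L) gNode(gb, "spd", in_id, list(scale = as.integer(scale)))
gShuffle <- function(gb, in_id, groups) gNode(gb, "shuffle", in_id, list(groups = as.integer(groups)))
gConcat <- function(gb, ins) gNode(gb, "concat", ins)
gAdd <- function(gb, ins) gNode(gb, "add", ins)
gMul <- function(gb, a, b) gNode(gb, "mul", c(a, b))
gChSlice <- function(gb, in_id, from, to) gNode(gb, "chslice", in_id, list(from = as.integer(from), to = as.integer(to)))
gGAP <- function(gb, in_id) gNode(gb, "gap", in_id)
gChanPool <- function(gb, in_id) gNode(gb, "chanpool", in_id)
gBSum <- function(gb, chan_id, spat_id) gNode(gb, "bsum", c(chan_id, spat_id))
gMaxPool <- function(gb, in_id, k = 5L) gNode(gb, "maxpool", in_id, list(k = as.integer(k), pad = (as.integer(k) - 1L) %/% 2L))
gUp2 <- function(gb, in_id) gNode(gb, "up2", in_id)

# ---------------------------------------------------------------------------
# Shape inference: channels always; spatial dims given an input size.
# Returns a data.frame with one row per node.
# ---------------------------------------------------------------------------
graphShapes <- function(nodes, input_hw, input_channels) {
  n <- length(nodes)
  ch <- integer(n); hh <- integer(n); ww <- integer(n)
  for (i in seq_len(n)) {
    nd <- nodes[[i]]
    a <- nd$attrs
    ins <- nd$ins
    switch(nd$op,
      input = { ch[i] <- a$cout; hh[i] <- input_hw[1]; ww[i] <- input_hw[2] },
      conv = {
        ch[i] <- a$cout
        hh[i] <- (hh[ins] + 2L * a$pad - a$k) %/% a$stride + 1L
        ww[i] <- (ww[ins] + 2L * a$pad - a$k) %/% a$stride + 1L
      },
      spd = { ch[i] <- ch[ins] * a$scale^2; hh[i] <- hh[ins] %/% a$scale; ww[i] <- ww[ins] %/% a$scale },
      shuffle = { ch[i] <- ch[ins]; hh[i] <- hh[ins]; ww[i] <- ww[ins] },
      concat = { ch[i] <- sum(ch[ins]); hh[i] <- hh[ins[1]]; ww[i] <- ww[ins[1]] },
      add = ,
      mul = { ch[i] <- ch[ins[1]]; hh[i] <- hh[ins[1]]; ww[i] <- ww[ins[1]] },
      chslice = { ch[i] <- a$to - a$from + 1L; hh[i] <- hh[ins]; ww[i] <- ww[ins] },
      gap = { ch[i] <- ch[ins]; hh[i] <- 1L; ww[i] <- 1L },
      chanpool = { ch[i] <- 2L; hh[i] <- hh[ins]; ww[i] <- ww[ins] },
      bsum = { ch[i] <- ch[ins[1]]; hh[i] <- hh[ins[2]]; ww[i] <- ww[ins[2]] },
      baddchan = { ch[i] <- ch[ins[1]]; hh[i] <- hh[ins[1]]; ww[i] <- ww[ins[1]] },
      maxpool = { ch[i] <- ch[ins]; hh[i] <- hh[ins]; ww[i] <- ww[ins] },
      up2 = { ch[i] <- ch[ins]; hh[i] <- hh[ins] * 2L; ww[i] <- ww[ins] * 2L },
      stop("unknown op ", nd$op)
    )
  }
  data.frame(id = seq_len(n), op = vapply(nodes, `[[`, "", "op"),
             channels = ch, h = hh, w = ww)
}

inChannels <- function(nodes, i) {
  nd <- nodes[[i]]
  if (nd$op == "concat") {
    sum(vapply(nd$ins, function(j) nodeOutChannels(nodes, j), integer(1)))
  } else {
    nodeOutChannels(nodes, nd$ins[1])
  }
}

nodeOutChannels <- function(nodes, i) {
  nd <- nodes[[i]]
  a <- nd$attrs
  switch(nd$op,
    input = a$cout,
    conv = a$cout,
    spd = nodeOutChannels(nodes, nd$ins) * a$scale^2,
    shuffle = ,
    maxpool = ,
    up2 = ,
    gap = nodeOutChannels(nodes, nd$ins),
    concat = sum(vapply(nd$ins, function(j) nodeOutChannels(nodes, j), integer(1))),
    add = ,
    mul = nodeOutChannels(nodes, nd$ins[1]),
    chslice = a$to - a$from + 1L,
    chanpool = 2L,
    bsum = ,
    baddchan = nodeOutChannels(nodes, nd$ins[1]),
    stop("unknown op ", nd$op))
}

# ---------------------------------------------------------------------------
# Parameter initialisation (Kaiming for conv weights, BN gamma = 1).
# ---------------------------------------------------------------------------
initGraphParams <- function(nodes) {
  params <- list()
  state <- list()
  for (nd in nodes) {
    if (nd$op != "conv") next
    a <- nd$attrs
    cin <- nd$cin
    cing <- cin %/% a$groups
    fan <- a$k * a$k * cing
    w <- array(stats::rnorm(a$k * a$k * cing * a$cout, sd = sqrt(2 / fan)),
               dim = c(a$k, a$k, cing, a$cout))
    params[[paste0(a$name, ".w")]] <- w
    if (isTRUE(a$bias))
      params[[paste0(a$name, ".b")]] <- rep(a$bias_init, a$cout)
    if (isTRUE(a$bn)) {
      params[[paste0(a$name, ".gamma")]] <- rep(1, a$cout)
      params[[paste0(a$name, ".beta")]] <- rep(0, a$cout)
      state[[paste0(a$name, ".rmean")]] <- rep(0, a$cout)
      state[[paste0(a$name, ".rvar")]] <- rep(1, a$cout)
    }
  }
  list(params = params, state = state)
}

# Annotate conv nodes with their input channel count (needed for params).
finalizeGraph <- function(nodes) {
  for (i in seq_along(nodes)) {
    if (nodes[[i]]$op == "conv")
      nodes[[i]]$cin <- nodeOutChannels(nodes, nodes[[i]]$ins[1])
  }
  nodes
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.03

actCode <- function(act) {
  switch(act, none = 0L, silu = 1L, relu = 2L, sigmoid = 3L,
         stop("unknown activation ", act))
}

# ---------------------------------------------------------------------------
# Forward pass.  Returns activations, caches and (possibly updated) state.
# ---------------------------------------------------------------------------
graphForward <- function(nodes, x, params, state, training = FALSE,
                         keep = NULL) {
  n <- length(nodes)
  acts <- vector("list", n)
  caches <- if (training) vector("list", n) else NULL
  for (i in seq_len(n)) {
    nd <- nodes[[i]]
    a <- nd$attrs
    ins <- nd$ins
    out <- switch(nd$op,
      input = x,
      conv = {
        xin <- acts[[ins]]
        w <- params[[paste0(a$name, ".w")]]
        b <- if (isTRUE(a$bias)) params[[paste0(a$name, ".b")]] else NULL
        xc <- cpp_conv2d_fwd(xin, w, b, a$stride, a$pad, a$groups)
        actc <- actCode(a$act)
        if (isTRUE(a$bn)) {
          r <- cpp_bnact_fwd(xc, params[[paste0(a$name, ".gamma")]],
                             params[[paste0(a$name, ".beta")]],
                             state[[paste0(a$name, ".rmean")]],
                             state[[paste0(a$name, ".rvar")]],
                             training, BN_MOMENTUM, BN_EPS, actc)
          if (training) {
            state[[paste0(a$name, ".rmean")]] <- r$rmean
            state[[paste0(a$name, ".rvar")]] <- r$rvar
            caches[[i]] <- list(xc = xc, mu = r$mu, inv = r$inv)
          }
          r$y
        } else {
          y <- if (actc == 0L) xc else cpp_act_fwd(xc, actc)
          if (training) caches[[i]] <- list(z = xc)
          y
        }
      },
      spd = cpp_spd_fwd(acts[[ins]], a$scale),
      shuffle = channelShuffle(acts[[ins]], a$groups),
      concat = cpp_concat(acts[ins]),
      add = cpp_addn(acts[ins]),
      mul = acts[[ins[1]]] * acts[[ins[2]]],
      chslice = cpp_chslice(acts[[ins]], a$from, a$to),
      gap = gapSpatial(acts[[ins]]),
      chanpool = {
        r <- cpp_chanpool_fwd(acts[[ins]])
        if (training) caches[[i]] <- list(arg = r$arg, C = dim(acts[[ins]])[3])
        r$y
      },
      bsum = {
        v <- acts[[ins[1]]]; s <- acts[[ins[2]]]
        d <- dim(s)
        bcastChan(v, d[1], d[2]) + bcastSpat(s, dim(v)[3])
      },
      baddchan = {
        s <- acts[[ins[1]]]; v <- acts[[ins[2]]]
        d <- dim(s)
        s + bcastChan(v, d[1], d[2])
      },
      maxpool = {
        r <- cpp_maxpool_fwd(acts[[ins]], a$k, a$pad)
        if (training) caches[[i]] <- list(arg = r$arg)
        r$y
      },
      up2 = cpp_up2_fwd(acts[[ins]]),
      stop("unknown op ", nd$op))
    acts[[i]] <- out
  }
  list(acts = acts, caches = caches, state = state)
}

# ---------------------------------------------------------------------------
# Backward pass.  `gouts` is a named list: names are node ids (as character),
# values the gradients of the loss w.r.t. those nodes' outputs.
# Returns the parameter-gradient list.
# ---------------------------------------------------------------------------
graphBackward <- function(nodes, fwd, params, gouts) {
  n <- length(nodes)
  acts <- fwd$acts; caches <- fwd$caches
  gacts <- vector("list", n)
  for (nm in names(gouts)) {
    i <- as.integer(nm)
    gacts[[i]] <- if (is.null(gacts[[i]])) gouts[[nm]] else gacts[[i]] + gouts[[nm]]
  }
  grads <- list()
  addg <- function(i, g) {
    if (is.null(gacts[[i]])) gacts[[i]] <<- g else gacts[[i]] <<- gacts[[i]] + g
  }
  for (i in rev(seq_len(n))) {
    g <- gacts[[i]]
    if (is.null(g)) next
    nd <- nodes[[i]]
    a <- nd$attrs
    ins <- nd$ins
    switch(nd$op,
      input = NULL,
      conv = {
        cache <- caches[[i]]
        actc <- actCode(a$act)
        if (isTRUE(a$bn)) {
          r <- cpp_bnact_bwd(cache$xc, g, params[[paste0(a$name, ".gamma")]],
                             params[[paste0(a$name, ".beta")]],
                             cache$mu, cache$inv, actc)
          gxc <- r$gxc
          grads[[paste0(a$name, ".gamma")]] <- r$ggamma
          grads[[paste0(a$name, ".beta")]] <- r$gbeta
        } else {
          gxc <- if (actc == 0L) g else cpp_act_bwd(cache$z, g, actc)
          dim(gxc) <- dim(cache$z)
        }
        xin <- acts[[ins]]
        w <- params[[paste0(a$name, ".w")]]
        need_gx <- nodes[[ins]]$op != "input"
        r <- cpp_conv2d_bwd(xin, w, gxc, a$stride, a$pad, a$groups, need_gx,
                            isTRUE(a$bias))
        grads[[paste0(a$name, ".w")]] <- r$gw
        if (isTRUE(a$bias)) grads[[paste0(a$name, ".b")]] <- r$gb
        if (need_gx) addg(ins, r$gx)
      },
      spd = addg(ins, cpp_spd_bwd(g, a$scale)),
      shuffle = {
        C <- dim(g)[3]
        perm <- shufflePerm(C, a$groups)
        invp <- order(perm)
        addg(ins, g[, , invp, , drop = FALSE])
      },
      concat = {
        at <- 0L
        for (j in ins) {
          cj <- nodeOutChannels(nodes, j)
          addg(j, g[, , at + seq_len(cj), , drop = FALSE])
          at <- at + cj
        }
      },
      add = for (j in ins) addg(j, g),
      mul = {
        addg(ins[1], g * acts[[ins[2]]])
        addg(ins[2], g * acts[[ins[1]]])
      },
      chslice = addg(ins, cpp_chslice_bwd(g, a$from, dim(acts[[ins]])[3])),
      gap = {
        d <- dim(acts[[ins]])
        addg(ins, bcastChan(g, d[1], d[2]) / (d[1] * d[2]))
      },
      chanpool = {
        cache <- caches[[i]]
        addg(ins, cpp_chanpool_bwd(g, cache$arg, cache$C))
      },
      bsum = {
        dv <- dim(acts[[ins[1]]])
        # gradient to channel vector: sum over H,W
        gv <- array(colSums(matrix(g, nrow = dim(g)[1] * dim(g)[2])),
                    dim = c(1, 1, dv[3], dv[4]))
        addg(ins[1], gv)
        # gradient to spatial map: sum over channels
        d <- dim(g)
        gsp <- array(0, dim = c(d[1], d[2], 1, d[4]))
        for (nn in seq_len(d[4]))
          gsp[, , 1, nn] <- rowSums(matrix(g[, , , nn], ncol = d[3]))
        addg(ins[2], gsp)
      },
      baddchan = {
        addg(ins[1], g)
        dv <- dim(acts[[ins[2]]])
        gv <- array(colSums(matrix(g, nrow = dim(g)[1] * dim(g)[2])),
                    dim = c(1, 1, dv[3], dv[4]))
        addg(ins[2], gv)
      },
      maxpool = addg(ins, cpp_maxpool_bwd(g, caches[[i]]$arg)),
      up2 = addg(ins, cpp_up2_bwd(g)),
      stop("unknown op ", nd$op))
    gacts[[i]] <- NULL  # free
  }
  grads
}

# ---------------------------------------------------------------------------
# SGD with momentum and decoupled-from-BN weight decay.
# ---------------------------------------------------------------------------
sgdInit <- function(params) lapply(params, function(p) p * 0)

sgdStep <- function(params, grads, vel, lr, momentum, weight_decay) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    decay <- if (grepl("\\.w$", nm)) weight_decay else 0
    v <- momentum * vel[[nm]] - lr * (g + decay * params[[nm]])
    vel[[nm]] <- v
    params[[nm]] <- params[[nm]] + v
  }
  list(params = params, vel = vel)
}
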
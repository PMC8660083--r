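## Minimal 3D conv-net engine.
##
## Activations travel as a list(a = C x V matrix, dims = c(nx, ny, nz)) with
## voxel order x-fastest (matching R's column-major 3D arrays). Layers are
## environments so gradients and batch-norm statistics mutate in place.
## Convolutions use im2col (C++) + BLAS matrix products; the transposed
## kernel-2/stride-2 convolution used for upsampling is expressed with eight
## per-offset matrix products.

.act <- function(a, dims) list(a = a, dims = as.integer(dims))

.convOutDims <- function(dims, k, stride, pad)
  (dims + 2L * pad - k) %/% stride + 1L

## He-style init keeps activations at a trainable scale for (leaky-)ReLU.
.initW <- function(fanOut, fanIn) {
  matrix(stats::rnorm(fanOut * fanIn, sd = sqrt(2 / fanIn)), fanOut, fanIn)
}

.newConv <- function(cin, cout, k = 3L, stride = 1L, pad = 1L) {
  e <- new.env(parent = emptyenv())
  e$type <- "conv"; e$cin <- cin; e$cout <- cout
  e$k <- as.integer(k); e$stride <- as.integer(stride)
  e$pad <- as.integer(pad)
  e$W <- .initW(cout, cin * k^3); e$b <- numeric(cout)
  e$gW <- 0 * e$W; e$gb <- 0 * e$b
  e
}

.convForward <- function(l, x, train = TRUE) {
  if (l$k == 1L && l$stride == 1L) {
    ## kernel-1 convolution is a per-voxel channel mix; no unfolding needed
    y <- l$W %*% x$a + l$b
    if (train) l$cache <- x
    return(.act(y, x$dims))
  }
  cols <- .im2col3d(x$a, x$dims, l$k, l$stride, l$pad)
  y <- l$W %*% cols + l$b
  if (train) l$cache <- list(cols = cols, dims = x$dims)
  .act(y, .convOutDims(x$dims, l$k, l$stride, l$pad))
}

.convBackward <- function(l, gy) {
  if (l$k == 1L && l$stride == 1L) {
    x <- l$cache
    l$gW <- l$gW + tcrossprod(gy$a, x$a)
    l$gb <- l$gb + rowSums(gy$a)
    return(.act(crossprod(l$W, gy$a), x$dims))
  }
  cc <- l$cache
  l$gW <- l$gW + tcrossprod(gy$a, cc$cols)
  l$gb <- l$gb + rowSums(gy$a)
  gcols <- crossprod(l$W, gy$a)
  gx <- .col2im3d(gcols, cc$dims, l$cin, l$k, l$stride, l$pad)
  .act(gx, cc$dims)
}

## Transposed convolution, kernel 2, stride 2: exact x2 upsampling. Each
## output voxel belongs to exactly one of the 8 parity offsets, so the
## forward pass is eight independent channel-mix products.
.newConvT2 <- function(cin, cout) {
  e <- new.env(parent = emptyenv())
  e$type <- "convT2"; e$cin <- cin; e$cout <- cout
  e$W <- lapply(1:8, function(i) .initW(cout, cin))
  e$b <- numeric(cout)
  e$gW <- lapply(1:8, function(i) matrix(0, cout, cin))
  e$gb <- numeric(cout)
  e
}

.offsetIndex <- function(dims, dx, dy, dz) {
  ## linear indices (1-based) of output voxels at parity (dx,dy,dz)
  od <- 2L * dims
  xs <- seq.int(dx, od[1] - 1L, by = 2L)
  ys <- seq.int(dy, od[2] - 1L, by = 2L)
  zs <- seq.int(dz, od[3] - 1L, by = 2L)
  g <- expand.grid(x = xs, y = ys, z = zs)
  1L + g$x + od[1] * (g$y + od[2] * g$z)
}

.convT2Forward <- function(l, x, train = TRUE) {
  od <- 2L * x$dims
  y <- matrix(0, l$cout, prod(od))
  o <- 0L
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    o <- o + 1L
    idx <- .offsetIndex(x$dims, dx, dy, dz)
    y[, idx] <- l$W[[o]] %*% x$a + l$b
  }
  if (train) l$cache <- x
  .act(y, od)
}

.convT2Backward <- function(l, gy) {
  x <- l$cache
  gx <- matrix(0, l$cin, ncol(x$a))
  o <- 0L
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    o <- o + 1L
    idx <- .offsetIndex(x$dims, dx, dy, dz)
    g <- gy$a[, idx, drop = FALSE]
    l$gW[[o]] <- l$gW[[o]] + tcrossprod(g, x$a)
    l$gb <- l$gb + rowSums(g)
    gx <- gx + crossprod(l$W[[o]], g)
  }
  .act(gx, x$dims)
}

## Batch normalization over the voxels of the current input (population
## variance). Running statistics (momentum 0.1) are used in eval mode; this
## keeps kernel-1 discriminators strictly voxel-local at inference.
.newBN <- function(c) {
  e <- new.env(parent = emptyenv())
  e$type <- "bn"; e$c <- c
  e$gamma <- rep(1, c); e$beta <- numeric(c)
  e$ggamma <- numeric(c); e$gbeta <- numeric(c)
  e$rmean <- numeric(c); e$rvar <- rep(1, c)
  e$eps <- 1e-5; e$momentum <- 0.1
  e
}

.bnForward <- function(l, x, train = TRUE) {
  if (train) {
    mu <- rowMeans(x$a)
    va <- rowMeans((x$a - mu)^2)
    l$rmean <- (1 - l$momentum) * l$rmean + l$momentum * mu
    l$rvar <- (1 - l$momentum) * l$rvar + l$momentum * va
  } else {
    mu <- l$rmean; va <- l$rvar
  }
  istd <- 1 / sqrt(va + l$eps)
  xhat <- (x$a - mu) * istd
  if (train) l$cache <- list(xhat = xhat, istd = istd, dims = x$dims)
  .act(xhat * l$gamma + l$beta, x$dims)
}

.bnBackward <- function(l, gy) {
  cc <- l$cache
  l$ggamma <- l$ggamma + rowSums(gy$a * cc$xhat)
  l$gbeta <- l$gbeta + rowSums(gy$a)
  gxhat <- gy$a * l$gamma
  gx <- cc$istd * (gxhat - rowMeans(gxhat) -
                     cc$xhat * rowMeans(gxhat * cc$xhat))
  .act(gx, cc$dims)
}

.newAct <- function(kind = c("relu", "leaky_relu"), slope = 0.2) {
  kind <- match.arg(kind)
  e <- new.env(parent = emptyenv())
  e$type <- "act"; e$kind <- kind
  e$slope <- if (kind == "relu") 0 else slope
  e
}

.actForward <- function(l, x, train = TRUE) {
  y <- x$a
  neg <- y < 0
  y[neg] <- l$slope * y[neg]
  if (train) l$cache <- list(neg = neg, dims = x$dims)
  .act(y, x$dims)
}

.actBackward <- function(l, gy) {
  cc <- l$cache
  g <- gy$a
  g[cc$neg] <- l$slope * g[cc$neg]
  .act(g, cc$dims)
}

## A "unit" is the composite H(.) applied once per block layer. The
## generator uses pre-activation order (BN -> ReLU -> conv); discriminators
## use the Ck order (conv -> BN -> leaky ReLU 0.2).
.newUnit <- function(cin, cout, order = c("pre", "post"), k = 3L,
                     stride = 1L, pad = 1L, slope = 0.2, bn = TRUE) {
  order <- match.arg(order)
  e <- new.env(parent = emptyenv())
  e$type <- "unit"; e$order <- order
  e$conv <- .newConv(cin, cout, k = k, stride = stride, pad = pad)
  e$bn <- if (bn) .newBN(if (order == "pre") cin else cout) else NULL
  e$act <- .newAct(if (order == "pre") "relu" else "leaky_relu",
                   slope = slope)
  e
}

.unitForward <- function(l, x, train = TRUE) {
  if (l$order == "pre") {
    h <- if (is.null(l$bn)) x else .bnForward(l$bn, x, train)
    h <- .actForward(l$act, h, train)
    .convForward(l$conv, h, train)
  } else {
    h <- .convForward(l$conv, x, train)
    if (!is.null(l$bn)) h <- .bnForward(l$bn, h, train)
    .actForward(l$act, h, train)
  }
}

.unitBackward <- function(l, gy) {
  if (l$order == "pre") {
    g <- .convBackward(l$conv, gy)
    g <- .actBackward(l$act, g)
    if (is.null(l$bn)) g else .bnBackward(l$bn, g)
  } else {
    g <- .actBackward(l$act, gy)
    if (!is.null(l$bn)) g <- .bnBackward(l$bn, g)
    .convBackward(l$conv, g)
  }
}

## parameter bookkeeping -----------------------------------------------------

.layerParams <- function(l) {
  switch(l$type,
    conv = list(W = "W", b = "b"),
    convT2 = list(W = "W", b = "b"),
    bn = list(gamma = "gamma", beta = "beta"),
    unit = NULL,
    act = NULL)
}

## flatten a nested layer structure into a list of environments with params
.collectLayers <- function(x) {
  out <- list()
  rec <- function(l) {
    if (is.environment(l)) {
      if (l$type == "unit") {
        rec(l$conv); if (!is.null(l$bn)) rec(l$bn)
      } else if (!is.null(.layerParams(l))) {
        out[[length(out) + 1L]] <<- l
      }
    } else if (is.list(l)) lapply(l, rec)
    invisible(NULL)
  }
  rec(x)
  out
}

.gradName <- function(p) paste0("g", p)

.zeroGrads <- function(layers) {
  for (l in layers) for (p in names(.layerParams(l))) {
    g <- .gradName(.layerParams(l)[[p]])
    v <- l[[.layerParams(l)[[p]]]]
    l[[g]] <- if (is.list(v)) lapply(v, function(m) 0 * m) else 0 * v
  }
  invisible(NULL)
}

.scaleGrads <- function(layers, f) {
  for (l in layers) for (p in names(.layerParams(l))) {
    g <- .gradName(.layerParams(l)[[p]])
    l[[g]] <- if (is.list(l[[g]])) lapply(l[[g]], function(m) m * f)
              else l[[g]] * f
  }
  invisible(NULL)
}

## serialize parameters to a plain list (for checkpoints / hashes)
.dumpParams <- function(layers) {
  lapply(layers, function(l) {
    ps <- .layerParams(l)
    out <- lapply(ps, function(nm) l[[nm]])
    if (l$type == "bn") out$rstats <- list(l$rmean, l$rvar)
    out
  })
}

.loadParams <- function(layers, dump) {
  stopifnot(length(layers) == length(dump))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (nm in names(.layerParams(l))) l[[.layerParams(l)[[nm]]]] <-
        dump[[i]][[nm]]
    if (l$type == "bn") {
      l$rmean <- dump[[i]]$rstats[[1]]; l$rvar <- dump[[i]]$rstats[[2]]
    }
  }
  invisible(NULL)
}

## Adam / momentum-SGD over the collected layers ------------------------------

.newOptimizer <- function(layers, kind = "adam", betas = c(0.9, 0.999)) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind; e$betas <- betas; e$t <- 0L; e$eps <- 1e-8
  e$state <- lapply(layers, function(l) {
    ps <- .layerParams(l)
    lapply(ps, function(nm) {
      v <- l[[nm]]
      zero <- function(m) 0 * m
      if (is.list(v)) list(m = lapply(v, zero), v = lapply(v, zero))
      else list(m = zero(v), v = zero(v))
    })
  })
  e
}

.optStep <- function(opt, layers, lr) {
  opt$t <- opt$t + 1L
  b1 <- opt$betas[1]; b2 <- opt$betas[2]
  upd1 <- function(w, g, st) {
    if (opt$kind == "adam") {
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g^2
      mhat <- st$m / (1 - b1^opt$t)
      vhat <- st$v / (1 - b2^opt$t)
      w <- w - lr * mhat / (sqrt(vhat) + opt$eps)
    } else {
      st$m <- b1 * st$m + g
      w <- w - lr * st$m
    }
    list(w = w, st = st)
  }
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    ps <- .layerParams(l)
    for (nm in names(ps)) {
      w <- l[[ps[[nm]]]]
      g <- l[[.gradName(ps[[nm]])]]
      st <- opt$state[[i]][[nm]]
      if (is.list(w)) {
        for (j in seq_along(w)) {
          r <- upd1(w[[j]], g[[j]], list(m = st$m[[j]], v = st$v[[j]]))
          w[[j]] <- r$w; st$m[[j]] <- r$st$m; st$v[[j]] <- r$st$v
        }
      } else {
        r <- upd1(w, g, st)
        w <- r$w; st <- r$st
      }
      l[[ps[[nm]]]] <- w
      opt$state[[i]][[nm]] <- st
    }
  }
  invisible(NULL)
}
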
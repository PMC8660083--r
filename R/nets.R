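#' Per-layer input-channel plan of a feature-aggregation block
#'
#' Computes the number of input channels each layer of a block consumes
#' under the three connection rules:
#' \describe{
#'   \item{fibonacci}{layer 1 consumes the block input; layer 2 the
#'     concatenation of the block input and layer 1's output; layer l >= 3
#'     the concatenation of the outputs of layers l-1 and l-2 only.}
#'   \item{dense}{layer l consumes the block input concatenated with all
#'     previous outputs.}
#'   \item{linear}{layer l consumes only layer l-1's output.}
#' }
#'
#' @param block list with `connection` ("fibonacci", "dense" or "linear"),
#'   `nLayers`, and `growth` (output channels of every layer).
#' @param inputChannels channels entering the block.
#' @return integer vector of per-layer input channel counts.
#' @examples
#' channelPlan(list(connection = "fibonacci", nLayers = 4, growth = 16), 8)
#' # 8 24 32 32
#' @export
channelPlan <- function(block, inputChannels) {
  L <- block$nLayers
  g <- block$growth
  stopifnot(L >= 1)
  out <- integer(L)
  for (l in seq_len(L)) {
    out[l] <- switch(block$connection,
      fibonacci = if (l == 1L) inputChannels
                  else if (l == 2L) inputChannels + g
                  else 2L * g,
      dense = inputChannels + (l - 1L) * g,
      linear = if (l == 1L) inputChannels else g,
      stop("unknown connection: ", block$connection))
  }
  as.integer(out)
}

## channels leaving a block (its output concatenation)
.blockOutChannels <- function(block, inputChannels) {
  L <- block$nLayers; g <- block$growth
  switch(block$connection,
    fibonacci = if (L == 1L) g else 2L * g,
    dense = inputChannels + L * g,
    linear = g)
}

#' Generator configuration
#'
#' Declares the segmentation generator: an input-transition convolution,
#' a shallow full-resolution stage, a stride-2 downsampled deep stage, a
#' transposed-convolution upsample, and two softmax heads (main and deep
#' supervision, the latter branching off the shallow stage). The default
#' places a Fibonacci block in the shallow stage and a dense block in the
#' deep stage; all convolutions are 3x3x3 except the 1x1x1 classifiers.
#'
#' @param inFilters filters of the input-transition convolution.
#' @param stages list of two block specs (`connection`, `nLayers`,
#'   `growth`), shallow first.
#' @param upFilters channels after the transposed-convolution upsample.
#' @param nClasses number of output classes (2: background, vessel).
#' @param dsWeight deep-supervision loss weight (recorded here, applied by
#'   the losses/training modules).
#' @return a config list consumed by [buildGenerator()].
#' @export
generatorConfig <- function(
    inFilters = 16,
    stages = list(
      list(connection = "fibonacci", nLayers = 4, growth = 16),
      list(connection = "dense", nLayers = 4, growth = 16)),
    upFilters = 32, nClasses = 2, dsWeight = 0.5) {
  stopifnot(length(stages) == 2L)
  for (s in stages)
    stopifnot(s$connection %in% c("fibonacci", "dense", "linear"),
              s$nLayers >= 1, s$growth >= 1)
  list(inFilters = as.integer(inFilters),
       stages = lapply(stages, function(s)
         list(connection = s$connection, nLayers = as.integer(s$nLayers),
              growth = as.integer(s$growth))),
       upFilters = as.integer(upFilters), nClasses = as.integer(nClasses),
       dsWeight = dsWeight)
}

#' Discriminator configuration
#'
#' Three receptive-field regimes: `voxel` (every layer kernel 1 / stride 1,
#' so each output score depends on exactly one input voxel), `patch`
#' (C64-C128-C256 trunk of kernel-3 / stride-2 convolutions, receptive
#' field 15^3) and `volume` (C64-C128-C256-C512-C512, receptive field
#' 63^3). Each Ck is convolution + batch norm + leaky ReLU (slope 0.2); a
#' 1-filter kernel-1 convolution with sigmoid is appended as the scoring
#' layer.
#'
#' @param kind "voxel", "patch" or "volume".
#' @param filters per-layer trunk widths; defaults: voxel `c(32, 64, 32)`,
#'   patch `c(64, 128, 256)`, volume `c(64, 128, 256, 512, 512)`.
#' @param bn include batch normalization (default TRUE).
#' @return a config list consumed by [buildDiscriminator()].
#' @export
discriminatorConfig <- function(kind = c("voxel", "patch", "volume"),
                                filters = NULL, bn = TRUE) {
  kind <- match.arg(kind)
  if (is.null(filters))
    filters <- switch(kind, voxel = c(32, 64, 32), patch = c(64, 128, 256),
                      volume = c(64, 128, 256, 512, 512))
  k <- if (kind == "voxel") 1L else 3L
  s <- if (kind == "voxel") 1L else 2L
  layers <- lapply(filters, function(f)
    list(kernel = k, stride = s, filters = as.integer(f)))
  list(kind2 = kind, layers = layers, bn = bn)
}

## block environment ----------------------------------------------------------

.newBlock <- function(blockSpec, cin, order = "pre") {
  e <- new.env(parent = emptyenv())
  e$connection <- blockSpec$connection
  e$L <- blockSpec$nLayers
  e$g <- blockSpec$growth
  e$cin <- as.integer(cin)
  e$plan <- channelPlan(blockSpec, cin)
  e$units <- lapply(seq_len(e$L), function(l)
    .newUnit(e$plan[l], e$g, order = order))
  e
}

.blockForward <- function(b, x, train = TRUE) {
  outs <- vector("list", b$L)
  for (l in seq_len(b$L)) {
    xin <- switch(b$connection,
      linear = if (l == 1L) x else outs[[l - 1L]],
      dense = if (l == 1L) x
              else .act(do.call(rbind, c(list(x$a),
                lapply(outs[seq_len(l - 1L)], `[[`, "a"))), x$dims),
      fibonacci = if (l == 1L) x
                  else if (l == 2L) .act(rbind(x$a, outs[[1L]]$a), x$dims)
                  else .act(rbind(outs[[l - 1L]]$a, outs[[l - 2L]]$a),
                            x$dims))
    outs[[l]] <- .unitForward(b$units[[l]], xin, train)
  }
  b$outs <- outs   # kept also in eval mode for feature-stack probes
  L <- b$L
  switch(b$connection,
    linear = outs[[L]],
    dense = .act(do.call(rbind, c(list(x$a), lapply(outs, `[[`, "a"))),
                 x$dims),
    fibonacci = if (L == 1L) outs[[1L]]
                else .act(rbind(outs[[L - 1L]]$a, outs[[L]]$a), x$dims))
}

## split a stacked gradient matrix into channel groups
.splitRows <- function(m, sizes) {
  res <- vector("list", length(sizes))
  at <- 0L
  for (i in seq_along(sizes)) {
    res[[i]] <- m[at + seq_len(sizes[i]), , drop = FALSE]
    at <- at + sizes[i]
  }
  res
}

.blockBackward <- function(b, gout) {
  L <- b$L; g <- b$g
  dims <- gout$dims
  V <- ncol(gout$a)
  gOuts <- vector("list", L)
  zero <- function(c) matrix(0, c, V)
  for (l in seq_len(L)) gOuts[[l]] <- zero(g)
  gX0 <- zero(b$cin)

  addBlockOut <- function() {
    if (b$connection == "linear") {
      gOuts[[L]] <<- gOuts[[L]] + gout$a
    } else if (b$connection == "dense") {
      parts <- .splitRows(gout$a, c(b$cin, rep(g, L)))
      gX0 <<- gX0 + parts[[1L]]
      for (l in seq_len(L)) gOuts[[l]] <<- gOuts[[l]] + parts[[l + 1L]]
    } else {
      if (L == 1L) gOuts[[1L]] <<- gOuts[[1L]] + gout$a
      else {
        parts <- .splitRows(gout$a, c(g, g))
        gOuts[[L - 1L]] <<- gOuts[[L - 1L]] + parts[[1L]]
        gOuts[[L]] <<- gOuts[[L]] + parts[[2L]]
      }
    }
  }
  addBlockOut()

  for (l in rev(seq_len(L))) {
    gin <- .unitBackward(b$units[[l]], .act(gOuts[[l]], dims))
    if (b$connection == "linear") {
      if (l == 1L) gX0 <- gX0 + gin$a
      else gOuts[[l - 1L]] <- gOuts[[l - 1L]] + gin$a
    } else if (b$connection == "dense") {
      if (l == 1L) gX0 <- gX0 + gin$a
      else {
        parts <- .splitRows(gin$a, c(b$cin, rep(g, l - 1L)))
        gX0 <- gX0 + parts[[1L]]
        for (j in seq_len(l - 1L)) gOuts[[j]] <- gOuts[[j]] + parts[[j + 1L]]
      }
    } else {
      if (l == 1L) gX0 <- gX0 + gin$a
      else if (l == 2L) {
        parts <- .splitRows(gin$a, c(b$cin, g))
        gX0 <- gX0 + parts[[1L]]
        gOuts[[1L]] <- gOuts[[1L]] + parts[[2L]]
      } else {
        parts <- .splitRows(gin$a, c(g, g))
        gOuts[[l - 1L]] <- gOuts[[l - 1L]] + parts[[1L]]
        gOuts[[l - 2L]] <- gOuts[[l - 2L]] + parts[[2L]]
      }
    }
  }
  .act(gX0, dims)
}

## softmax over the class (row) dimension
.softmax <- function(z) {
  zmax <- if (nrow(z) == 2L) pmax(z[1L, ], z[2L, ]) else apply(z, 2, max)
  e <- exp(sweep(z, 2, zmax))
  sweep(e, 2, colSums(e), `/`)
}

## gradient wrt logits given gradient wrt probabilities
.softmaxBackward <- function(p, gp) {
  dot <- colSums(p * gp)
  p * sweep(gp, 2, dot)
}

#' Build the segmentation generator
#'
#' Constructs the trainable network described by a [generatorConfig()].
#' A forward pass (see [genForward()]) maps a single-channel patch to two
#' per-voxel class-probability maps of the input's spatial size: the main
#' head (after the deep stage and upsampling) and the deep-supervision head
#' (directly off the shallow stage).
#'
#' @param cfg a [generatorConfig()] list.
#' @param seed integer seed for weight initialization.
#' @return a [Network3D] of kind "generator".
#' @export
buildGenerator <- function(cfg = generatorConfig(), seed = 1L) {
  e <- new.env(parent = emptyenv())
  .withSeed(seed, {
    f0 <- cfg$inFilters
    e$transition <- .newConv(1L, f0, k = 3L, stride = 1L, pad = 1L)
    e$stage1 <- .newBlock(cfg$stages[[1]], f0, order = "pre")
    c1 <- .blockOutChannels(cfg$stages[[1]], f0)
    e$down <- .newUnit(c1, c1, order = "pre", k = 3L, stride = 2L, pad = 1L)
    e$stage2 <- .newBlock(cfg$stages[[2]], c1, order = "pre")
    c2 <- .blockOutChannels(cfg$stages[[2]], c1)
    e$up <- .newConvT2(c2, cfg$upFilters)
    e$headMain <- list(bn = .newBN(cfg$upFilters), act = .newAct("relu"),
                       conv = .newConv(cfg$upFilters, cfg$nClasses, k = 1L,
                                       stride = 1L, pad = 0L))
    e$headDs <- list(bn = .newBN(c1), act = .newAct("relu"),
                     conv = .newConv(c1, cfg$nClasses, k = 1L, stride = 1L,
                                     pad = 0L))
  })
  e$params <- .collectLayers(list(e$transition, e$stage1$units,
                                  e$down, e$stage2$units, e$up,
                                  e$headMain, e$headDs))
  new("Network3D", kind = "generator", config = cfg, env = e)
}

.headForward <- function(h, x, train = TRUE) {
  y <- .bnForward(h$bn, x, train)
  y <- .actForward(h$act, y, train)
  z <- .convForward(h$conv, y, train)
  .act(.softmax(z$a), z$dims)
}

.headBackward <- function(h, p, gp, dims) {
  gz <- .softmaxBackward(p, gp)
  g <- .convBackward(h$conv, .act(gz, dims))
  g <- .actBackward(h$act, g)
  .bnBackward(h$bn, g)
}

#' Generator forward pass
#'
#' @param net a generator [Network3D].
#' @param patch 3D array (or `Volume3D`) of raw intensities.
#' @param train logical; TRUE stores caches for backprop and uses batch
#'   statistics in batch norm, FALSE uses running statistics.
#' @return list with `main` and `ds` (class x voxel probability matrices,
#'   rows = (background, foreground)), and `dims`.
#' @export
genForward <- function(net, patch, train = TRUE) {
  stopifnot(is(net, "Network3D"), net@kind == "generator")
  if (is(patch, "Volume3D")) patch <- patch@values
  dims <- dim(patch)
  if (any(dims %% 2L != 0L))
    stop("generator input dimensions must be even (one stride-2 stage)")
  e <- net@env
  x <- .act(matrix(as.numeric(patch), 1L, prod(dims)), dims)
  t0 <- .convForward(e$transition, x, train)
  s1 <- .blockForward(e$stage1, t0, train)
  pDs <- .headForward(e$headDs, s1, train)
  dn <- .unitForward(e$down, s1, train)
  s2 <- .blockForward(e$stage2, dn, train)
  up <- .convT2Forward(e$up, s2, train)
  pMain <- .headForward(e$headMain, up, train)
  if (train) e$cache <- list(pMain = pMain, pDs = pDs, dims = dims)
  list(main = pMain$a, ds = pDs$a, dims = dims)
}

#' Generator backward pass
#'
#' Accumulates parameter gradients from gradients with respect to the two
#' heads' probability maps (as produced by the loss functions).
#'
#' @param net a generator [Network3D] that has run [genForward()] with
#'   `train = TRUE`.
#' @param gMain,gDs gradients wrt the main / deep-supervision probability
#'   maps (class x voxel); `gDs = NULL` skips the branch.
#' @export
genBackward <- function(net, gMain, gDs = NULL) {
  e <- net@env
  cc <- e$cache
  dims <- cc$dims
  gUp <- .headBackward(e$headMain, cc$pMain$a, gMain, dims)
  gS2 <- .convT2Backward(e$up, gUp)
  gDn <- .blockBackward(e$stage2, gS2)
  gS1 <- .unitBackward(e$down, gDn)
  if (!is.null(gDs)) {
    gS1ds <- .headBackward(e$headDs, cc$pDs$a, gDs, dims)
    gS1$a <- gS1$a + gS1ds$a
  }
  gT0 <- .blockBackward(e$stage1, gS1)
  invisible(.convBackward(e$transition, gT0))
}

#' Build a discriminator
#'
#' @param cfg a [discriminatorConfig()] list.
#' @param inChannels channels of the discriminator input (1: the raw-patch
#'   times probability-map product).
#' @param seed integer seed for weight initialization.
#' @return a [Network3D] of kind "discriminator".
#' @export
buildDiscriminator <- function(cfg = discriminatorConfig("voxel"),
                               inChannels = 1L, seed = 1L) {
  e <- new.env(parent = emptyenv())
  .withSeed(seed, {
    cin <- as.integer(inChannels)
    e$units <- list()
    for (ls in cfg$layers) {
      e$units[[length(e$units) + 1L]] <-
        .newUnit(cin, ls$filters, order = "post", k = ls$kernel,
                 stride = ls$stride, pad = if (ls$kernel > 1L) 1L else 0L,
                 slope = 0.2, bn = cfg$bn)
      cin <- ls$filters
    }
    e$score <- .newConv(cin, 1L, k = 1L, stride = 1L, pad = 0L)
  })
  e$params <- .collectLayers(list(e$units, e$score))
  new("Network3D", kind = "discriminator", config = cfg, env = e)
}

#' Discriminator forward / backward
#'
#' `discForward` maps an input patch to per-voxel scores in \[0, 1\]
#' (sigmoid of the terminal 1-filter convolution); the voxel kind preserves
#' the spatial shape, the patch/volume kinds downsample by their stride-2
#' stacks. `discBackward` propagates a gradient with respect to the scores
#' back to the input (accumulating parameter gradients on the way).
#'
#' @param net a discriminator [Network3D].
#' @param patch 3D array (single channel) or an activation list.
#' @param train logical, as in [genForward()].
#' @return `discForward`: list(`scores` = 1 x V' matrix, `dims` = output
#'   spatial dims); `discBackward`: gradient wrt the input as a 3D array.
#' @export
discForward <- function(net, patch, train = TRUE) {
  stopifnot(is(net, "Network3D"), net@kind == "discriminator")
  e <- net@env
  x <- if (is.list(patch) && !is.null(patch$a)) patch
       else .act(matrix(as.numeric(patch), 1L, length(patch)), dim(patch))
  h <- x
  for (u in e$units) h <- .unitForward(u, h, train)
  z <- .convForward(e$score, h, train)
  s <- 1 / (1 + exp(-z$a))
  if (train) e$cache <- list(s = s, dims = z$dims, inDims = x$dims)
  list(scores = s, dims = z$dims)
}

#' @rdname discForward
#' @param gScores gradient wrt the scores (1 x V' matrix).
#' @export
discBackward <- function(net, gScores) {
  e <- net@env
  cc <- e$cache
  gz <- gScores * cc$s * (1 - cc$s)
  g <- .convBackward(e$score, .act(gz, cc$dims))
  for (u in rev(e$units)) g <- .unitBackward(u, g)
  array(g$a, dim = cc$inDims)
}

#' Receptive-field side length of an isotropic convolution stack
#'
#' `RF = 1 + sum_i (k_i - 1) * prod_{j < i} s_j` for layers applied in
#' order with kernel `k_i` and stride `s_i`.
#'
#' @param layers a list of `c(kernel, stride)` pairs, a 2-column matrix, or
#'   a [discriminatorConfig()] list.
#' @return receptive-field side length in voxels.
#' @examples
#' receptiveField(list(c(3, 2), c(3, 2), c(3, 2)))  # 15
#' receptiveField(discriminatorConfig("volume"))    # 63
#' @export
receptiveField <- function(layers) {
  if (is.list(layers) && !is.null(layers$layers))
    layers <- lapply(layers$layers, function(l) c(l$kernel, l$stride))
  if (is.matrix(layers))
    layers <- lapply(seq_len(nrow(layers)), function(i) layers[i, ])
  if (length(layers) == 0L) stop("empty layer list")
  rf <- 1
  jump <- 1
  for (ks in layers) {
    rf <- rf + (ks[1] - 1) * jump
    jump <- jump * ks[2]
  }
  rf
}

#' Empirical receptive-field probe
#'
#' Builds the given discriminator trunk without batch normalization (batch
#' statistics would couple voxels and mask the architectural footprint),
#' runs one forward/backward pass from a single central output score, and
#' measures the bounding-box side of input voxels with nonzero gradient.
#' Leaky activations keep gradients nonzero almost surely, so the footprint
#' equals the architectural receptive field when it fits in the input.
#'
#' @param cfg a [discriminatorConfig()] list.
#' @param inputDim input side length; default comfortably exceeds the
#'   calculated receptive field.
#' @param seed seed for weights and the probe input.
#' @return measured footprint side length (max over axes).
#' @export
receptiveFieldProbe <- function(cfg, inputDim = NULL, seed = 1L) {
  rf <- receptiveField(cfg)
  if (is.null(inputDim)) inputDim <- rf + 2 * prod(vapply(
    cfg$layers, function(l) l$stride, numeric(1)))
  cfg$bn <- FALSE
  net <- buildDiscriminator(cfg, seed = seed)
  x <- .withSeed(seed, array(stats::rnorm(inputDim^3),
                             dim = rep(inputDim, 3)))
  fw <- discForward(net, x, train = TRUE)
  gs <- matrix(0, 1, prod(fw$dims))
  center <- floor(fw$dims / 2) + 1L
  gs[1, center[1] + fw$dims[1] * ((center[2] - 1L) +
       fw$dims[2] * (center[3] - 1L))] <- 1
  gin <- discBackward(net, gs)
  hit <- which(abs(gin) > 0, arr.ind = TRUE)
  max(apply(hit, 2, function(i) diff(range(i)) + 1L))
}

#' Channel-diversity histogram of a feature stack
#'
#' Computes the per-voxel standard deviation across channels of a feature
#' stack shaped `[H, W, D, C]` (population convention) and histograms it
#' over the given bins. Low SD indicates redundant (strongly regularized)
#' channels; high SD indicates diversified features.
#'
#' @param features 4D numeric array `[H, W, D, C]` with `C >= 2`.
#' @param breaks histogram breaks (count or vector), as in
#'   [graphics::hist()].
#' @return list with `sdMap` (3D array), `breaks`, `counts`, and `meanSd`.
#' @export
diversityHistogram <- function(features, breaks = 30) {
  stopifnot(length(dim(features)) == 4L)
  C <- dim(features)[4]
  if (C < 2L) stop("need at least 2 channels to measure diversity")
  if (!all(is.finite(features))) stop("features must be finite")
  mu <- apply(features, 1:3, mean)
  sdMap <- sqrt(apply(features^2, 1:3, mean) - mu^2)
  sdMap[sdMap < 0] <- 0    # numerical guard
  h <- graphics::hist(sdMap, breaks = breaks, plot = FALSE)
  list(sdMap = sdMap, breaks = h$breaks, counts = h$counts,
       meanSd = mean(sdMap))
}

#' Extract a generator block's activations as a feature stack
#'
#' Runs a forward pass in eval mode and returns the requested stage's block
#' output as an `[H, W, D, C]` array, suitable for [diversityHistogram()].
#'
#' @param net a generator [Network3D].
#' @param patch 3D array or [Volume3D].
#' @param stage 1 (shallow, full resolution) or 2 (deep, half resolution).
#' @param output "block" returns the block's output concatenation;
#'   "layers" stacks the outputs of every layer in the block (the same
#'   channel count for any connection rule with equal depth and growth,
#'   which makes diversity comparisons across connection types fair).
#' @return 4D array `[H, W, D, C]`.
#' @export
blockActivations <- function(net, patch, stage = 1L,
                             output = c("block", "layers")) {
  stopifnot(is(net, "Network3D"), net@kind == "generator")
  output <- match.arg(output)
  if (is(patch, "Volume3D")) patch <- patch@values
  dims <- dim(patch)
  e <- net@env
  x <- .act(matrix(as.numeric(patch), 1L, prod(dims)), dims)
  t0 <- .convForward(e$transition, x, train = FALSE)
  blk <- e$stage1
  s1 <- .blockForward(blk, t0, train = FALSE)
  out <- if (stage == 1L) s1 else {
    blk <- e$stage2
    dn <- .unitForward(e$down, s1, train = FALSE)
    .blockForward(blk, dn, train = FALSE)
  }
  if (output == "layers")
    out <- .act(do.call(rbind, lapply(blk$outs, `[[`, "a")), out$dims)
  aperm(array(out$a, dim = c(nrow(out$a), out$dims)), c(2, 3, 4, 1))
}

#' Snapshot a network's parameters
#'
#' Returns a plain list of parameter arrays, usable for equality checks
#' (freezing contracts) and external checkpointing. `what = "trainable"`
#' (default) covers convolution weights/biases and batch-norm scale/shift
#' — the quantities an optimizer updates; `what = "all"` additionally
#' includes batch-norm running statistics.
#'
#' @param net a [Network3D].
#' @param what "trainable" or "all".
#' @return list of numeric arrays.
#' @export
networkParameters <- function(net, what = c("trainable", "all")) {
  what <- match.arg(what)
  dump <- .dumpParams(net@env$params)
  if (what == "trainable")
    dump <- lapply(dump, function(d) d[setdiff(names(d), "rstats")])
  dump
}
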
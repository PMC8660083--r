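#' Training configuration
#'
#' Defaults reproduce the method's reference regime: initial learning rate 0.001
#' decaying by 10\% every 5 epochs, moment parameters (0.9, 0.999), 40
#' epochs. Because beta pairs parameterize adaptive-moment optimizers, the
#' default optimizer is Adam with those betas; plain momentum SGD is
#' available via `optimizer = "sgd"`.
#'
#' @param lr0 initial learning rate.
#' @param decay decay factor per period.
#' @param decayEvery epochs per decay period.
#' @param betas moment parameters.
#' @param optimizer "adam" (default) or "sgd".
#' @param epochs training epochs.
#' @param batchSize patches per optimization step.
#' @param patchSize training patch side(s), voxels.
#' @param overlap tiling overlap for training volumes.
#' @param seed master seed: weight init, shuffling and noise all derive
#'   from it.
#' @param mode "adversarial" or "generator_only" (CE+Dice ablation; stage 2
#'   is skipped and the adversarial weight is forced to 0).
#' @param discKind discriminator kind for adversarial mode.
#' @param discNoiseSd SD of the fresh Gaussian noise put on raw patches
#'   entering the discriminator, as a fraction of the per-patch SD
#'   (guards against degenerate distributions).
#' @return a [TrainConfig].
#' @export
trainConfig <- function(lr0 = 0.001, decay = 0.9, decayEvery = 5,
                        betas = c(0.9, 0.999), optimizer = "adam",
                        epochs = 40, batchSize = 2,
                        patchSize = c(64, 64, 64), overlap = c(0, 0, 0),
                        seed = 1L, mode = "adversarial",
                        discKind = "voxel", discNoiseSd = 0.1) {
  new("TrainConfig", lr0 = lr0, decay = decay, decayEvery = decayEvery,
      betas = betas, optimizer = optimizer, epochs = epochs,
      batchSize = batchSize,
      patchSize = as.integer(rep(patchSize, length.out = 3)),
      overlap = as.integer(rep(overlap, length.out = 3)),
      seed = as.integer(seed), mode = mode, discKind = discKind,
      discNoiseSd = discNoiseSd)
}

#' Learning rate at a given epoch
#'
#' `lr0 * decay^floor(epoch / decayEvery)` with 0-based epochs: piecewise
#' constant, non-increasing, one decay step per period.
#'
#' @param epoch 0-based epoch index.
#' @param cfg a [TrainConfig].
#' @return the learning rate.
#' @examples
#' lrAt(0, trainConfig())   # 0.001
#' lrAt(5, trainConfig())   # 0.0009
#' lrAt(12, trainConfig())  # 0.00081
#' @export
lrAt <- function(epoch, cfg = trainConfig()) {
  stopifnot(epoch >= 0)
  cfg@lr0 * cfg@decay^floor(epoch / cfg@decayEvery)
}

## fresh per-patch discriminator noise (uses the current RNG stream)
.discNoisy <- function(x, cfg) {
  sdx <- stats::sd(as.numeric(x))
  if (!is.finite(sdx) || sdx == 0) sdx <- 1
  x + array(stats::rnorm(length(x), sd = cfg@discNoiseSd * sdx), dim(x))
}

#' One two-stage training iteration
#'
#' Stage 1 updates only the generator: CE + (1 - Dice) on both heads plus
#' the adversarial term computed through the frozen discriminator on the
#' product of a freshly noised raw patch and the predicted foreground map.
#' Stage 2 updates only the discriminator: focal loss driving scores on
#' (noisy raw x prediction) to 0 and on (noisy raw x ground truth) to 1,
#' with the generator frozen (its stage-2 forward runs in eval mode).
#' Gradients are averaged over the batch. Randomness (discriminator noise)
#' is drawn from the ambient RNG stream, so a fixed seed fixes the whole
#' trace.
#'
#' @param gen generator [Network3D].
#' @param disc discriminator [Network3D] or NULL in generator-only mode.
#' @param batch list of `list(x = 3D array, y = 3D binary array)`.
#' @param cfg a [TrainConfig].
#' @param lossCfg a [LossConfig].
#' @param lr learning rate for this step.
#' @param stages which stages to run; default both. Running a single stage
#'   exposes the freezing contract: stage 1 never touches discriminator
#'   state, stage 2 never touches generator state.
#' @return named list of per-term losses (batch means).
#' @export
trainStep <- function(gen, disc, batch, cfg, lossCfg = lossConfig(),
                      lr = cfg@lr0,
                      stages = c("generator", "discriminator")) {
  adversarial <- cfg@mode == "adversarial"
  if (adversarial && (is.null(disc) || cfg@discKind == "none"))
    stop("adversarial mode requires a discriminator (discKind != 'none')")
  if (!adversarial) lossCfg@advWeight <- 0
  N <- length(batch)
  e <- gen@env
  if (is.null(e$opt))
    e$opt <- .newOptimizer(e$params, cfg@optimizer, cfg@betas)
  if (adversarial && is.null(disc@env$opt))
    disc@env$opt <- .newOptimizer(disc@env$params, cfg@optimizer, cfg@betas)

  ## --- stage 1: generator update, discriminator frozen ---
  terms <- c(ce = NA_real_, dice = NA_real_, adv = NA_real_,
             ds = NA_real_, g_total = NA_real_)
  if ("generator" %in% stages) {
  .zeroGrads(e$params)
  if (adversarial) .zeroGrads(disc@env$params)
  terms <- c(ce = 0, dice = 0, adv = 0, ds = 0, g_total = 0)
  for (s in batch) {
    fw <- genForward(gen, s$x, train = TRUE)
    Y <- asTargetMap(s$y)
    Sfake <- NULL
    noisy <- NULL
    if (adversarial && lossCfg@advWeight != 0) {
      noisy <- .discNoisy(s$x, cfg)
      dfw <- discForward(disc, makeDiscInput(noisy, fw$main), train = TRUE)
      Sfake <- dfw$scores
    }
    ls <- generatorLoss(fw$main, Y, Sfake, lossCfg, Pds = fw$ds)
    terms <- terms + c(ls$ce, ls$dice, ls$adv, ls$ds, ls$total)

    gP <- .ceGrad(fw$main, Y, lossCfg) - .diceGrad(fw$main, Y, lossCfg)
    if (!is.null(Sfake)) {
      V <- length(Sfake)
      gS <- if (lossCfg@advForm == "minimax")
        -.focalGrad(Sfake, 0, lossCfg) / V
      else .focalGrad(Sfake, 1, lossCfg) / V
      gS <- lossCfg@advWeight * gS
      gin <- discBackward(disc, matrix(gS, nrow = 1))
      gP[2, ] <- gP[2, ] + as.numeric(gin) * as.numeric(noisy)
    }
    gPds <- lossCfg@dsWeight *
      (.ceGrad(fw$ds, Y, lossCfg) - .diceGrad(fw$ds, Y, lossCfg))
    genBackward(gen, gP, gPds)
  }
  .scaleGrads(e$params, 1 / N)
  .optStep(e$opt, e$params, lr)
  terms <- terms / N
  }

  ## --- stage 2: discriminator update, generator frozen ---
  dTerms <- c(d_fake = NA_real_, d_real = NA_real_, d_total = NA_real_)
  if (adversarial && "discriminator" %in% stages) {
    .zeroGrads(disc@env$params)
    acc <- c(0, 0, 0)
    for (s in batch) {
      fw <- genForward(gen, s$x, train = FALSE)   # frozen generator
      noisy <- .discNoisy(s$x, cfg)
      fake <- makeDiscInput(noisy, fw$main)
      dfw <- discForward(disc, fake, train = TRUE)
      Vf <- length(dfw$scores)
      gSf <- .focalGrad(dfw$scores, 0, lossCfg) / Vf
      lf <- focalLoss(dfw$scores, 0, lossCfg) / Vf
      discBackward(disc, matrix(gSf, nrow = 1))
      real <- makeDiscInput(noisy, s$y)
      drw <- discForward(disc, real, train = TRUE)
      Vr <- length(drw$scores)
      gSr <- .focalGrad(drw$scores, 1, lossCfg) / Vr
      lrl <- focalLoss(drw$scores, 1, lossCfg) / Vr
      discBackward(disc, matrix(gSr, nrow = 1))
      acc <- acc + c(lf, lrl, lf + lrl)
    }
    .scaleGrads(disc@env$params, 1 / N)
    .optStep(disc@env$opt, disc@env$params, lr)
    dTerms <- acc / N
    names(dTerms) <- c("d_fake", "d_real", "d_total")
  }
  as.list(c(terms, dTerms))
}

## tile training volumes into (x, y) patch samples
.makeSamples <- function(trainVolumes, cfg) {
  samples <- list()
  for (tv in trainVolumes) {
    vol <- normalizeVolume(tv$volume)
    grid <- planPatchGrid(dim(vol@values), cfg@patchSize, cfg@overlap)
    px <- extractPatches(vol, grid)
    py <- extractPatches(tv$label, grid)
    for (i in seq_along(px@patches))
      samples[[length(samples) + 1L]] <-
        list(x = px@patches[[i]], y = py@patches[[i]])
  }
  if (!any(vapply(samples, function(s) any(s$y > 0), logical(1))))
    warning("no foreground voxels in any training patch; ",
            "the task is degenerate")
  samples
}

.snapshot <- function(gen, disc) {
  list(gen = .dumpParams(gen@env$params),
       genOpt = if (!is.null(gen@env$opt))
         list(t = gen@env$opt$t, state = gen@env$opt$state),
       disc = if (!is.null(disc)) .dumpParams(disc@env$params),
       discOpt = if (!is.null(disc) && !is.null(disc@env$opt))
         list(t = disc@env$opt$t, state = disc@env$opt$state))
}

.restoreSnapshot <- function(gen, disc, snap, cfg) {
  .loadParams(gen@env$params, snap$gen)
  if (!is.null(snap$genOpt)) {
    gen@env$opt <- .newOptimizer(gen@env$params, cfg@optimizer, cfg@betas)
    gen@env$opt$t <- snap$genOpt$t
    gen@env$opt$state <- snap$genOpt$state
  }
  if (!is.null(disc) && !is.null(snap$disc)) {
    .loadParams(disc@env$params, snap$disc)
    if (!is.null(snap$discOpt)) {
      disc@env$opt <- .newOptimizer(disc@env$params, cfg@optimizer,
                                    cfg@betas)
      disc@env$opt$t <- snap$discOpt$t
      disc@env$opt$state <- snap$discOpt$state
    }
  }
  invisible(NULL)
}

.trainEpochs <- function(gen, disc, samples, cfg, lossCfg, epochSeq) {
  history <- list()
  checkpoints <- list()
  step <- 0L
  for (epoch in epochSeq) {
    checkpoints[[as.character(epoch)]] <-
      list(epoch = epoch, step = step, rng = .Random.seed,
           snapshot = .snapshot(gen, disc))
    lr <- lrAt(epoch, cfg)
    ord <- sample(length(samples))
    starts <- seq(1, length(samples), by = cfg@batchSize)
    for (b in starts) {
      idx <- ord[b:min(b + cfg@batchSize - 1, length(samples))]
      losses <- trainStep(gen, disc, samples[idx], cfg, lossCfg, lr)
      step <- step + 1L
      history[[length(history) + 1L]] <-
        c(list(epoch = epoch, step = step, lr = lr), losses)
    }
  }
  list(history = do.call(rbind, lapply(history, as.data.frame)),
       checkpoints = checkpoints)
}

#' Train a segmentation model on labeled volumes
#'
#' Normalizes each training volume, tiles it into patches, and runs the
#' two-stage adversarial loop (or the generator-only CE+Dice ablation) for
#' `cfg@epochs` epochs over all patches, shuffled each epoch, with the
#' scheduled learning rate. A checkpoint (parameters, optimizer state, RNG
#' state) is recorded at the start of every epoch, making training
#' resumable and exactly replayable via [resumeFit()].
#'
#' @param trainVolumes list of `list(volume = Volume3D, label =
#'   LabelVolume)`.
#' @param cfg a [TrainConfig].
#' @param genConfig a [generatorConfig()].
#' @param lossCfg a [LossConfig]; defaults to `lossConfig()`.
#' @return an object of class `vansegFit`: list with `generator`,
#'   `discriminator`, `history` (one row per step with every loss term),
#'   `checkpoints`, and the configurations.
#' @export
fitModel <- function(trainVolumes, cfg = trainConfig(),
                     genConfig = generatorConfig(),
                     lossCfg = lossConfig()) {
  if (length(trainVolumes) < 1) stop("need at least one training volume")
  if (cfg@mode == "generator_only") lossCfg@advWeight <- 0
  res <- .withSeed(cfg@seed, {
    gen <- buildGenerator(genConfig,
                          seed = sample.int(.Machine$integer.max, 1))
    disc <- NULL
    discCfg <- NULL
    if (cfg@mode == "adversarial") {
      if (cfg@discKind == "none")
        stop("adversarial mode requires discKind of voxel/patch/volume")
      discCfg <- discriminatorConfig(cfg@discKind)
      disc <- buildDiscriminator(discCfg,
                                 seed = sample.int(.Machine$integer.max, 1))
    }
    samples <- .makeSamples(trainVolumes, cfg)
    tr <- .trainEpochs(gen, disc, samples, cfg, lossCfg,
                       seq_len(cfg@epochs) - 1L)
    gen@env$trainPatchSize <- cfg@patchSize
    gen@env$trainOverlap <- cfg@overlap
    list(generator = gen, discriminator = disc, history = tr$history,
         checkpoints = tr$checkpoints, cfg = cfg, genConfig = genConfig,
         discConfig = discCfg, lossCfg = lossCfg)
  })
  class(res) <- "vansegFit"
  res
}

#' Resume training from a recorded checkpoint
#'
#' Restores parameters, optimizer state and RNG state from a checkpoint of
#' a [fitModel()] result and replays the remaining epochs on the same
#' training volumes. With unchanged inputs the replayed loss history is
#' identical to the original run's.
#'
#' @param fit a `vansegFit` object.
#' @param fromEpoch 0-based epoch whose checkpoint to restart from.
#' @param trainVolumes the training volumes originally used.
#' @return a `vansegFit` covering epochs `fromEpoch ..
#'   cfg@epochs - 1`.
#' @export
resumeFit <- function(fit, fromEpoch, trainVolumes) {
  cfg <- fit$cfg
  ck <- fit$checkpoints[[as.character(fromEpoch)]]
  if (is.null(ck)) stop("no checkpoint for epoch ", fromEpoch)
  gen <- buildGenerator(fit$genConfig, seed = 1L)
  disc <- if (!is.null(fit$discConfig))
    buildDiscriminator(fit$discConfig, seed = 1L)
  .restoreSnapshot(gen, disc, ck$snapshot, cfg)
  samples <- .makeSamples(trainVolumes, cfg)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv())
  assign(".Random.seed", ck$rng, envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  tr <- .trainEpochs(gen, disc, samples, cfg, fit$lossCfg,
                     fromEpoch:(cfg@epochs - 1L))
  gen@env$trainPatchSize <- cfg@patchSize
  gen@env$trainOverlap <- cfg@overlap
  res <- list(generator = gen, discriminator = disc,
              history = tr$history, checkpoints = tr$checkpoints,
              cfg = cfg, genConfig = fit$genConfig,
              discConfig = fit$discConfig, lossCfg = fit$lossCfg)
  class(res) <- "vansegFit"
  res
}

#' @describeIn predictVolume patch-wise inference with a trained generator:
#'   normalize, tile, predict each patch in eval mode, take per-voxel
#'   argmax (ties to foreground), stitch by majority vote.
#' @export
setMethod("predictVolume", "Network3D",
  function(model, vol, patchSize = NULL, overlap = NULL,
           tie = "foreground") {
    stopifnot(model@kind == "generator")
    if (is.null(patchSize)) patchSize <- model@env$trainPatchSize
    if (is.null(patchSize))
      stop("patchSize not given and the model records none")
    if (is.null(overlap)) overlap <- model@env$trainOverlap %||% c(0, 0, 0)
    nv <- normalizeVolume(vol)
    grid <- planPatchGrid(dim(nv@values), patchSize, overlap)
    px <- extractPatches(nv, grid)
    labels <- lapply(px@patches, function(p) {
      fw <- genForward(model, p, train = FALSE)
      array((fw$main[2, ] >= fw$main[1, ]) * 1, dim = dim(p))
    })
    ps <- new("PatchSet", grid = grid, patches = labels, noisy = FALSE)
    stitchMajority(ps, grid, tie = tie, spacing = vol@spacing,
                   origin = vol@origin)
  })

#' @describeIn predictVolume a plain function used as a model: it receives
#'   the normalized volume and must return a [LabelVolume] (oracle or
#'   thresholding stand-ins).
#' @export
setMethod("predictVolume", "function",
  function(model, vol, ...) {
    out <- model(normalizeVolume(vol))
    stopifnot(is(out, "LabelVolume"))
    out
  })
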
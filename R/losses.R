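#' Loss configuration
#'
#' @param gamma focal decay exponent; the method's standard value is 4.
#' @param dsWeight deep-supervision weight (default 0.5).
#' @param advWeight adversarial-term weight (default 1).
#' @param eps smoothing constant for logs and Dice denominators.
#' @param classReduction "mean" (default; keeps soft Dice in \[0, 1\]) or
#'   "foreground_only".
#' @param focalForm "pt" (canonical modulation of the true-target
#'   probability, default) or "printed" (literal `(1 - S)^gamma` factor).
#' @param advForm "minimax" (default) or "nonsaturating".
#' @return a [LossConfig].
#' @export
lossConfig <- function(gamma = 4, dsWeight = 0.5, advWeight = 1,
                       eps = 1e-7, classReduction = "mean",
                       focalForm = "pt", advForm = "minimax") {
  new("LossConfig", gamma = gamma, dsWeight = dsWeight,
      advWeight = advWeight, eps = eps, classReduction = classReduction,
      focalForm = focalForm, advForm = advForm)
}

#' Probability and one-hot target maps
#'
#' Losses operate on class-by-voxel matrices with rows (background,
#' foreground). `asProbMap` lifts a foreground-probability array to that
#' form; `asTargetMap` one-hot-encodes a binary label array or
#' [LabelVolume].
#'
#' @param fg array/vector of foreground probabilities in \[0, 1\].
#' @param labels binary array, vector, or [LabelVolume].
#' @return a 2 x V numeric matrix.
#' @export
asProbMap <- function(fg) {
  fg <- as.numeric(if (is(fg, "Volume3D")) fg@values else fg)
  rbind(1 - fg, fg)
}

#' @rdname asProbMap
#' @export
asTargetMap <- function(labels) {
  y <- as.numeric(if (is(labels, "Volume3D")) labels@values else labels)
  if (!all(y %in% c(0, 1))) stop("labels must be binary")
  rbind(1 - y, y)
}

.checkPY <- function(P, Y) {
  if (!identical(dim(P), dim(Y)))
    stop("probability and target maps must have identical shapes")
}

#' Cross-entropy over a patch
#'
#' `-sum_c sum_v y_cv * log(p_cv + eps)`: summed over both classes and all
#' voxels, non-negative, and zero (up to eps) iff the prediction is the
#' one-hot truth.
#'
#' @param P,Y class x voxel matrices (see [asProbMap()]).
#' @param cfg a [LossConfig].
#' @return scalar loss.
#' @export
crossEntropy <- function(P, Y, cfg = lossConfig()) {
  .checkPY(P, Y)
  -sum(Y * log(P + cfg@eps))
}

.ceGrad <- function(P, Y, cfg) -Y / (P + cfg@eps)

#' Soft Dice coefficient
#'
#' Per class `c`: `(2 * sum_v p_cv y_cv + eps) / (sum_v p_cv^2 +
#' sum_v y_cv^2 + eps)` (squared denominators), reduced over the two
#' classes by `cfg@classReduction`. Perfect binary overlap gives 1 and
#' fully disjoint binary maps give 0; training minimizes `1 - DC`.
#'
#' @inheritParams crossEntropy
#' @return scalar in \[0, 1\].
#' @export
diceCoeff <- function(P, Y, cfg = lossConfig()) {
  .checkPY(P, Y)
  eps <- cfg@eps
  perClass <- vapply(seq_len(nrow(P)), function(c) {
    num <- 2 * sum(P[c, ] * Y[c, ]) + eps
    den <- sum(P[c, ]^2) + sum(Y[c, ]^2) + eps
    num / den
  }, numeric(1))
  switch(cfg@classReduction,
         mean = mean(perClass),
         foreground_only = perClass[nrow(P)])
}

## gradient of diceCoeff wrt P
.diceGrad <- function(P, Y, cfg) {
  eps <- cfg@eps
  g <- 0 * P
  classes <- if (cfg@classReduction == "mean") seq_len(nrow(P))
             else nrow(P)
  w <- if (cfg@classReduction == "mean") 1 / nrow(P) else 1
  for (c in classes) {
    num <- 2 * sum(P[c, ] * Y[c, ]) + eps
    den <- sum(P[c, ]^2) + sum(Y[c, ]^2) + eps
    g[c, ] <- w * (2 * Y[c, ] * den - num * 2 * P[c, ]) / den^2
  }
  g
}

#' Focal loss over a score map
#'
#' Modulated binary cross-entropy summed over voxels. With the default
#' `"pt"` form, each voxel contributes `(1 - p_t)^gamma * (-log p_t)` where
#' `p_t` is the score assigned to the true target (`S` when `T = 1`,
#' `1 - S` when `T = 0`); `gamma = 0` recovers plain binary cross-entropy.
#' The `"printed"` form applies the factor `(1 - S)^gamma` irrespective of
#' target.
#'
#' @param S score matrix/vector in \[0, 1\].
#' @param T targets (scalar 0/1 or same shape as S).
#' @param cfg a [LossConfig].
#' @return scalar loss (sum over voxels).
#' @export
focalLoss <- function(S, T, cfg = lossConfig()) {
  if (length(T) == 1L) T <- array(T, dim = dim(as.array(S)) %||% length(S))
  S <- pmin(pmax(as.numeric(S), cfg@eps), 1 - cfg@eps)
  T <- as.numeric(T)
  g <- cfg@gamma
  if (cfg@focalForm == "pt") {
    pt <- T * S + (1 - T) * (1 - S)
    sum((1 - pt)^g * (-log(pt)))
  } else {
    bce <- -(T * log(S) + (1 - T) * log(1 - S))
    sum((1 - S)^g * bce)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## gradient of focalLoss wrt S (same conventions/clamping as focalLoss)
.focalGrad <- function(S, T, cfg) {
  dm <- dim(S)
  if (length(T) == 1L) T <- rep(T, length(S))
  Sc <- pmin(pmax(as.numeric(S), cfg@eps), 1 - cfg@eps)
  T <- as.numeric(T)
  g <- cfg@gamma
  out <- if (cfg@focalForm == "pt") {
    pt <- T * Sc + (1 - T) * (1 - Sc)
    dpt <- if (g == 0) -1 / pt
           else g * (1 - pt)^(g - 1) * log(pt) - (1 - pt)^g / pt
    dpt * (2 * T - 1)
  } else {
    bce <- -(T * log(Sc) + (1 - T) * log(1 - Sc))
    dbce <- -T / Sc + (1 - T) / (1 - Sc)
    mod <- if (g == 0) 0 else -g * (1 - Sc)^(g - 1) * bce
    mod + (1 - Sc)^g * dbce
  }
  out[as.numeric(S) <= cfg@eps | as.numeric(S) >= 1 - cfg@eps] <- 0
  if (!is.null(dm)) dim(out) <- dm
  out
}

#' Multiplicative discriminator input
#'
#' The discriminator never sees a probability or label map alone: its input
#' is the voxel-wise product of the (noisy) raw patch and the foreground
#' channel of either the generator's probability map (fake branch) or the
#' one-hot ground truth (real branch).
#'
#' @param raw 3D array (or [Volume3D]) of raw intensities.
#' @param fgMap foreground probabilities/labels, same voxel count (a
#'   class x voxel matrix is reduced to its foreground row).
#' @return 3D array, `raw * fgMap`.
#' @export
makeDiscInput <- function(raw, fgMap) {
  if (is(raw, "Volume3D")) raw <- raw@values
  if (is.matrix(fgMap) && nrow(fgMap) == 2L) fgMap <- fgMap[2L, ]
  if (is(fgMap, "Volume3D")) fgMap <- fgMap@values
  if (length(raw) != length(fgMap))
    stop("raw patch and map must have the same number of voxels")
  array(as.numeric(raw) * as.numeric(fgMap), dim = dim(raw))
}

#' Composite generator loss
#'
#' `CE + (1 - DC) + advWeight * adversarial + dsWeight * (CE_ds +
#' (1 - DC_ds))`. The adversarial term follows `cfg@advForm`: under
#' "minimax" it is `-FL(S_fake, T = 0)` (the generator maximizes the
#' discriminator's error on the fake branch), under "nonsaturating" it is
#' `+FL(S_fake, T = 1)`. Focal terms are averaged over score voxels so the
#' adversarial scale does not depend on the discriminator's output size.
#'
#' @param P,Y class x voxel matrices for the main head.
#' @param Sfake discriminator scores on `makeDiscInput(noisy raw, P)`;
#'   NULL for generator-only training.
#' @param cfg a [LossConfig].
#' @param Pds deep-supervision head probabilities (optional).
#' @return list with `ce`, `dice`, `adv`, `ds`, `total`.
#' @export
generatorLoss <- function(P, Y, Sfake = NULL, cfg = lossConfig(),
                          Pds = NULL) {
  ce <- crossEntropy(P, Y, cfg)
  dc <- diceCoeff(P, Y, cfg)
  adv <- 0
  if (!is.null(Sfake) && cfg@advWeight != 0) {
    V <- length(Sfake)
    adv <- if (cfg@advForm == "minimax")
      -focalLoss(Sfake, 0, cfg) / V
    else focalLoss(Sfake, 1, cfg) / V
    adv <- cfg@advWeight * adv
  }
  ds <- 0
  if (!is.null(Pds)) {
    ds <- cfg@dsWeight *
      (crossEntropy(Pds, Y, cfg) + (1 - diceCoeff(Pds, Y, cfg)))
  }
  list(ce = ce, dice = dc, adv = adv, ds = ds,
       total = ce + (1 - dc) + adv + ds)
}

#' Discriminator loss
#'
#' Focal loss pushing fake-branch scores toward 0 and real-branch scores
#' toward 1, each branch averaged over its voxels:
#' `FL(S_fake, 0)/V + FL(S_real, 1)/V`.
#'
#' @param Sfake scores on `makeDiscInput(noisy raw, P)`.
#' @param Sreal scores on `makeDiscInput(noisy raw, Y)`.
#' @param cfg a [LossConfig].
#' @return list with `fake`, `real`, `total`.
#' @export
discriminatorLoss <- function(Sfake, Sreal, cfg = lossConfig()) {
  fake <- focalLoss(Sfake, 0, cfg) / length(Sfake)
  real <- focalLoss(Sreal, 1, cfg) / length(Sreal)
  list(fake = fake, real = real, total = fake + real)
}
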
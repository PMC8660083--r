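#' @import methods
NULL

#' Spacing-aware 3D intensity volume
#'
#' `Volume3D` is the central container for a single-channel 3D image: a
#' numeric array of voxel intensities plus the physical voxel spacing (mm per
#' axis) and a world-space origin (mm). It corresponds to one TOF-MRA volume
#' (or one synthetic phantom).
#'
#' @slot values numeric 3D array of finite intensities.
#' @slot spacing numeric(3), mm per axis, all positive.
#' @slot origin numeric(3), mm offset of the first voxel's center.
#' @export
setClass("Volume3D",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("Volume3D", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "'values' must be a 3D array")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "'values' must be finite")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 positive numbers (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "'origin' must be 3 finite numbers (mm)")
  if (length(msg)) msg else TRUE
})

#' Binary label volume
#'
#' A [Volume3D] whose values are restricted to \{0, 1\}; used for ground-truth
#' annotations and stitched predictions (1 = vessel foreground).
#'
#' @export
setClass("LabelVolume", contains = "Volume3D")

setValidity("LabelVolume", function(object) {
  if (!all(object@values %in% c(0, 1)))
    "'values' must contain only 0 and 1" else TRUE
})

#' Deterministic overlapping-patch tiling plan
#'
#' Records how a volume is tiled into overlapping cubic patches: per-axis
#' patch counts, stride (= patch size minus overlap), the zero-padded shape
#' the grid actually covers, and the 0-based origin of every patch. Patches
#' are ordered row-major with the x index moving fastest.
#'
#' @slot volumeShape integer(3), voxels per axis of the original volume.
#' @slot patchSize integer(3), voxels per axis of each patch.
#' @slot overlap integer(3), voxels shared by adjacent patches per axis.
#' @slot stride integer(3), `patchSize - overlap`.
#' @slot counts integer(3), patches per axis.
#' @slot paddedShape integer(3), extent covered by the grid (>= volumeShape);
#'   padding is trailing (high-index) zeros only.
#' @slot patchOrigins integer matrix, one row per patch, 0-based offsets.
#' @export
setClass("PatchGrid",
  representation(volumeShape = "integer", patchSize = "integer",
                 overlap = "integer", stride = "integer", counts = "integer",
                 paddedShape = "integer", patchOrigins = "matrix"))

setValidity("PatchGrid", function(object) {
  msg <- character()
  if (any(object@stride < 1L)) msg <- c(msg, "stride must be >= 1 per axis")
  if (any(object@counts < 1L)) msg <- c(msg, "counts must be >= 1 per axis")
  if (any(object@paddedShape < object@volumeShape))
    msg <- c(msg, "paddedShape must cover volumeShape")
  if (nrow(object@patchOrigins) != prod(object@counts))
    msg <- c(msg, "patchOrigins must have one row per patch")
  if (length(msg)) msg else TRUE
})

#' Ordered set of patches extracted under a PatchGrid
#'
#' Holds the sub-volumes cut from a (zero-padded) volume in the grid's
#' row-major order, and whether they carry added noise (the "noisy raw patch"
#' role in adversarial training).
#'
#' @slot grid the [PatchGrid] the patches were cut under.
#' @slot patches list of 3D arrays, one per grid cell.
#' @slot noisy logical flag.
#' @export
setClass("PatchSet",
  representation(grid = "PatchGrid", patches = "list", noisy = "logical"),
  prototype(noisy = FALSE))

setValidity("PatchSet", function(object) {
  msg <- character()
  if (length(object@patches) != prod(object@grid@counts))
    msg <- c(msg, "patch list length must equal prod(counts)")
  ps <- object@grid@patchSize
  ok <- vapply(object@patches, function(p)
    identical(dim(p), as.integer(ps)), logical(1))
  if (!all(ok)) msg <- c(msg, "every patch must have dim == patchSize")
  if (length(msg)) msg else TRUE
})

#' Synthetic vascular phantom specification
#'
#' Declares the study conditions a phantom realizes: volume geometry, how
#' many vessel trees with how many branching generations, the radius range,
#' a monotone law mapping vessel radius to mean foreground intensity (the
#' flow-rate/intensity link of TOF-MRA), background level and texture, and
#' the foreground-fraction ceiling expressing the extreme class imbalance of
#' cerebrovascular data.
#'
#' @slot shape integer(3), voxels per axis (each >= 32).
#' @slot spacing numeric(3), mm per axis.
#' @slot nTrees number of vessel trees.
#' @slot branchDepth branching generations per tree.
#' @slot radiusRange numeric(2), min/max vessel radius in mm (min > 0).
#' @slot intensityLaw function(radius mm) -> mean foreground intensity;
#'   must be monotone non-decreasing.
#' @slot backgroundLevel baseline background intensity.
#' @slot backgroundTextureSd SD of the Gaussian background texture.
#' @slot targetFgFraction ceiling on the foreground voxel fraction, in
#'   (0, 0.01].
#' @slot seed integer RNG seed; identical (spec, seed) pairs generate
#'   bit-identical phantoms.
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", spacing = "numeric", nTrees = "integer",
                 branchDepth = "integer", radiusRange = "numeric",
                 intensityLaw = "function", backgroundLevel = "numeric",
                 backgroundTextureSd = "numeric", targetFgFraction = "numeric",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 32L))
    msg <- c(msg, "'shape' must be 3 integers, each >= 32")
  if (any(object@spacing <= 0)) msg <- c(msg, "'spacing' must be positive")
  if (object@radiusRange[1] <= 0)
    msg <- c(msg, "minimum radius must be > 0")
  if (object@radiusRange[2] < object@radiusRange[1])
    msg <- c(msg, "radiusRange must be (min, max) with max >= min")
  if (object@targetFgFraction <= 0 || object@targetFgFraction > 0.01)
    msg <- c(msg, "'targetFgFraction' must lie in (0, 0.01]")
  if (length(msg)) msg else TRUE
})

#' Additive Gaussian noise specification
#'
#' Noise magnitude is a percentage of the image magnitude (max - min of the
#' volume the noise is added to), matching how robustness is probed on test
#' images.
#'
#' @slot percentMagnitude noise SD as a percentage of the intensity range
#'   (e.g. 0.1, 0.5, 1, 1.5, 2); must be >= 0.
#' @slot seed integer RNG seed for the noise field.
#' @export
setClass("NoiseSpec",
  representation(percentMagnitude = "numeric", seed = "integer"))

setValidity("NoiseSpec", function(object) {
  if (length(object@percentMagnitude) != 1L ||
      !is.finite(object@percentMagnitude) || object@percentMagnitude < 0)
    "'percentMagnitude' must be a single number >= 0" else TRUE
})

#' Loss-function configuration
#'
#' @slot gamma focal-loss decay exponent (>= 0); default 4.
#' @slot dsWeight weight of the deep-supervision head's CE + (1 - Dice) term.
#' @slot advWeight weight of the adversarial term in the generator loss.
#' @slot eps smoothing constant for logs and Dice denominators.
#' @slot classReduction how per-class soft Dice is reduced: "mean" over the
#'   two classes (keeps the coefficient in [0, 1]) or "foreground_only".
#' @slot focalForm "pt" uses the canonical (1 - p_t)^gamma modulation of the
#'   probability assigned to the true target; "printed" uses the literal
#'   (1 - S)^gamma factor irrespective of target.
#' @slot advForm "minimax" subtracts the focal loss of the fake branch at
#'   target 0 (the printed objective); "nonsaturating" adds the focal loss at
#'   target 1 instead.
#' @export
setClass("LossConfig",
  representation(gamma = "numeric", dsWeight = "numeric",
                 advWeight = "numeric", eps = "numeric",
                 classReduction = "character", focalForm = "character",
                 advForm = "character"))

setValidity("LossConfig", function(object) {
  msg <- character()
  if (object@gamma < 0) msg <- c(msg, "'gamma' must be >= 0")
  if (object@eps <= 0) msg <- c(msg, "'eps' must be > 0")
  if (!object@classReduction %in% c("mean", "foreground_only"))
    msg <- c(msg, "'classReduction' must be 'mean' or 'foreground_only'")
  if (!object@focalForm %in% c("pt", "printed"))
    msg <- c(msg, "'focalForm' must be 'pt' or 'printed'")
  if (!object@advForm %in% c("minimax", "nonsaturating"))
    msg <- c(msg, "'advForm' must be 'minimax' or 'nonsaturating'")
  if (length(msg)) msg else TRUE
})

#' Training configuration
#'
#' Defaults follow the method's reference regime: initial learning rate 0.001
#' decaying by 10\% every 5 epochs, moment parameters (0.9, 0.999), 40
#' epochs. `mode` selects full two-stage adversarial training or the
#' generator-only CE+Dice ablation; `discKind` picks the discriminator
#' (voxel-wise, patch-level, or volume-level receptive field).
#'
#' @slot lr0 initial learning rate.
#' @slot decay multiplicative decay factor applied every `decayEvery` epochs.
#' @slot decayEvery epochs between decay steps.
#' @slot betas numeric(2) moment parameters.
#' @slot optimizer "adam" or "sgd" (momentum SGD using betas[1]).
#' @slot epochs number of training epochs.
#' @slot batchSize patches per optimization step.
#' @slot patchSize integer(3) training patch size in voxels.
#' @slot overlap integer(3) patch overlap used when tiling training volumes.
#' @slot seed integer master seed.
#' @slot mode "adversarial" or "generator_only".
#' @slot discKind "voxel", "patch", "volume", or "none".
#' @slot discNoiseSd SD of the fresh Gaussian noise added to raw patches
#'   before they enter the discriminator, as a fraction of the per-patch SD.
#' @export
setClass("TrainConfig",
  representation(lr0 = "numeric", decay = "numeric", decayEvery = "numeric",
                 betas = "numeric", optimizer = "character",
                 epochs = "numeric", batchSize = "numeric",
                 patchSize = "integer", overlap = "integer",
                 seed = "integer", mode = "character", discKind = "character",
                 discNoiseSd = "numeric"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@lr0 <= 0) msg <- c(msg, "'lr0' must be > 0")
  if (object@epochs < 1) msg <- c(msg, "'epochs' must be >= 1")
  if (!object@mode %in% c("adversarial", "generator_only"))
    msg <- c(msg, "'mode' must be 'adversarial' or 'generator_only'")
  if (!object@discKind %in% c("voxel", "patch", "volume", "none"))
    msg <- c(msg, "'discKind' must be voxel/patch/volume/none")
  if (!object@optimizer %in% c("adam", "sgd"))
    msg <- c(msg, "'optimizer' must be 'adam' or 'sgd'")
  if (length(msg)) msg else TRUE
})

#' Trainable network handle
#'
#' Wraps the mutable state of a constructed network (layer parameters,
#' gradients, batch-norm statistics, forward caches) in an environment slot,
#' alongside the declarative configuration it was built from. `kind` is
#' "generator" or "discriminator".
#'
#' @slot kind character, network role.
#' @slot config the configuration list the network was built from.
#' @slot env environment holding layers and caches.
#' @export
setClass("Network3D",
  representation(kind = "character", config = "list", env = "environment"))
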
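#' @rdname Volume3D-class
#' @param object,x a `Volume3D`
#' @export
setGeneric("volValues", function(x) standardGeneric("volValues"))

#' @rdname Volume3D-class
#' @export
setGeneric("volSpacing", function(x) standardGeneric("volSpacing"))

#' @rdname Volume3D-class
#' @export
setGeneric("volOrigin", function(x) standardGeneric("volOrigin"))

#' @rdname PatchGrid-class
#' @export
setGeneric("gridCounts", function(x) standardGeneric("gridCounts"))

#' @rdname PatchGrid-class
#' @export
setGeneric("gridOrigins", function(x) standardGeneric("gridOrigins"))

#' @rdname PatchGrid-class
#' @export
setGeneric("nPatches", function(x) standardGeneric("nPatches"))

#' Segment a whole volume with a trained model
#'
#' Runs the full patch-wise inference pipeline: normalize, tile into
#' overlapping patches, predict each patch, and stitch the hard labels back
#' with majority voting. Methods exist for trained [Network3D] generators
#' and for plain functions (a function model receives the normalized
#' [Volume3D] and must return a [LabelVolume]; useful for oracle or
#' thresholding stand-ins).
#'
#' @param model a trained generator [Network3D] or a function.
#' @param vol a [Volume3D].
#' @param patchSize,overlap tiling used for inference (integer(3) each).
#' @param tie majority-vote tie rule, "foreground" (default) or
#'   "background".
#' @param ... passed to methods.
#' @return a [LabelVolume] with the spacing/origin of `vol`.
#' @export
setGeneric("predictVolume",
  function(model, vol, ...) standardGeneric("predictVolume"))

setMethod("volValues", "Volume3D", function(x) x@values)
setMethod("volSpacing", "Volume3D", function(x) x@spacing)
setMethod("volOrigin", "Volume3D", function(x) x@origin)

setMethod("gridCounts", "PatchGrid", function(x) x@counts)
setMethod("gridOrigins", "PatchGrid", function(x) x@patchOrigins)
setMethod("nPatches", "PatchGrid", function(x) as.integer(prod(x@counts)))

setMethod("show", "Volume3D", function(object) {
  d <- dim(object@values)
  cat(sprintf("%s %dx%dx%d, spacing %.3gx%.3gx%.3g mm\n", class(object),
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(object@values),
              max(object@values)))
  if (is(object, "LabelVolume"))
    cat(sprintf("  foreground fraction %.5f\n", mean(object@values)))
})

setMethod("show", "PatchGrid", function(object) {
  cat(sprintf(
    "PatchGrid: %s volume, %s patches, overlap %s\n",
    paste(object@volumeShape, collapse = "x"),
    paste(object@patchSize, collapse = "x"),
    paste(object@overlap, collapse = "x")))
  cat(sprintf("  counts %s (%d patches), padded to %s\n",
              paste(object@counts, collapse = "x"), prod(object@counts),
              paste(object@paddedShape, collapse = "x")))
})

setMethod("show", "PatchSet", function(object) {
  cat(sprintf("PatchSet: %d patches of %s%s\n", length(object@patches),
              paste(object@grid@patchSize, collapse = "x"),
              if (object@noisy) " (noisy)" else ""))
})

setMethod("show", "Network3D", function(object) {
  cat(sprintf("Network3D <%s>\n", object@kind))
  np <- sum(vapply(object@env$params, length, numeric(1)))
  cat(sprintf("  %d parameter arrays, %d parameters\n",
              length(object@env$params), np))
  if (!is.null(object@config$stages))
    for (s in object@config$stages)
      cat(sprintf("  stage: %s block, %d layers, growth %d\n",
                  s$connection, s$nLayers, s$growth))
  if (!is.null(object@config$kind2))
    cat(sprintf("  discriminator kind: %s\n", object@config$kind2))
})
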
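#' Construct a Volume3D
#'
#' @param values numeric 3D array.
#' @param spacing numeric(3), mm per axis.
#' @param origin numeric(3), mm.
#' @return a [Volume3D].
#' @examples
#' v <- volume3D(array(rnorm(27), dim = c(3, 3, 3)), spacing = c(1, 1, 2))
#' volSpacing(v)
#' @export
volume3D <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("Volume3D", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a LabelVolume
#'
#' @param values 3D array of 0/1 values.
#' @inheritParams volume3D
#' @return a [LabelVolume].
#' @export
labelVolume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(values) <- "double"
  new("LabelVolume", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Z-score normalization of a whole volume
#'
#' Standardizes a volume to zero mean and unit standard deviation,
#' `(X - mean(X)) / sd(X)`, using the population SD (denominator n). The
#' normalization is per volume, not per patch. A constant volume has no
#' defined z-score and is refused.
#'
#' @param vol a [Volume3D].
#' @return the normalized [Volume3D] (spacing/origin preserved).
#' @export
normalizeVolume <- function(vol) {
  stopifnot(is(vol, "Volume3D"))
  x <- vol@values
  mu <- mean(x)
  sdp <- sqrt(mean((x - mu)^2))
  if (sdp == 0)
    stop("cannot normalize a constant volume (zero standard deviation)")
  volume3D((x - mu) / sdp, vol@spacing, vol@origin)
}

#' Plan a deterministic overlapping-patch tiling
#'
#' Computes the grid of overlapping patches covering a volume. Per axis of
#' length L with patch p and overlap o (stride s = p - o), the patch count
#' is `ceil((L - p) / s) + 1` (1 if L <= p); the grid covers
#' `p + (count - 1) * s` voxels, so any shortfall of the volume is made up
#' by trailing zero-padding. Patch origins are `i * s`, 0-based; the first
#' patch always starts at 0.
#'
#' @param volumeShape integer(3), voxels per axis.
#' @param patchSize integer(3) (a scalar is recycled).
#' @param overlap integer(3) (a scalar is recycled); must be < patchSize.
#' @return a [PatchGrid].
#' @examples
#' g <- planPatchGrid(c(1024, 1024, 92), c(64, 64, 64), c(4, 4, 36))
#' gridCounts(g)   # 17 17 2
#' nPatches(g)     # 578
#' @export
planPatchGrid <- function(volumeShape, patchSize, overlap) {
  volumeShape <- as.integer(rep(volumeShape, length.out = 3))
  patchSize <- as.integer(rep(patchSize, length.out = 3))
  overlap <- as.integer(rep(overlap, length.out = 3))
  if (any(overlap < 0L)) stop("overlap must be >= 0")
  if (any(overlap >= patchSize)) stop("overlap must be < patchSize per axis")
  if (any(patchSize < 1L) || any(volumeShape < 1L))
    stop("patchSize and volumeShape must be positive")
  stride <- patchSize - overlap
  counts <- ifelse(volumeShape <= patchSize, 1L,
                   as.integer(ceiling((volumeShape - patchSize) / stride)) + 1L)
  padded <- patchSize + (counts - 1L) * stride
  idx <- as.matrix(expand.grid(x = seq_len(counts[1]) - 1L,
                               y = seq_len(counts[2]) - 1L,
                               z = seq_len(counts[3]) - 1L))
  origins <- sweep(idx, 2, stride, `*`)
  storage.mode(origins) <- "integer"
  dimnames(origins) <- NULL
  new("PatchGrid", volumeShape = volumeShape, patchSize = patchSize,
      overlap = overlap, stride = stride, counts = counts,
      paddedShape = padded, patchOrigins = origins)
}

## zero-pad an array up to the grid's padded shape (trailing only)
.padToGrid <- function(values, grid) {
  ps <- grid@paddedShape
  d <- dim(values)
  if (all(d == ps)) return(values)
  out <- array(0, dim = ps)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- values
  out
}

#' Extract the patches of a planned grid
#'
#' Cuts every patch of `grid` out of the (trailing-zero-padded) volume.
#' Extraction is read-only: overlapping voxels appear identically in every
#' covering patch.
#'
#' @param vol a [Volume3D], [LabelVolume], or bare 3D array.
#' @param grid a [PatchGrid] planned for the volume's shape.
#' @return a [PatchSet].
#' @export
extractPatches <- function(vol, grid) {
  values <- if (is(vol, "Volume3D")) vol@values else vol
  if (!identical(as.integer(dim(values)), grid@volumeShape))
    stop("volume shape does not match the grid's volumeShape")
  padded <- .padToGrid(values, grid)
  ps <- grid@patchSize
  patches <- lapply(seq_len(nrow(grid@patchOrigins)), function(i) {
    o <- grid@patchOrigins[i, ]
    padded[o[1] + seq_len(ps[1]), o[2] + seq_len(ps[2]),
           o[3] + seq_len(ps[3]), drop = FALSE]
  })
  new("PatchSet", grid = grid, patches = patches, noisy = FALSE)
}

#' Stitch binary label patches by majority voting
#'
#' Reassembles a full-size label volume from per-patch hard labels. Every
#' voxel takes the class receiving the most votes among the patches covering
#' it; ties go to the foreground by default (favoring recall of thin
#' vessels). The padded margin is discarded.
#'
#' @param labelPatches a [PatchSet] whose patches contain only 0/1 values.
#' @param grid the [PatchGrid] the patches were cut under.
#' @param tie "foreground" (default) or "background".
#' @param spacing,origin metadata for the output volume.
#' @return a [LabelVolume] of shape `grid@volumeShape`.
#' @export
stitchMajority <- function(labelPatches, grid = labelPatches@grid,
                           tie = c("foreground", "background"),
                           spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  tie <- match.arg(tie)
  stopifnot(is(labelPatches, "PatchSet"))
  if (length(labelPatches@patches) != prod(grid@counts))
    stop("incomplete patch set: expected ", prod(grid@counts), " patches")
  ok <- vapply(labelPatches@patches, function(p) all(p %in% c(0, 1)),
               logical(1))
  if (!all(ok)) stop("patches must be binary (0/1) hard labels")
  ps <- grid@patchSize
  votesFg <- array(0L, dim = grid@paddedShape)
  votesN <- array(0L, dim = grid@paddedShape)
  for (i in seq_len(nrow(grid@patchOrigins))) {
    o <- grid@patchOrigins[i, ]
    ix <- o[1] + seq_len(ps[1]); iy <- o[2] + seq_len(ps[2])
    iz <- o[3] + seq_len(ps[3])
    votesFg[ix, iy, iz] <- votesFg[ix, iy, iz] + labelPatches@patches[[i]]
    votesN[ix, iy, iz] <- votesN[ix, iy, iz] + 1L
  }
  out <- if (tie == "foreground") {
    (2L * votesFg >= votesN) * 1
  } else {
    (2L * votesFg > votesN) * 1
  }
  vs <- grid@volumeShape
  labelVolume(out[seq_len(vs[1]), seq_len(vs[2]), seq_len(vs[3]),
                  drop = FALSE],
              spacing = spacing, origin = origin)
}

#' Read / write volumes as NIfTI
#'
#' `writeNiftiVolume` stores a [Volume3D] losslessly (float64; labels as
#' uint8) with spacing in the header `pixdim` and origin in the qform
#' offsets. `readNiftiVolume` inverts it; `label = TRUE` (or auto-detection
#' of a 0/1-valued image) returns a [LabelVolume].
#'
#' @param vol a [Volume3D] or [LabelVolume].
#' @param path file path (`.nii` or `.nii.gz`).
#' @param label force reading as a label volume; default auto-detects.
#' @return `readNiftiVolume` returns a [Volume3D] or [LabelVolume];
#'   `writeNiftiVolume` returns `path` invisibly.
#' @export
writeNiftiVolume <- function(vol, path) {
  stopifnot(is(vol, "Volume3D"))
  lab <- is(vol, "LabelVolume")
  ref <- list(pixdim = c(-1, vol@spacing, rep(1, 4)),
              qoffset_x = vol@origin[1], qoffset_y = vol@origin[2],
              qoffset_z = vol@origin[3], qform_code = 2)
  img <- RNifti::asNifti(vol@values, reference = ref)
  RNifti::writeNifti(img, path, datatype = if (lab) "uint8" else "double")
  invisible(path)
}

#' @rdname writeNiftiVolume
#' @export
readNiftiVolume <- function(path, label = NA) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D image, got ", length(d), "D")
  hdr <- RNifti::niftiHeader(img)
  spacing <- abs(hdr$pixdim[2:4])
  origin <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
  values <- array(as.numeric(img), dim = d)
  if (is.na(label)) label <- all(values %in% c(0, 1))
  if (label && !all(values %in% c(0, 1)))
    stop("label = TRUE but the image is not binary")
  if (label) labelVolume(values, spacing, origin)
  else volume3D(values, spacing, origin)
}
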
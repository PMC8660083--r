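#' Define a synthetic vascular phantom
#'
#' Defaults emulate the statistics of cerebrovascular TOF-MRA that the
#' segmentation method assumes: thin bright tubes on a dark textured
#' background, mean tube intensity increasing with tube radius (the
#' flow-rate / intensity link of TOF imaging), and extreme class imbalance
#' (well under 1\% of voxels vascular; the default ceiling is 0.3\%).
#'
#' @param shape voxels per axis (each >= 32); default 64^3.
#' @param spacing mm per axis; default `c(0.5, 0.5, 0.6)`.
#' @param nTrees number of vessel trees; default 3.
#' @param branchDepth branching generations; default 3.
#' @param radiusRange mm, `c(min, max)` with min > 0; default
#'   `c(0.4, 1.2)`.
#' @param intensityLaw monotone function radius (mm) -> mean foreground
#'   intensity; default linear, `200 * r`.
#' @param backgroundLevel baseline background intensity; default 20.
#' @param backgroundTextureSd SD of Gaussian background texture; default 5.
#' @param targetFgFraction foreground-fraction ceiling in (0, 0.01];
#'   default 0.003.
#' @param seed integer seed; identical (spec, seed) pairs give bit-identical
#'   phantoms.
#' @return a [PhantomSpec].
#' @export
phantomSpec <- function(shape = c(64, 64, 64), spacing = c(0.5, 0.5, 0.6),
                        nTrees = 3, branchDepth = 3,
                        radiusRange = c(0.4, 1.2),
                        intensityLaw = function(r) 200 * r,
                        backgroundLevel = 20, backgroundTextureSd = 5,
                        targetFgFraction = 0.003, seed = 1L) {
  new("PhantomSpec", shape = as.integer(rep(shape, length.out = 3)),
      spacing = as.numeric(rep(spacing, length.out = 3)),
      nTrees = as.integer(nTrees), branchDepth = as.integer(branchDepth),
      radiusRange = as.numeric(radiusRange), intensityLaw = intensityLaw,
      backgroundLevel = as.numeric(backgroundLevel),
      backgroundTextureSd = as.numeric(backgroundTextureSd),
      targetFgFraction = as.numeric(targetFgFraction),
      seed = as.integer(seed))
}

#' @rdname addGaussianNoise
#' @param percentMagnitude noise SD as a percentage of the image magnitude.
#' @param seed integer seed for the noise field.
#' @export
noiseSpec <- function(percentMagnitude, seed = 1L) {
  new("NoiseSpec", percentMagnitude = as.numeric(percentMagnitude),
      seed = as.integer(seed))
}

## Evaluate an expression under a local RNG seed, restoring global state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Grow a branching set of centerline segments (mm coordinates).
## Each segment: list(p0, p1, radius). Endpoints are clamped so the whole
## tube (centerline +/- radius plus a one-voxel halo) stays inside.
.growSegments <- function(spec) {
  extent <- (spec@shape - 1) * spec@spacing
  segs <- list()
  for (t in seq_len(spec@nTrees)) {
    r0 <- stats::runif(1, mean(spec@radiusRange), spec@radiusRange[2])
    margin <- r0 + max(spec@spacing)
    lo <- pmin(margin, extent / 2); hi <- pmax(extent - margin, extent / 2)
    p <- stats::runif(3, lo, hi)
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    frontier <- list(list(p = p, dir = dir, radius = r0))
    for (depth in seq_len(spec@branchDepth)) {
      nxt <- list()
      for (br in frontier) {
        len <- stats::runif(1, 0.2, 0.35) * min(extent)
        d <- br$dir + stats::rnorm(3, sd = 0.35)
        d <- d / sqrt(sum(d^2))
        m <- br$radius + max(spec@spacing)
        p1 <- pmin(pmax(br$p + len * d, m), extent - m)
        segs[[length(segs) + 1L]] <- list(p0 = br$p, p1 = p1,
                                          radius = br$radius)
        nKids <- if (depth < spec@branchDepth) sample(1:2, 1) else 0L
        if (nKids > 0) for (kid in seq_len(nKids)) {
          rk <- max(br$radius * stats::runif(1, 0.55, 0.8),
                    spec@radiusRange[1])
          dk <- d + stats::rnorm(3, sd = 0.6)
          dk <- dk / sqrt(sum(dk^2))
          nxt[[length(nxt) + 1L]] <- list(p = p1, dir = dk, radius = rk)
        }
      }
      frontier <- nxt
    }
  }
  segs
}

## Rasterize one tube: returns list(idx = linear voxel indices of the
## foreground, intensity = per-voxel intensity contribution including the
## soft partial-volume halo just outside the hard label).
.rasterizeSegment <- function(seg, spec) {
  sp <- spec@spacing
  halo <- mean(sp)                       # one-voxel partial-volume ramp
  rEff <- seg$radius + halo
  lo <- floor(pmin(seg$p0, seg$p1 - 0) / sp) - ceiling(rEff / sp) - 1
  hi <- ceiling(pmax(seg$p0, seg$p1) / sp) + ceiling(rEff / sp) + 1
  lo <- pmax(lo, 0); hi <- pmin(hi, spec@shape - 1)
  if (any(hi < lo)) return(NULL)
  gx <- (lo[1]:hi[1]); gy <- (lo[2]:hi[2]); gz <- (lo[3]:hi[3])
  pts <- as.matrix(expand.grid(x = gx * sp[1], y = gy * sp[2],
                               z = gz * sp[3]))
  ab <- seg$p1 - seg$p0
  len2 <- sum(ab^2)
  ap <- sweep(pts, 2, seg$p0)
  tt <- if (len2 > 0) pmin(pmax((ap %*% ab) / len2, 0), 1) else 0
  proj <- sweep(tt %*% t(ab), 2, seg$p0, `+`)
  d <- sqrt(rowSums((pts - proj)^2))
  keep <- d <= rEff
  if (!any(keep)) return(NULL)
  grid <- as.matrix(expand.grid(x = gx, y = gy, z = gz))[keep, , drop = FALSE]
  idx <- 1 + grid[, 1] + spec@shape[1] * (grid[, 2] + spec@shape[2] *
                                            grid[, 3])
  soft <- pmin(pmax((rEff - d[keep]) / halo, 0), 1)
  base <- spec@intensityLaw(seg$radius)
  list(idx = idx, hard = d[keep] <= seg$radius, intensity = base * soft)
}

#' Generate a synthetic vascular phantom
#'
#' Grows piecewise-linear branching centerlines with circular cross-section,
#' rasterizes them as tubes (distance-to-centerline <= radius), assigns each
#' tube the intensity given by the spec's radius->intensity law with a
#' one-voxel linear partial-volume halo outside the hard label, and places
#' the tubes on a Gaussian-textured background. Tubes are added in
#' decreasing radius order while the foreground stays within
#' `targetFgFraction`; if not even the first tube fits the budget the spec
#' is infeasible and an error is raised.
#'
#' @param spec a [PhantomSpec].
#' @return list with elements `volume` ([Volume3D]) and `label`
#'   ([LabelVolume]).
#' @examples
#' ph <- generatePhantom(phantomSpec(seed = 7))
#' mean(volValues(ph$label))   # foreground fraction <= 0.003
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  .withSeed(spec@seed, {
    nVox <- prod(spec@shape)
    budget <- spec@targetFgFraction * nVox
    segs <- .growSegments(spec)
    ord <- order(-vapply(segs, function(s) s$radius, numeric(1)))
    segs <- segs[ord]

    label <- logical(nVox)
    signal <- numeric(nVox)
    placed <- 0L
    for (s in segs) {
      ras <- .rasterizeSegment(s, spec)
      if (is.null(ras)) next
      newFg <- union(which(label), ras$idx[ras$hard])
      if (length(newFg) > budget) {
        if (placed == 0L) next else break
      }
      label[ras$idx[ras$hard]] <- TRUE
      signal[ras$idx] <- pmax(signal[ras$idx], ras$intensity)
      placed <- placed + 1L
    }
    if (placed == 0L)
      stop("infeasible phantom spec: no tube of the requested radius fits ",
           "within targetFgFraction = ", spec@targetFgFraction)

    bg <- spec@backgroundLevel +
      stats::rnorm(nVox, sd = spec@backgroundTextureSd)
    values <- array(bg + signal, dim = spec@shape)
    lab <- array(as.numeric(label), dim = spec@shape)
    list(volume = volume3D(values, spec@spacing),
         label = labelVolume(lab, spec@spacing))
  })
}

#' Add calibrated Gaussian noise to a volume
#'
#' Adds a zero-mean Gaussian field whose standard deviation is
#' `percentMagnitude / 100` times the image magnitude, defined as
#' `max(vol) - min(vol)` of the volume at the time the noise is added.
#' The noise field is fully determined by the spec's seed.
#'
#' @param vol a [Volume3D].
#' @param noise a [NoiseSpec] (see `noiseSpec()`).
#' @return the noisy [Volume3D].
#' @export
addGaussianNoise <- function(vol, noise) {
  stopifnot(is(vol, "Volume3D"), is(noise, "NoiseSpec"))
  if (noise@percentMagnitude == 0) return(vol)
  rng <- max(vol@values) - min(vol@values)
  sdN <- noise@percentMagnitude / 100 * rng
  e <- .withSeed(noise@seed,
                 stats::rnorm(length(vol@values), mean = 0, sd = sdN))
  volume3D(vol@values + array(e, dim = dim(vol@values)),
           vol@spacing, vol@origin)
}

#' Signal-to-noise ratio between a clean and a degraded volume
#'
#' Power-ratio definition in decibels:
#' `10 * log10(sum(clean^2) / sum((noisy - clean)^2))`. When the two volumes
#' are identical the noise power is zero and `Inf` is returned as the
#' documented "infinite SNR" sentinel.
#'
#' @param clean,noisy [Volume3D]s of equal shape.
#' @return SNR in dB (`Inf` for zero noise power).
#' @export
computeSNR <- function(clean, noisy) {
  stopifnot(is(clean, "Volume3D"), is(noisy, "Volume3D"))
  if (!identical(dim(clean@values), dim(noisy@values)))
    stop("volumes must have identical shapes")
  noisePow <- sum((noisy@values - clean@values)^2)
  if (noisePow == 0) return(Inf)
  10 * log10(sum(clean@values^2) / noisePow)
}
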
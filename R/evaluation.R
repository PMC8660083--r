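#' Binary Dice coefficient between two masks
#'
#' `DC = 2|P ∩ G| / (|P| + |G|)` on foreground voxels. Both masks empty is
#' treated as perfect agreement (1); exactly one empty gives 0.
#'
#' @param P,G [LabelVolume]s (or binary arrays) of equal shape.
#' @return Dice coefficient in \[0, 1\].
#' @export
diceBinary <- function(P, G) {
  p <- if (is(P, "Volume3D")) P@values else P
  g <- if (is(G, "Volume3D")) G@values else G
  if (!identical(dim(p), dim(g))) stop("masks must have identical shapes")
  if (!all(p %in% c(0, 1)) || !all(g %in% c(0, 1)))
    stop("masks must be binary")
  sp <- sum(p); sg <- sum(g)
  if (sp + sg == 0) return(1)
  2 * sum(p * g) / (sp + sg)
}

## boundary voxels: foreground with at least one background 6-neighbor
## (the volume border counts as background)
.boundaryMask <- function(m) {
  d <- dim(m)
  pad <- array(0, d + 2L)
  pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- m
  ix <- 1 + seq_len(d[1]); iy <- 1 + seq_len(d[2]); iz <- 1 + seq_len(d[3])
  nb <- pad[ix - 1, iy, iz] + pad[ix + 1, iy, iz] +
        pad[ix, iy - 1, iz] + pad[ix, iy + 1, iz] +
        pad[ix, iy, iz - 1] + pad[ix, iy, iz + 1]
  m == 1 & nb < 6
}

#' Directed boundary-distance sets between two masks
#'
#' Boundary voxels are foreground voxels with at least one background
#' 6-neighbor (the volume border counts as background). `distPG` holds, for
#' every boundary voxel of P, the Euclidean distance in mm (voxel center to
#' voxel center, anisotropic spacing respected) to the nearest boundary
#' voxel of G; `distGP` is the converse. Distances use an exact Euclidean
#' distance transform.
#'
#' @param P,G [LabelVolume]s or binary arrays of equal shape; both must
#'   have nonempty foreground.
#' @param spacing mm per axis; defaults to P's spacing when available.
#' @return list with `distPG`, `distGP` (numeric vectors, mm) and
#'   `boundary = "6-connectivity, border counts as background"`.
#' @export
surfaceDistances <- function(P, G, spacing = NULL) {
  if (is.null(spacing))
    spacing <- if (is(P, "Volume3D")) P@spacing else c(1, 1, 1)
  p <- if (is(P, "Volume3D")) P@values else P
  g <- if (is(G, "Volume3D")) G@values else G
  if (!identical(dim(p), dim(g))) stop("masks must have identical shapes")
  if (sum(p) == 0 || sum(g) == 0)
    stop("surface distances are undefined for an empty mask")
  bp <- .boundaryMask(p)
  bg <- .boundaryMask(g)
  d <- dim(p)
  dtG <- .edt3d(as.logical(bg), as.integer(d), as.numeric(spacing))
  dtP <- .edt3d(as.logical(bp), as.integer(d), as.numeric(spacing))
  list(distPG = dtG[as.logical(bp)], distGP = dtP[as.logical(bg)],
       boundary = "6-connectivity, border counts as background")
}

#' Symmetric average surface distance
#'
#' `(mean(Dist(P, G)) + mean(Dist(G, P))) / 2` in mm.
#'
#' @param result a [surfaceDistances()] result.
#' @return SASD in mm.
#' @export
sasd <- function(result) {
  if (!length(result$distPG) || !length(result$distGP))
    stop("empty distance sets")
  (mean(result$distPG) + mean(result$distGP)) / 2
}

#' Symmetric 95th-percentile Hausdorff distance
#'
#' `(P95(Dist(P, G)) + P95(Dist(G, P))) / 2` in mm, with the linear
#' interpolation percentile convention (R's default type 7).
#'
#' @inheritParams sasd
#' @return SHD95 in mm.
#' @export
shd95 <- function(result) {
  if (!length(result$distPG) || !length(result$distGP))
    stop("empty distance sets")
  q <- function(x) unname(stats::quantile(x, 0.95, type = 7))
  (q(result$distPG) + q(result$distGP)) / 2
}

#' Per-volume segmentation metrics
#'
#' Dice, SASD and SHD95 for each prediction/ground-truth pair, plus the
#' aggregate mean and SD of each metric.
#'
#' @param preds,gts lists of [LabelVolume]s (paired).
#' @return list with `perVolume` (data.frame) and `aggregate`
#'   (mean/sd rows).
#' @export
metricsReport <- function(preds, gts) {
  stopifnot(length(preds) == length(gts), length(preds) >= 1)
  rows <- lapply(seq_along(preds), function(i) {
    ## surface metrics are undefined for an empty mask; report NA there
    ## instead of refusing the whole report
    sd_ <- tryCatch(surfaceDistances(preds[[i]], gts[[i]]),
                    error = function(e) NULL)
    data.frame(volume = i, DC = diceBinary(preds[[i]], gts[[i]]),
               SASD = if (is.null(sd_)) NA_real_ else sasd(sd_),
               SHD95 = if (is.null(sd_)) NA_real_ else shd95(sd_))
  })
  per <- do.call(rbind, rows)
  agg <- data.frame(
    metric = c("DC", "SASD", "SHD95"),
    mean = c(mean(per$DC), mean(per$SASD, na.rm = TRUE),
             mean(per$SHD95, na.rm = TRUE)),
    sd = c(stats::sd(per$DC), stats::sd(per$SASD, na.rm = TRUE),
           stats::sd(per$SHD95, na.rm = TRUE)))
  list(perVolume = per, aggregate = agg)
}

#' Drop-to performance
#'
#' `DTP = DC_p / DC_0 * 100`: segmentation accuracy under p\% noise as a
#' percentage of the noise-free accuracy.
#'
#' @param dcP Dice under noise.
#' @param dc0 noise-free Dice; must be > 0.
#' @return DTP in percent.
#' @export
dtp <- function(dcP, dc0) {
  if (dc0 <= 0) stop("dc0 must be > 0 for drop-to performance")
  100 * (dcP / dc0)
}

#' Noise-robustness sweep
#'
#' For every noise percentage: add calibrated Gaussian noise to each test
#' volume, run the full inference pipeline (normalize, tile, predict,
#' stitch), and record the mean Dice against ground truth; report it as
#' drop-to performance relative to the noise-free baseline (percent 0,
#' always included first).
#'
#' @param model a trained generator [Network3D] or a function model (see
#'   [predictVolume()]).
#' @param volumes list of `list(volume = Volume3D, label = LabelVolume)`.
#' @param percents noise magnitudes as percent of image magnitude; default
#'   `c(0.1, 0.5, 1, 1.5, 2)`.
#' @param seed seed for the noise fields.
#' @param ... passed to [predictVolume()].
#' @return data.frame with `percent`, `DC`, `DTP`.
#' @export
noiseSweep <- function(model, volumes, percents = c(0.1, 0.5, 1, 1.5, 2),
                       seed = 1L, ...) {
  stopifnot(length(volumes) >= 1)
  percents <- c(0, percents[percents > 0])
  meanDc <- vapply(seq_along(percents), function(i) {
    p <- percents[i]
    dcs <- vapply(seq_along(volumes), function(j) {
      v <- volumes[[j]]$volume
      if (p > 0)
        v <- addGaussianNoise(v, noiseSpec(p, seed = seed + 1000L * i + j))
      pred <- predictVolume(model, v, ...)
      diceBinary(pred, volumes[[j]]$label)
    }, numeric(1))
    mean(dcs)
  }, numeric(1))
  if (meanDc[1] <= 0)
    stop("noise-free Dice is 0; drop-to performance is undefined")
  data.frame(percent = percents, DC = meanDc,
             DTP = dtp(meanDc, meanDc[1]))
}

#' Paired statistical comparison of two methods
#'
#' One-tailed paired t-test of H0: mu_a = mu_b against H1: mu_a > mu_b on
#' paired per-volume scores (typically Dice), with Cohen's D in the paired
#' convention (mean difference / SD of differences) and the two-way mixed,
#' consistency, single-measure intraclass correlation coefficient. The
#' significance level alpha = 0.01 is reported alongside. With zero
#' variance of the differences the t statistic is undefined; the all-equal
#' case is reported as t = 0, p = 0.5, D = 0 with a degenerate flag.
#'
#' @param dcA,dcB equal-length paired samples (n >= 2).
#' @param alpha significance level to report (default 0.01).
#' @return list with `n`, `t`, `p`, `cohensD`, `icc`, `alpha`,
#'   `significant`, `degenerate`.
#' @export
compareMethods <- function(dcA, dcB, alpha = 0.01) {
  n <- length(dcA)
  if (n != length(dcB)) stop("paired samples must have equal length")
  if (n < 2) stop("need at least 2 paired observations")
  d <- dcA - dcB
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(n = n, t = 0, p = 0.5, cohensD = 0, icc = .icc31(dcA, dcB),
                  alpha = alpha, significant = FALSE, degenerate = TRUE))
    return(list(n = n, t = sign(mean(d)) * Inf,
                p = if (mean(d) > 0) 0 else 1,
                cohensD = sign(mean(d)) * Inf, icc = .icc31(dcA, dcB),
                alpha = alpha, significant = mean(d) > 0,
                degenerate = TRUE))
  }
  tt <- stats::t.test(dcA, dcB, paired = TRUE, alternative = "greater")
  cd <- mean(d) / stats::sd(d)
  icc <- .icc31(dcA, dcB)
  list(n = n, t = unname(tt$statistic), p = tt$p.value, cohensD = cd,
       icc = icc, alpha = alpha, significant = tt$p.value < alpha,
       degenerate = FALSE)
}

## ICC(3,1): two-way mixed, consistency, single measure, k = 2 raters
.icc31 <- function(a, b) {
  n <- length(a); k <- 2
  m <- cbind(a, b)
  rowM <- rowMeans(m); colM <- colMeans(m); gm <- mean(m)
  msr <- k * sum((rowM - gm)^2) / (n - 1)
  msc <- n * sum((colM - gm)^2) / (k - 1)
  sse <- sum((m - outer(rowM, rep(1, k)) -
                outer(rep(1, n), colM) + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr + (k - 1) * mse == 0) return(NA_real_)
  (msr - mse) / (msr + (k - 1) * mse)
}
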
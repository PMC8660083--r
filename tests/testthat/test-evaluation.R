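test_that("binary Dice matches set arithmetic and its conventions", {
  m <- array(0, c(4, 4, 4))
  P <- m; P[1:4, 1, 1] <- 1                 # |P| = 4
  G <- m; G[2:4, 1, 1] <- 1; G[1:3, 2, 1] <- 1  # |G| = 6, overlap 3
  expect_equal(diceBinary(P, G), 0.6)
  expect_equal(diceBinary(G, P), 0.6)        # symmetric
  expect_equal(diceBinary(P, P), 1)
  D <- m; D[1, 1, 4] <- 1
  E <- m; E[4, 4, 1] <- 1
  expect_equal(diceBinary(D, E), 0)
  expect_equal(diceBinary(m, m), 1)          # both empty: agreement
  expect_equal(diceBinary(P, m), 0)          # one empty
  expect_error(diceBinary(P, array(0, c(3, 3, 3))), "shape")
})

test_that("surface distances respect spacing and refuse empty masks", {
  P <- array(0, c(5, 5, 5)); P[2, 3, 3] <- 1
  G <- array(0, c(5, 5, 5)); G[3, 3, 3] <- 1
  r <- surfaceDistances(P, G, spacing = c(1, 1, 1))
  expect_equal(r$distPG, 1); expect_equal(r$distGP, 1)
  r2 <- surfaceDistances(P, G, spacing = c(0.5, 1, 1))
  expect_equal(r2$distPG, 0.5)
  self <- surfaceDistances(P, P, spacing = c(1, 1, 1))
  expect_true(all(self$distPG == 0) && all(self$distGP == 0))
  expect_error(surfaceDistances(P, array(0, c(5, 5, 5))), "empty")
})

test_that("distance transform equals brute-force all-pairs minima", {
  set.seed(11)
  for (i in 1:12) {
    d <- sample(5:12, 3, replace = TRUE)
    P <- array(rbinom(prod(d), 1, 0.3), dim = d)
    G <- array(rbinom(prod(d), 1, 0.3), dim = d)
    if (sum(P) == 0 || sum(G) == 0) next
    sp <- runif(3, 0.3, 1.5)
    got <- surfaceDistances(P, G, spacing = sp)
    want <- bruteSurfaceDistances(P, G, sp)
    expect_equal(sort(got$distPG), sort(want$distPG), tolerance = 1e-9)
    expect_equal(sort(got$distGP), sort(want$distGP), tolerance = 1e-9)
  }
})

test_that("SASD and SHD95 aggregate directed sets as defined", {
  r <- list(distPG = 1.0, distGP = 1.0)
  expect_equal(sasd(r), 1.0)
  expect_equal(shd95(r), 1.0)
  # the 95th percentile shrugs off a single outlier; the max does not
  r2 <- list(distPG = c(rep(0, 99), 10), distGP = 0)
  expect_lt(shd95(r2), max(r2$distPG) / 2)
  expect_equal(sasd(r2), (10 / 100) / 2)
  expect_error(sasd(list(distPG = numeric(), distGP = 1)), "empty")
  # all three metrics vanish iff the masks coincide
  set.seed(3)
  m <- array(rbinom(6^3, 1, 0.3), c(6, 6, 6))
  r3 <- surfaceDistances(m, m, spacing = c(1, 1, 1))
  expect_equal(c(sasd(r3), shd95(r3), 1 - diceBinary(m, m)), c(0, 0, 0))
  m2 <- m; m2[1, 1, 1] <- 1 - m2[1, 1, 1]
  r4 <- surfaceDistances(m2, m, spacing = c(1, 1, 1))
  expect_gt(sasd(r4) + shd95(r4) + (1 - diceBinary(m2, m)), 0)
})

test_that("metrics reports aggregate per-volume values", {
  set.seed(4)
  gts <- lapply(1:3, function(i)
    labelVolume(array(rbinom(6^3, 1, 0.3), c(6, 6, 6))))
  preds <- lapply(gts, function(g) {
    v <- volValues(g); v[1, 1, ] <- 1; labelVolume(v)
  })
  rep_ <- metricsReport(preds, gts)
  expect_identical(nrow(rep_$perVolume), 3L)
  expect_true(all(rep_$perVolume$DC >= 0 & rep_$perVolume$DC <= 1))
  expect_true(all(rep_$perVolume$SASD >= 0))
  expect_identical(rep_$aggregate$metric, c("DC", "SASD", "SHD95"))
})

test_that("drop-to performance is the defined ratio", {
  expect_equal(dtp(0.8, 0.8), 100)
  expect_equal(dtp(0.4, 0.8), 50)
  expect_error(dtp(0.4, 0), "dc0")
  dcs <- c(0.8, 0.7, 0.7, 0.5)
  expect_true(all(diff(dtp(dcs, 0.8)) <= 0))
})

test_that("a ground-truth oracle holds DTP at 100 across all noise levels", {
  ph <- standardPhantom(seed = 21)
  truth <- ph$label
  oracle <- function(nv) truth
  sweep <- noiseSweep(oracle, list(ph), percents = c(0.1, 0.5, 1, 1.5, 2),
                      seed = 1)
  expect_identical(nrow(sweep), 6L)          # baseline + five levels
  expect_equal(sweep$percent[1], 0)
  expect_identical(sweep$DTP[1], 100)        # DTP(0) exact for any model
  expect_true(all(sweep$DTP == 100))
})

test_that("a thresholding stand-in degrades with noise on average", {
  # moderate-contrast phantom; noise strong enough to disturb a quantile
  # threshold (a quantile rule is insensitive to very small perturbations)
  mk <- function(seed) generatePhantom(phantomSpec(
    intensityLaw = function(r) 60 * r, backgroundTextureSd = 8,
    seed = seed))
  ph <- mk(31)
  fgq <- 1 - mean(volValues(ph$label))
  thresholdModel <- function(nv) {
    v <- volValues(nv)
    labelVolume((v > quantile(v, fgq)) * 1, volSpacing(nv))
  }
  sweeps <- lapply(1:3, function(s)
    noiseSweep(thresholdModel, list(ph), percents = c(5, 20), seed = s))
  avg <- Reduce(`+`, lapply(sweeps, function(s) s$DC)) / 3
  expect_identical(sweeps[[1]]$DTP[1], 100)
  expect_true(all(diff(avg) < 0))            # 0 > 5% > 20% on average
})

test_that("paired comparisons report t, Cohen's D and ICC conventions", {
  same <- compareMethods(c(0.8, 0.7, 0.9), c(0.8, 0.7, 0.9))
  expect_equal(c(same$t, same$p, same$cohensD), c(0, 0.5, 0))
  expect_true(same$degenerate)

  set.seed(5)
  a <- runif(8, 0.7, 0.9)
  b <- a - 0.05 + rnorm(8, sd = 0.002)
  st <- compareMethods(a, b)
  expect_lt(st$p, 0.01)
  expect_true(st$significant)
  expect_equal(st$alpha, 0.01)
  # independent check of the one-tailed p against the t CDF
  d <- a - b
  tstat <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(st$t, tstat, tolerance = 1e-10)
  expect_equal(st$p, pt(tstat, df = length(d) - 1, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(st$cohensD, mean(d) / sd(d), tolerance = 1e-12)

  # ICC(3,1) is 1 for perfectly correlated, equal-variance samples
  x <- rnorm(10)
  st2 <- compareMethods(x + 5, x)
  expect_equal(st2$icc, 1, tolerance = 1e-6)
  expect_error(compareMethods(1, 1), "at least 2")
  expect_error(compareMethods(c(1, 2), c(1, 2, 3)), "equal length")
})
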
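lc <- lossConfig()

test_that("cross-entropy has its closed-form values and additivity", {
  expect_lt(crossEntropy(asProbMap(c(1, 0, 0)), asTargetMap(c(1, 0, 0))),
            1e-5)
  expect_equal(crossEntropy(asProbMap(0.5), asTargetMap(1)), -log(0.5),
               tolerance = 1e-6)
  one <- crossEntropy(asProbMap(0.3), asTargetMap(1))
  two <- crossEntropy(asProbMap(c(0.3, 0.3)), asTargetMap(c(1, 1)))
  expect_equal(two, 2 * one, tolerance = 1e-12)
  expect_error(crossEntropy(asProbMap(c(0.5, 0.5)), asTargetMap(1)),
               "shape")
})

test_that("soft Dice spans [0,1] with its defined endpoints", {
  expect_equal(diceCoeff(asProbMap(c(1, 0, 1, 0)),
                         asTargetMap(c(1, 0, 1, 0)), lc), 1,
               tolerance = 1e-6)
  # fully disjoint binary maps: both class overlaps empty
  expect_equal(diceCoeff(asProbMap(c(1, 0)), asTargetMap(c(0, 1)), lc), 0,
               tolerance = 1e-6)
  # hand evaluation: P_fg=(1,1,0,0), Y_fg=(1,0,0,0) -> (2/3 + 4/5)/2
  expect_equal(diceCoeff(asProbMap(c(1, 1, 0, 0)),
                         asTargetMap(c(1, 0, 0, 0)), lc), 11 / 15,
               tolerance = 1e-6)
  # foreground-only reduction isolates the vessel class
  lcf <- lossConfig(classReduction = "foreground_only")
  expect_equal(diceCoeff(asProbMap(c(1, 1, 0, 0)),
                         asTargetMap(c(1, 0, 0, 0)), lcf), 2 / 3,
               tolerance = 1e-6)
})

test_that("soft Dice is symmetric, bounded and monotone in true positives", {
  set.seed(1)
  for (i in 1:20) {
    p <- rbinom(10, 1, 0.4); y <- rbinom(10, 1, 0.4)
    d1 <- diceCoeff(asProbMap(p), asTargetMap(y), lc)
    d2 <- diceCoeff(asProbMap(y), asTargetMap(p), lc)
    expect_equal(d1, d2, tolerance = 1e-12)
    expect_true(d1 >= 0 && d1 <= 1)
  }
  # raising the probability on a true foreground voxel never lowers Dice
  y <- c(1, 1, 0, 0, 0)
  lo <- diceCoeff(asProbMap(c(0.6, 0.2, 0.1, 0, 0)), asTargetMap(y), lc)
  hi <- diceCoeff(asProbMap(c(0.6, 0.9, 0.1, 0, 0)), asTargetMap(y), lc)
  expect_gte(hi, lo)
})

test_that("focal loss reduces to BCE at gamma 0 and matches hand values", {
  lc0 <- lossConfig(gamma = 0)
  S <- c(0.3, 0.8, 0.6); T <- c(0, 1, 1)
  expect_equal(focalLoss(S, T, lc0),
               -sum(T * log(S) + (1 - T) * log(1 - S)), tolerance = 1e-9)
  expect_equal(focalLoss(0.5, 1, lc), 0.5^4 * (-log(0.5)),
               tolerance = 1e-6)
  expect_lt(focalLoss(c(0.999999, 1e-6), c(1, 0), lc), 1e-10)
  # modulation never increases a voxel's contribution (gamma > 0)
  for (s in seq(0.05, 0.95, by = 0.15)) for (t in c(0, 1)) {
    expect_lte(focalLoss(s, t, lc), focalLoss(s, t, lc0) + 1e-12)
  }
  # the literal printed form is available and differs for T = 0 voxels
  lcp <- lossConfig(focalForm = "printed")
  expect_false(isTRUE(all.equal(focalLoss(0.2, 0, lcp),
                                focalLoss(0.2, 0, lc))))
})

test_that("discriminator inputs are voxel-wise products", {
  expect_identical(makeDiscInput(array(c(2, 3), c(2, 1, 1)), c(0.5, 1)),
                   array(c(1, 3), c(2, 1, 1)))
  raw <- array(rnorm(8), c(2, 2, 2))
  expect_identical(makeDiscInput(raw, array(1, c(2, 2, 2))), raw)
  expect_true(all(makeDiscInput(raw, array(0, c(2, 2, 2))) == 0))
  expect_error(makeDiscInput(raw, c(1, 2)), "voxels")
})

test_that("generator loss composes its terms as defined", {
  P <- asProbMap(c(1, 0, 0, 1)); Y <- asTargetMap(c(1, 0, 0, 1))
  lc0 <- lossConfig(advWeight = 0)
  gl <- generatorLoss(P, Y, NULL, lc0)
  expect_lt(gl$total, 1e-4)
  set.seed(2)
  P2 <- asProbMap(runif(6)); Y2 <- asTargetMap(rbinom(6, 1, 0.5))
  gl2 <- generatorLoss(P2, Y2, NULL, lc0)
  expect_equal(gl2$total,
               crossEntropy(P2, Y2, lc0) + (1 - diceCoeff(P2, Y2, lc0)),
               tolerance = 1e-12)
  # adversarial term strictly decreases as the discriminator is fooled
  adv <- vapply(seq(0.1, 0.9, by = 0.1), function(s)
    generatorLoss(P2, Y2, matrix(s, 1, 6), lc)$adv, numeric(1))
  expect_true(all(diff(adv) < 0))
})

test_that("generator loss is minimized exactly at P = Y on tiny maps", {
  lc0 <- lossConfig(advWeight = 0)
  y <- c(1, 0, 1)
  Y <- asTargetMap(y)
  enum <- expand.grid(rep(list(c(0, 1)), 3))
  tot <- apply(enum, 1, function(p)
    generatorLoss(asProbMap(as.numeric(p)), Y, NULL, lc0)$total)
  expect_equal(unname(which.min(tot)),
               which(apply(enum, 1, function(p) all(p == y))))
})

test_that("discriminator loss rewards perfect discrimination", {
  good <- discriminatorLoss(matrix(1e-6, 1, 8), matrix(1 - 1e-6, 1, 8), lc)
  expect_lt(good$total, 1e-10)
  half <- discriminatorLoss(matrix(0.5, 1, 10), matrix(0.5, 1, 10), lc)
  expect_equal(half$total, 2 * 0.5^4 * log(2), tolerance = 1e-9)
  expect_equal(half$fake, half$real, tolerance = 1e-12)
  # swapping the branch targets hurts when discrimination is good
  sf <- matrix(0.1, 1, 8); sr <- matrix(0.9, 1, 8)
  expect_gt(discriminatorLoss(sr, sf, lc)$total,
            discriminatorLoss(sf, sr, lc)$total)
})

test_that("losses are finite and scale linearly with voxel count", {
  set.seed(3)
  p <- runif(5); y <- rbinom(5, 1, 0.5)
  ce1 <- crossEntropy(asProbMap(p), asTargetMap(y), lc)
  ce3 <- crossEntropy(asProbMap(rep(p, 3)), asTargetMap(rep(y, 3)), lc)
  expect_equal(ce3, 3 * ce1, tolerance = 1e-9)
  fl1 <- focalLoss(p, y, lc)
  fl3 <- focalLoss(rep(p, 3), rep(y, 3), lc)
  expect_equal(fl3, 3 * fl1, tolerance = 1e-9)
  expect_true(is.finite(crossEntropy(asProbMap(c(0, 1)),
                                     asTargetMap(c(1, 0)), lc)))
  expect_true(is.finite(focalLoss(c(0, 1), c(1, 0), lc)))
})
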
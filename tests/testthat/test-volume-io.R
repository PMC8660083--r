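test_that("normalization gives zero mean, unit population SD", {
  ph <- standardPhantom(seed = 1)
  nv <- normalizeVolume(ph$volume)
  x <- volValues(nv)
  expect_lt(abs(mean(x)), 1e-6)
  expect_lt(abs(sqrt(mean((x - mean(x))^2)) - 1), 1e-6)
  # hand-computed toy: {1,2,3,4}, population SD sqrt(1.25)
  toy <- volume3D(array(c(1, 2, 3, 4, 1, 2, 3, 4), dim = c(2, 2, 2)))
  got <- sort(unique(as.numeric(volValues(normalizeVolume(toy)))))
  expect_equal(got, c(-1.3416, -0.4472, 0.4472, 1.3416), tolerance = 1e-4)
  expect_error(normalizeVolume(volume3D(array(5, dim = c(3, 3, 3)))),
               "constant")
})

test_that("patch-grid arithmetic matches the per-axis formula", {
  g <- planPatchGrid(c(64, 64, 64), c(64, 64, 64), c(4, 4, 36))
  expect_identical(gridCounts(g), c(1L, 1L, 1L))
  expect_identical(gridOrigins(g)[1, ], c(0L, 0L, 0L))
  # first origin 0; last patch exactly reaches the padded boundary
  g2 <- planPatchGrid(c(30, 20, 10), c(8, 8, 8), c(3, 0, 5))
  last <- gridOrigins(g2)[nPatches(g2), ]
  expect_identical(as.integer(last + g2@patchSize), g2@paddedShape)
  expect_true(all(g2@paddedShape >= c(30L, 20L, 10L)))
  expect_error(planPatchGrid(c(30, 30, 30), 8, 8), "overlap")
})

test_that("patch counts equal brute-force origin enumeration", {
  for (L in c(16L, 23L, 40L, 64L, 97L, 128L)) {
    for (p in c(8L, 16L, 32L)) {
      for (o in unique(c(0L, 1L, p %/% 2L, p - 1L))) {
        g <- planPatchGrid(c(L, 16L, 16L), c(p, 8L, 8L), c(o, 0L, 0L))
        expect_identical(gridCounts(g)[1], brutePatchCount(L, p, o),
                         label = sprintf("L=%d p=%d o=%d", L, p, o))
      }
    }
  }
})

test_that("every voxel is covered and votes match analytic multiplicity", {
  g <- planPatchGrid(c(10, 9, 8), c(4, 4, 4), c(2, 1, 0))
  cover <- array(0L, dim = g@paddedShape)
  for (i in seq_len(nPatches(g))) {
    o <- gridOrigins(g)[i, ]
    idx <- list(o[1] + 1:4, o[2] + 1:4, o[3] + 1:4)
    cover[idx[[1]], idx[[2]], idx[[3]]] <-
      cover[idx[[1]], idx[[2]], idx[[3]]] + 1L
  }
  expect_true(all(cover >= 1L))
  # analytic multiplicity per axis: number of origins covering coordinate v
  mult1 <- function(v, p, s, n) sum(v > (0:(n - 1)) * s &
                                      v <= (0:(n - 1)) * s + p)
  for (v in c(1, 3, 5, 10)) {
    got <- cover[v, 1, 1]
    expect_identical(got, mult1(v, 4L, g@stride[1], gridCounts(g)[1]) *
                       mult1(1, 4L, g@stride[2], gridCounts(g)[2]) *
                       mult1(1, 4L, g@stride[3], gridCounts(g)[3]))
  }
})

test_that("extraction is read-only and padding is trailing zeros", {
  bx <- boxVolume(c(10, 10, 10), seed = 2)
  g <- planPatchGrid(c(10, 10, 10), c(8, 8, 8), c(6, 6, 6))
  ps <- extractPatches(bx$volume, g)
  # overlap region appears identically in adjacent patches
  p1 <- ps@patches[[1]]; p2 <- ps@patches[[2]]   # x-neighbors, stride 2
  expect_identical(p1[3:8, , ], p2[1:6, , ])
  # grid with padding: last patch holds zeros beyond the volume
  g2 <- planPatchGrid(c(10, 10, 10), c(8, 8, 8), c(4, 4, 4))
  expect_identical(g2@paddedShape, c(12L, 12L, 12L))
  ps2 <- extractPatches(bx$volume, g2)
  lastP <- ps2@patches[[nPatches(g2)]]
  expect_true(all(lastP[7:8, , ] == 0))
  expect_error(extractPatches(array(0, c(5, 5, 5)), g2), "shape")
})

test_that("split then stitch is the identity when patches agree", {
  bx <- boxVolume(c(12, 10, 8), seed = 3)
  for (ov in list(c(0, 0, 0), c(2, 1, 3))) {
    g <- planPatchGrid(c(12, 10, 8), c(4, 4, 4), ov)
    ps <- extractPatches(bx$label, g)
    out <- stitchMajority(ps, g)
    expect_identical(volValues(out), volValues(bx$label))
  }
})

test_that("majority voting counts votes and breaks ties to foreground", {
  # 1D-style grid: volume 6 x 4 x 4, patches 4^3, overlap (3,0,0):
  # x=4 is covered by all three patches, x=2 by the first two.
  g <- planPatchGrid(c(6, 4, 4), c(4, 4, 4), c(3, 0, 0))
  expect_identical(gridCounts(g), c(3L, 1L, 1L))
  zero <- array(0, c(4, 4, 4))
  p1 <- zero; p2 <- zero; p3 <- zero
  p1[4, 1, 1] <- 1   # x=4 is local x 4 in patch at origin 0
  p2[3, 1, 1] <- 1   # x=4 is local x 3 in patch at origin 1
  p3[2, 1, 1] <- 0   # x=4 is local x 2 in patch at origin 2
  p1[2, 2, 1] <- 1   # x=2: covered by patches 1 (local 2) and 2 (local 1)
  p2[1, 2, 1] <- 0
  ps <- new("PatchSet", grid = g, patches = list(p1, p2, p3))
  out <- volValues(stitchMajority(ps, g))
  expect_identical(out[4, 1, 1], 1)   # votes (1,1,0) -> majority fg
  expect_identical(out[2, 2, 1], 1)   # votes (1,0) -> tie -> fg
  outBg <- volValues(stitchMajority(ps, g, tie = "background"))
  expect_identical(outBg[2, 2, 1], 0) # tie rule is configurable
  expect_error(stitchMajority(new("PatchSet", grid = g,
                                  patches = list(p1, p2, p3 + 0.5))),
               "binary")
})

test_that("NIfTI round trip preserves values, spacing, origin and labels", {
  tmp <- tempfile(fileext = ".nii.gz")
  on.exit(unlink(tmp))
  set.seed(4)
  vol <- volume3D(array(rnorm(6 * 5 * 4), dim = c(6, 5, 4)),
                  spacing = c(0.264, 0.264, 0.8), origin = c(1.5, -2, 3))
  writeNiftiVolume(vol, tmp)
  back <- readNiftiVolume(tmp)
  expect_identical(volValues(back), volValues(vol))
  expect_equal(volSpacing(back), volSpacing(vol), tolerance = 1e-6)
  expect_equal(volOrigin(back), volOrigin(vol), tolerance = 1e-6)

  lab <- labelVolume(array(rbinom(120, 1, 0.3), dim = c(6, 5, 4)))
  writeNiftiVolume(lab, tmp)
  lback <- readNiftiVolume(tmp)
  expect_s4_class(lback, "LabelVolume")
  expect_identical(volValues(lback), volValues(lab))

  # 4D images are refused
  arr4 <- array(0, dim = c(4, 4, 4, 2))
  RNifti::writeNifti(RNifti::asNifti(arr4), tmp)
  expect_error(readNiftiVolume(tmp), "3D")
  expect_error(readNiftiVolume("no/such/file.nii"), "not found")
})
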
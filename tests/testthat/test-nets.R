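test_that("channel plans follow the three connection rules", {
  fib <- list(connection = "fibonacci", nLayers = 4, growth = 16)
  expect_identical(channelPlan(fib, 8), c(8L, 24L, 32L, 32L))
  dense <- list(connection = "dense", nLayers = 4, growth = 16)
  expect_identical(channelPlan(dense, 8), c(8L, 24L, 40L, 56L))
  lin <- list(connection = "linear", nLayers = 3, growth = 16)
  expect_identical(channelPlan(lin, 8), c(8L, 16L, 16L))
  for (conn in c("fibonacci", "dense", "linear"))
    expect_identical(channelPlan(list(connection = conn, nLayers = 1,
                                      growth = 5), 7), 7L)
  # layers 3 and beyond of a uniform-growth Fibonacci block see 2g channels
  expect_true(all(channelPlan(list(connection = "fibonacci", nLayers = 6,
                                   growth = 4), 10)[3:6] == 8L))
})

test_that("built blocks use exactly the planned channel widths", {
  gen <- buildGenerator(tinyGenConfig(), seed = 1)
  plan <- channelPlan(list(connection = "fibonacci", nLayers = 3,
                           growth = 6), 6)
  got <- vapply(gen@env$stage1$units, function(u) u$conv$cin, integer(1))
  expect_identical(got, plan)
})

test_that("generator heads preserve shape and normalize per voxel", {
  for (conn in c("fibonacci", "dense", "linear")) {
    gen <- buildGenerator(tinyGenConfig(conn), seed = 2)
    x <- array(rnorm(12^3), dim = c(12, 12, 12))
    fw <- genForward(gen, x, train = FALSE)
    expect_equal(dim(fw$main), c(2, 12^3))
    expect_equal(dim(fw$ds), c(2, 12^3))
    expect_true(all(abs(colSums(fw$main) - 1) < 1e-5))
    expect_true(all(abs(colSums(fw$ds) - 1) < 1e-5))
    expect_true(all(fw$main >= 0 & fw$main <= 1))
  }
  expect_error(genForward(buildGenerator(tinyGenConfig(), 1),
                          array(0, c(7, 8, 8))), "even")
})

test_that("generator gradients match finite differences", {
  set.seed(3)
  gen <- buildGenerator(microGenConfig(), seed = 4)
  x <- array(rnorm(6^3), dim = c(6, 6, 6))
  y <- array(rbinom(6^3, 1, 0.3), dim = c(6, 6, 6))
  Y <- asTargetMap(y)
  lc <- lossConfig()
  lossOf <- function() {
    f <- genForward(gen, x, train = TRUE)
    generatorLoss(f$main, Y, NULL, lc, Pds = f$ds)$total
  }
  f0 <- genForward(gen, x, train = TRUE)
  gP <- vanseg:::.ceGrad(f0$main, Y, lc) - vanseg:::.diceGrad(f0$main, Y, lc)
  gD <- lc@dsWeight * (vanseg:::.ceGrad(f0$ds, Y, lc) -
                         vanseg:::.diceGrad(f0$ds, Y, lc))
  vanseg:::.zeroGrads(gen@env$params)
  genBackward(gen, gP, gD)
  h <- 1e-5
  for (li in c(1, 4, length(gen@env$params))) {
    l <- gen@env$params[[li]]
    nm <- vanseg:::.layerParams(l)[[1]]
    getw <- function() if (is.list(l[[nm]])) l[[nm]][[1]][1, 1]
                       else l[[nm]][1]
    setw <- function(v) if (is.list(l[[nm]])) l[[nm]][[1]][1, 1] <- v
                        else l[[nm]][1] <- v
    orig <- getw()
    setw(orig + h); fp <- lossOf()
    setw(orig - h); fm <- lossOf()
    setw(orig)
    gnum <- (fp - fm) / (2 * h)
    gan <- if (is.list(l[[nm]]))
      l[[vanseg:::.gradName(nm)]][[1]][1, 1]
    else l[[vanseg:::.gradName(nm)]][1]
    expect_equal(gan, gnum, tolerance = 1e-4)
  }
})

test_that("the voxel discriminator is strictly voxel-local", {
  d <- buildDiscriminator(discriminatorConfig("voxel", filters = c(8, 8)),
                          seed = 3)
  x <- array(rnorm(6^3), dim = c(6, 6, 6))
  invisible(discForward(d, x, train = TRUE))   # warm running stats
  s1 <- discForward(d, x, train = FALSE)
  expect_identical(s1$dims, c(6L, 6L, 6L))
  expect_true(all(s1$scores >= 0 & s1$scores <= 1))
  x2 <- x; x2[3, 4, 2] <- x2[3, 4, 2] + 1
  s2 <- discForward(d, x2, train = FALSE)
  changed <- which(abs(s2$scores - s1$scores) > 1e-12)
  expect_identical(changed, 3L + 6L * (3L + 6L * 1L))
})

test_that("patch/volume discriminators downsample their score maps", {
  dp <- buildDiscriminator(discriminatorConfig("patch", filters = c(4, 8, 8)),
                           seed = 1)
  fw <- discForward(dp, array(rnorm(16^3), dim = c(16, 16, 16)),
                    train = FALSE)
  expect_identical(fw$dims, c(2L, 2L, 2L))  # three stride-2 layers
  expect_true(all(fw$dims < 16L))
  expect_error(discriminatorConfig("blob"))
})

test_that("receptive-field calculus matches the closed form and probes", {
  expect_equal(receptiveField(list(c(1, 1), c(1, 1), c(1, 1))), 1)
  expect_error(receptiveField(list()), "empty")
  # calculator vs gradient-footprint probe on random small stacks
  set.seed(7)
  for (i in 1:4) {
    nl <- sample(1:3, 1)
    ks <- replicate(nl, c(sample(c(1, 3, 5), 1), sample(1:2, 1)),
                    simplify = FALSE)
    cfg <- list(kind2 = "probe", layers = lapply(ks, function(p)
      list(kernel = as.integer(p[1]), stride = as.integer(p[2]),
           filters = 4L)), bn = FALSE)
    rf <- receptiveField(cfg)
    expect_equal(receptiveFieldProbe(cfg, seed = i), rf,
                 label = paste("stack", i))
  }
})

test_that("diversity histograms measure channel-wise SD correctly", {
  base <- array(rnorm(4^3), dim = c(4, 4, 4))
  same <- array(rep(base, 3), dim = c(4, 4, 4, 3))
  h <- diversityHistogram(same, breaks = seq(0, 1, by = 0.1))
  expect_true(all(h$sdMap == 0))
  expect_identical(sum(h$counts[-1]), 0L)
  two <- array(c(array(0, c(4, 4, 4)), array(2, c(4, 4, 4))),
               dim = c(4, 4, 4, 2))
  expect_true(all(diversityHistogram(two)$sdMap == 1))  # population SD of {0,2}
  set.seed(9)
  rnd <- array(rnorm(4 * 4 * 4 * 5), dim = c(4, 4, 4, 5))
  h2 <- diversityHistogram(rnd, breaks = 12)
  brute <- apply(rnd, 1:3, function(v) sqrt(mean((v - mean(v))^2)))
  expect_equal(h2$sdMap, brute, tolerance = 1e-12)
  expect_identical(h2$counts,
                   graphics::hist(brute, breaks = h2$breaks,
                                  plot = FALSE)$counts)
  expect_error(diversityHistogram(array(0, c(2, 2, 2, 1))), "channels")
})

test_that("block activations expose the feature stack in [H,W,D,C] form", {
  gen <- buildGenerator(tinyGenConfig(), seed = 5)
  x <- array(rnorm(8^3), dim = c(8, 8, 8))
  fs <- blockActivations(gen, x, stage = 1, output = "layers")
  expect_identical(dim(fs), c(8L, 8L, 8L, 18L))   # 3 layers x growth 6
  fs2 <- blockActivations(gen, x, stage = 2)
  expect_identical(dim(fs2)[1:3], c(4L, 4L, 4L))  # half resolution
})
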
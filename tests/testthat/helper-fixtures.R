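# Shared fixtures, all generated in code.

# Standard phantom conditions: TOF-MRA-like imbalance (<=0.3% foreground),
# linear radius->intensity law.
standardPhantom <- function(seed = 1L, ...) {
  generatePhantom(phantomSpec(seed = seed, ...))
}

# "Easy" phantom for capability checks: thick, bright vessels, foreground
# ceiling 1%, low background texture.
easyPhantomSpec <- function(seed) {
  phantomSpec(shape = c(64, 64, 64), targetFgFraction = 0.01,
              radiusRange = c(1.0, 2.0), intensityLaw = function(r) 400 * r,
              backgroundTextureSd = 2, nTrees = 2, branchDepth = 2,
              seed = seed)
}

# Tiny generator used in training tests (small widths, fast steps).
tinyGenConfig <- function(conn1 = "fibonacci") {
  generatorConfig(inFilters = 6, stages = list(
    list(connection = conn1, nLayers = 3, growth = 6),
    list(connection = "dense", nLayers = 2, growth = 6)), upFilters = 8)
}

# Even tinier generator for determinism / replay tests.
microGenConfig <- function() {
  generatorConfig(inFilters = 3, stages = list(
    list(connection = "fibonacci", nLayers = 2, growth = 3),
    list(connection = "dense", nLayers = 1, growth = 3)), upFilters = 4)
}

# A small labeled volume (random texture + a bright box) for plumbing tests
# where realistic vasculature is unnecessary. Shape must be even.
boxVolume <- function(shape = c(16, 16, 16), seed = 1L) {
  set.seed(seed)
  x <- array(rnorm(prod(shape)), dim = shape)
  lab <- array(0, dim = shape)
  lo <- pmax(shape %/% 4, 1)
  hi <- pmin(lo + shape %/% 4, shape)
  lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1
  x <- x + 4 * lab
  list(volume = volume3D(x), label = labelVolume(lab))
}

# Brute-force directed boundary distances (oracle for surfaceDistances).
bruteSurfaceDistances <- function(P, G, spacing) {
  bnd <- function(m) {
    d <- dim(m)
    pad <- array(0, d + 2L)
    pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- m
    ix <- 1 + seq_len(d[1]); iy <- 1 + seq_len(d[2]); iz <- 1 + seq_len(d[3])
    nb <- pad[ix - 1, iy, iz] + pad[ix + 1, iy, iz] +
      pad[ix, iy - 1, iz] + pad[ix, iy + 1, iz] +
      pad[ix, iy, iz - 1] + pad[ix, iy, iz + 1]
    which(m == 1 & nb < 6, arr.ind = TRUE)
  }
  cp <- bnd(P); cg <- bnd(G)
  directed <- function(a, b) {
    vapply(seq_len(nrow(a)), function(i) {
      d2 <- ((a[i, 1] - b[, 1]) * spacing[1])^2 +
        ((a[i, 2] - b[, 2]) * spacing[2])^2 +
        ((a[i, 3] - b[, 3]) * spacing[3])^2
      sqrt(min(d2))
    }, numeric(1))
  }
  list(distPG = directed(cp, cg), distGP = directed(cg, cp))
}

# Brute-force per-axis patch count: smallest n with p + (n-1)*stride >= L.
brutePatchCount <- function(L, p, o) {
  s <- p - o
  n <- 1L
  while (p + (n - 1L) * s < L) n <- n + 1L
  n
}
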
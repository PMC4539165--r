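## Shared fixture builders. Everything is generated in code at test time.

## a smoothed disk image on an n x n grid
diskImage <- function(n, centre, radius, smoothWidth = 1) {
  rho <- diskRho(n, centre)
  img <- array(0, c(n, n))
  img[rho <= radius] <- 1
  if (smoothWidth > 0)
    img <- strokemorph:::smoothScalar(img, smoothWidth, c(1, 1))
  img
}

diskRho <- function(n, centre) {
  array(sqrt(outer((seq_len(n) - centre[1])^2,
                   (seq_len(n) - centre[2])^2, "+")), c(n, n))
}

diskMask <- function(n, centre, radius) diskRho(n, centre) <= radius

## constant vector field c over an n x n grid
constantField2d <- function(n, c1, c2) {
  v <- array(0, c(n, n, 2))
  v[, , 1] <- c1
  v[, , 2] <- c2
  v
}

## smooth random velocity field with fixed seed
randomSmoothField2d <- function(n, scale = 1, seed = 1, width = 4) {
  set.seed(seed)
  v <- array(stats::rnorm(n * n * 2), c(n, n, 2))
  v <- strokemorph:::smoothField(v, width, c(1, 1))
  v * scale / max(abs(v))
}

## radial (outward) unit field times magnitude over an n x n grid
radialField2d <- function(n, centre, magnitude) {
  rho <- pmax(diskRho(n, centre), 1e-9)
  v <- array(0, c(n, n, 2))
  v[, , 1] <- magnitude * outer(seq_len(n) - centre[1], rep(1, n)) / rho
  v[, , 2] <- magnitude * outer(rep(1, n), seq_len(n) - centre[2]) / rho
  v
}

## fast metamorphosis parameters for pipeline-level tests
fastParams <- function(...) {
  metamorphosisParams(sigma = 0.1, kernelWidth = 4, nTimesteps = 6L,
                      maxIters = 60L, tol = 1e-5, ...)
}

## small, quick synthetic case: one growing and one shrinking component on a
## 48 x 48 grid
smallCaseConfig <- function(seed = 1L, ...) {
  caseConfig(gridShape = c(48L, 48L),
             centers = rbind(c(34, 14), c(34, 34)),
             radii = c(6, 5),
             growth = rbind(c(2, 1), c(-2, -1)),
             seed = seed, ...)
}

## exact Gaussian samples object
gaussianSamples <- function(a, mu, s, x, direction = "contraction",
                            noiseSd = 0, binWidth = 0.01) {
  y <- a * exp(-(x - mu)^2 / (2 * s^2))
  if (noiseSd > 0) y <- y + stats::rnorm(length(x), 0, noiseSd)
  new("DeformationPerfusionSamples", bins = x, meanDeformation = y,
      counts = rep(1L, length(x)), direction = direction,
      binWidth = binWidth)
}
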
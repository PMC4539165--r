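test_that("mirror reflection: fixed point, coordinate arithmetic, involution", {
  ## a volume symmetric about the midline is its own reflection
  sym <- array(0, c(8, 5))
  sym[, ] <- outer(abs(1:8 - 4.5), 1:5)
  expect_identical(mirrorReflect(sym), sym)

  ## a voxel at sagittal offset +k lands at offset -k
  m <- array(FALSE, c(9, 4))
  m[8, 2] <- TRUE  # offset +3 from midline index 5
  r <- mirrorReflect(m)
  expect_identical(which(r, arr.ind = TRUE)[1, ], c(row = 2L, col = 2L))

  ## double reflection is bitwise the identity, odd and even grids
  set.seed(13)
  for (n1 in c(8, 9)) {
    a <- array(rnorm(n1 * 6), c(n1, 6))
    expect_identical(mirrorReflect(mirrorReflect(a)), a)
  }
  expect_error(mirrorReflect(sym, midline = 12), "midline outside grid")
})

test_that("rMTT is the ratio to the mirrored-region mean", {
  ## hand-worked fixture: 8 x 4 grid, lesion on the right, contralateral
  ## values chosen to average exactly 5.0
  mtt <- array(5, c(8, 4))
  mask <- array(FALSE, c(8, 4))
  mask[6, 2] <- TRUE; mask[7, 3] <- TRUE
  ## mirror of (6,2) is (3,2); of (7,3) is (2,3)
  mtt[3, 2] <- 4; mtt[2, 3] <- 6         # contralateral mean = 5.0
  mtt[6, 2] <- 4; mtt[7, 3] <- 10
  r <- computeRMTT(mtt, mask)
  expect_equal(r@contralateralMean, 5.0)
  expect_equal(r@values[6, 2], 0.8)      # 4 / 5
  expect_equal(r@values[7, 3], 2.0)      # 10 / 5
  expect_true(all(is.na(r@values[!mask])))

  ## self-normalization: every lesion voxel equal to the contralateral mean
  mtt2 <- array(7, c(8, 4))
  r2 <- computeRMTT(mtt2, mask)
  expect_equal(unique(r2@values[mask]), 1.0)
  ## the mirrored (contralateral) region itself normalizes to exactly 1
  mirrored <- mirrorReflect(mask)
  expect_equal(mean(mtt2[mirrored]) / r2@contralateralMean, 1.0)

  ## non-finite contralateral voxels are excluded and counted
  mtt3 <- mtt; mtt3[3, 2] <- NaN
  r3 <- computeRMTT(mtt3, mask)
  expect_equal(r3@contralateralMean, 6.0)
  expect_equal(attr(r3, "nExcluded"), 1L)
})

test_that("deformation-vs-rMTT binning matches a brute-force group-by", {
  d <- c(5, 4)
  mask <- array(FALSE, d); mask[1:10] <- TRUE
  rvals <- c(1.02, 1.02, 1.02, 0.98, 0.98, 1.13, 1.13, 0.87, 1.25, 1.02)
  defs <- c(0.2, 0.4, 0.6, 0.5, 0.7, 0.1, 0.3, 0.9, 0.8, 0.8)
  signs <- rep(-1, 10)
  vals <- array(NA_real_, d); vals[1:10] <- rvals
  rmtt <- new("RMTTMap", values = vals, regionMask = mask,
              contralateralMean = 6, midline = 3, spacing = c(1, 1))
  dm <- new("DeformationMap", magnitude = array(c(defs^2, rep(0, 10)), d),
            sign = array(c(signs, rep(0, 10)), d), lesionMask = mask,
            phase = "acute-subacute", spacing = c(1, 1), converged = TRUE)

  s <- deformationVsRMTT(rmtt, dm, "contraction", binWidth = 0.01)
  ## brute-force group-by with an explicit loop
  centres <- round(rvals / 0.01) * 0.01
  for (b in unique(centres)) {
    i <- which(abs(s@bins - b) < 1e-9)
    expect_length(i, 1L)
    expect_equal(s@meanDeformation[i], mean(defs[centres == b]))
    expect_equal(s@counts[i], sum(centres == b))
  }
  expect_true(all(diff(s@bins) > 0))

  ## single shared rMTT value collapses to one bin with the overall mean
  vals1 <- vals; vals1[1:10] <- 1.5
  rmtt1 <- new("RMTTMap", values = vals1, regionMask = mask,
               contralateralMean = 6, midline = 3, spacing = c(1, 1))
  s1 <- deformationVsRMTT(rmtt1, dm, "contraction")
  expect_equal(s1@bins, 1.5)
  expect_equal(s1@meanDeformation, mean(defs))

  ## no voxels of the requested direction: empty samples, and the fit errors
  s2 <- deformationVsRMTT(rmtt, dm, "expansion")
  expect_length(s2@bins, 0L)
  expect_error(fitDeformationGaussian(s2), "at least 3")

  ## permuting voxel order never changes the binning
  perm <- c(10:1)
  valsP <- array(NA_real_, d); valsP[1:10] <- rvals[perm]
  dmP <- new("DeformationMap",
             magnitude = array(c(defs[perm]^2, rep(0, 10)), d),
             sign = array(c(signs, rep(0, 10)), d), lesionMask = mask,
             phase = "acute-subacute", spacing = c(1, 1), converged = TRUE)
  rmttP <- new("RMTTMap", values = valsP, regionMask = mask,
               contralateralMean = 6, midline = 3, spacing = c(1, 1))
  sP <- deformationVsRMTT(rmttP, dmP, "contraction")
  expect_equal(sP@bins, s@bins)
  expect_equal(sP@meanDeformation, s@meanDeformation)
})

test_that("Gaussian fit recovers exact input to 4 decimals with RMSE ~ 0", {
  x <- seq(0.3, 2.1, by = 0.02)
  s <- gaussianSamples(a = 0.01, mu = 1.2, s = 0.3, x = x)
  f <- fitDeformationGaussian(s)
  expect_true(isConverged(f))
  expect_equal(f@amplitude, 0.01, tolerance = 1e-4)
  expect_equal(f@mean, 1.2, tolerance = 1e-4)
  expect_equal(f@sd, 0.3, tolerance = 1e-4)
  expect_lte(f@rmse, 1e-8)
  ## the interval follows as mu -/+ s
  expect_equal(unname(confidenceInterval(f)), c(0.9, 1.5), tolerance = 1e-4)
})

test_that("Gaussian fit peak is stable under noise across 100 seeds", {
  x <- seq(0.3, 2.1, length.out = 50)
  mus <- vapply(1:100, function(seed) {
    set.seed(seed)
    f <- fitDeformationGaussian(
      gaussianSamples(a = 0.01, mu = 1.2, s = 0.3, x = x, noiseSd = 1e-3))
    f@mean
  }, numeric(1))
  expect_true(all(abs(mus - 1.2) <= 0.05))
})

test_that("confidence interval arithmetic, including degenerate spread", {
  f <- new("GaussianFit", amplitude = 1, mean = 1.0, sd = 0.2, rmse = 0,
           p1 = 0.8, p2 = 1.2, direction = "expansion", converged = TRUE,
           nBins = 10L)
  expect_equal(unname(confidenceInterval(f)), c(0.8, 1.2))
  f0 <- new("GaussianFit", amplitude = 1, mean = 1.0, sd = 0, rmse = 0,
            p1 = 1, p2 = 1, direction = "expansion", converged = TRUE,
            nBins = 10L)
  expect_equal(unname(diff(confidenceInterval(f0))), 0)
})
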
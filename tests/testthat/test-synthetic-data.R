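test_that("a fixed seed reproduces a case voxel for voxel", {
  a <- generateCase(caseConfig(seed = 5L))
  b <- generateCase(caseConfig(seed = 5L))
  expect_identical(a@images$acute@data, b@images$acute@data)
  expect_identical(a@images$final@data, b@images$final@data)
  expect_identical(a@mtt$acute@data, b@mtt$acute@data)
  expect_identical(a@masks, b@masks)
  ## a different seed changes at least the noise
  c <- generateCase(caseConfig(seed = 6L))
  expect_false(identical(a@images$acute@data, c@images$acute@data))
  ## and the global RNG state is left untouched
  set.seed(99); before <- .Random.seed
  generateCase(caseConfig(seed = 5L))
  expect_identical(before, .Random.seed)
})

test_that("zero growth yields identical masks and empty truth masks", {
  cfg <- caseConfig(growth = rbind(c(0, 0), c(0, 0)))
  case <- generateCase(cfg)
  expect_identical(case@masks$acute, case@masks$subacute)
  expect_identical(case@masks$subacute, case@masks$final)
  expect_false(any(case@truthExpansion[["acute-subacute"]]))
  expect_false(any(case@truthContraction[["acute-subacute"]]))
})

test_that("truth masks equal the brute-force set difference of rasterized spheres", {
  cfg <- caseConfig(centers = rbind(c(44, 32)), radii = 8,
                    growth = rbind(c(2, 0)))
  case <- generateCase(cfg)
  ## independent brute force: loop over all voxels, count 8 < rho <= 10
  nExp <- 0L
  for (i in 1:64) for (j in 1:64) {
    rho <- sqrt((i - 44)^2 + (j - 32)^2)
    if (rho > 8 && rho <= 10) nExp <- nExp + 1L
  }
  expect_identical(sum(case@truthExpansion[["acute-subacute"]]), nExp)
  expect_identical(sum(case@truthContraction[["acute-subacute"]]), 0L)
})

test_that("truth masks obey the set algebra of the timepoint masks", {
  for (seed in 1:3) {
    case <- generateCase(smallCaseConfig(seed = seed))
    m1 <- case@masks$acute; m2 <- case@masks$subacute
    expect_identical(case@truthExpansion[["acute-subacute"]], m2 & !m1)
    expect_identical(case@truthContraction[["acute-subacute"]], m1 & !m2)
    expect_identical(case@truthExpansion[["subacute-final"]],
                     case@masks$final & !m2)
    expect_false(any(case@truthExpansion[["acute-subacute"]] &
                       case@truthContraction[["acute-subacute"]]))
  }
})

test_that("rMTT in each designated zone averages to its configured mean", {
  case <- generateCase(caseConfig(seed = 2L))
  spec <- case@config@rmttSpec
  mtt <- case@mtt$acute@data
  ## the contralateral normalizer is the baseline by symmetric construction
  cmean <- mean(mtt[mirrorReflect(case@masks$acute)])
  for (dir in c("contraction", "expansion")) {
    zone <- case@rmttZones[["acute-subacute"]][[dir]]
    vals <- mtt[zone] / cmean
    se <- stats::sd(vals) / sqrt(length(vals))
    expect_lt(abs(mean(vals) - spec[[dir]][["mu"]]), 3 * se + 1e-12)
  }
})

test_that("grown components must stay inside the grid", {
  expect_error(caseConfig(centers = rbind(c(60, 32)), radii = 8,
                          growth = rbind(c(2, 1))),
               "exceeds grid bounds")
})

test_that("applyKnownDisplacement: identity, lattice shift, inversion residual", {
  img <- diskImage(24, c(12, 12), 6)
  ## zero displacement is the identity
  expect_identical(applyKnownDisplacement(img, array(0, c(24, 24, 2))), img)
  ## a uniform integer shift reproduces index shifting exactly
  u <- constantField2d(24, 3, 0)
  out <- applyKnownDisplacement(img, u)
  expect_equal(out[4:24, ], img[1:21, ], tolerance = 1e-12)
  ## forward then backward warp returns close to the input
  us <- randomSmoothField2d(24, scale = 1.5, seed = 3)
  fwd <- applyKnownDisplacement(img, us)
  back <- applyKnownDisplacement(fwd, -us)
  expect_lt(max(abs(back - img)), 0.15)
  expect_lt(mean(abs(back - img)), 0.01)
})
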
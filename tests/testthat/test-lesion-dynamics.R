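## Deformation maps, sign assignment and the mean +/- sd threshold rule.

## build a path with prescribed velocities (no optimization)
pathWithVelocities <- function(vlist, d = dim(vlist[[1]])[1:2]) {
  I <- rep(list(array(0.5, d)), length(vlist) + 1L)
  p <- metamorphosisParams(nTimesteps = length(vlist))
  new("MetamorphosisPath", intensities = I, velocities = vlist,
      maps = integrateFlow(vlist, c(1, 1), stopOnFold = FALSE),
      energyTrace = numeric(0), converged = TRUE, spacing = c(1, 1),
      params = p, obsIndex = c(1L, length(vlist) + 1L),
      endpointResiduals = c(0, 0), momenta = list(),
      normalization = list(offset = 0, scale = 1))
}

test_that("deformation magnitude is the direct time-integrated squared speed", {
  n <- 12
  mask <- diskMask(n, c(6, 6), 4)
  ## zero velocities: magnitude identically zero, sign zero
  zp <- pathWithVelocities(rep(list(array(0, c(n, n, 2))), 3))
  dm <- totalDeformationMap(zp, mask)
  expect_equal(max(abs(dm@magnitude)), 0)
  expect_equal(max(abs(dm@sign)), 0)

  ## uniform speed s over unit time: magnitude == s^2 in the mask
  v <- constantField2d(n, 0.3, 0.4)  # speed 0.5
  up <- pathWithVelocities(rep(list(v), 4))
  dm <- totalDeformationMap(up, mask)
  expect_equal(unique(dm@magnitude[mask]), 0.25, tolerance = 1e-12)
  expect_equal(max(abs(dm@magnitude[!mask])), 0)

  ## arbitrary time-varying field on a tiny fixture: exact brute-force sum
  set.seed(4)
  vl <- replicate(3, array(rnorm(n * n * 2), c(n, n, 2)), simplify = FALSE)
  ap <- pathWithVelocities(vl)
  dm <- totalDeformationMap(ap, mask)
  oracle <- Reduce(`+`, lapply(vl, function(v)
    (v[, , 1]^2 + v[, , 2]^2) / 3))
  expect_equal(dm@magnitude[mask], oracle[mask], tolerance = 1e-12)
})

test_that("sign follows the outward-normal projection of the motion", {
  n <- 21
  mask <- diskMask(n, c(11, 11), 6)
  shell <- mask & !diskMask(n, c(11, 11), 4)

  grow <- pathWithVelocities(rep(list(radialField2d(n, c(11, 11), 0.8)), 2))
  sg <- signDeformation(grow, mask)
  expect_true(all(sg[shell] == 1))

  shrink <- pathWithVelocities(rep(list(-radialField2d(n, c(11, 11), 0.8)), 2))
  ssh <- signDeformation(shrink, mask)
  expect_true(all(ssh[shell] == -1))

  ## translation: leading edge expands, trailing edge contracts, matching
  ## the analytic projection of c onto the disk's radial normal
  trans <- pathWithVelocities(rep(list(constantField2d(n, 0.8, 0)), 2))
  st <- signDeformation(trans, mask)
  radial <- radialField2d(n, c(11, 11), 1)
  proj <- 0.8 * radial[, , 1]
  clear <- shell & abs(proj) > 0.2
  expect_true(all(st[clear] == sign(proj)[clear]))
  ## everything outside the lesion is unsigned
  expect_true(all(st[!mask] == 0))
})

test_that("threshold rule matches brute force on a listed-speed fixture", {
  ## 10 lesion voxels with listed speeds and signs on a 5 x 4 grid
  mask <- array(FALSE, c(5, 4)); mask[1:10] <- TRUE
  speeds <- c(0.1, 0.5, 0.9, 1.2, 0.05, 0.3, 0.7, 1.5, 0.2, 0.8)
  signs <- c(-1, -1, -1, -1, -1, 1, 1, 1, 1, 1)
  dm <- new("DeformationMap",
            magnitude = array(c(speeds^2, rep(0, 10)), c(5, 4)),
            sign = array(c(signs, rep(0, 10)), c(5, 4)),
            lesionMask = mask, phase = "acute-subacute", spacing = c(1, 1),
            converged = TRUE)

  ## independent per-voxel evaluation of the printed rule
  sc <- speeds[signs == -1]; se <- speeds[signs == 1]
  thrC <- mean(sc) - sd(sc)
  bruteC <- signs == -1 & speeds > thrC
  thrEcorr <- mean(se) + sd(se)
  bruteEcorr <- signs == 1 & speeds > thrEcorr
  thrEprint <- mean(sc) + sd(sc)
  bruteEprint <- signs == 1 & speeds > thrEprint

  reg <- thresholdDynamicRegions(dm, rule = "corrected")
  expect_identical(reg@contractingMask[1:10], bruteC)
  expect_identical(reg@expandingMask[1:10], bruteEcorr)
  expect_equal(unname(reg@thresholds), c(thrC, thrEcorr))
  expect_equal(unname(reg@proportions),
               100 * c(sum(bruteC), sum(bruteEcorr)) / 10)

  regP <- thresholdDynamicRegions(dm, rule = "as-printed")
  expect_identical(regP@expandingMask[1:10], bruteEprint)
  ## contraction is identical under both rule variants
  expect_identical(regP@contractingMask, reg@contractingMask)
})

test_that("threshold rule edge cases: uniform speeds, zero map, empty directions", {
  mask <- array(TRUE, c(4, 3))
  ## uniform contraction speed: sd = 0, strict '>' empties the mask
  dm <- new("DeformationMap", magnitude = array(0.49, c(4, 3)),
            sign = array(-1, c(4, 3)), lesionMask = mask,
            phase = "acute-subacute", spacing = c(1, 1), converged = TRUE)
  reg <- thresholdDynamicRegions(dm)
  expect_false(any(reg@contractingMask))
  ## no expanding voxels at all: NA threshold, empty mask
  expect_true(is.na(reg@thresholds["expansion"]))
  expect_false(any(reg@expandingMask))

  ## all-zero map: both masks empty, proportions 0
  dm0 <- new("DeformationMap", magnitude = array(0, c(4, 3)),
             sign = array(0, c(4, 3)), lesionMask = mask,
             phase = "acute-subacute", spacing = c(1, 1), converged = TRUE)
  reg0 <- thresholdDynamicRegions(dm0)
  expect_equal(unname(reg0@proportions), c(0, 0))
})

test_that("the rule is scale-equivariant and the masks nest monotonically", {
  set.seed(11)
  n <- 10
  mask <- array(TRUE, c(n, n))
  mag <- array(rexp(n * n), c(n, n))
  sgn <- array(sample(c(-1, 1), n * n, TRUE), c(n, n))
  dm <- new("DeformationMap", magnitude = mag, sign = sgn, lesionMask = mask,
            phase = "acute-subacute", spacing = c(1, 1), converged = TRUE)
  reg <- thresholdDynamicRegions(dm)

  ## multiplying all velocities by k multiplies magnitude by k^2 and leaves
  ## the mean +/- sd masks unchanged
  dmk <- new("DeformationMap", magnitude = 9 * mag, sign = sgn,
             lesionMask = mask, phase = "acute-subacute", spacing = c(1, 1),
             converged = TRUE)
  regk <- thresholdDynamicRegions(dmk)
  expect_identical(regk@contractingMask, reg@contractingMask)
  expect_identical(regk@expandingMask, reg@expandingMask)
  expect_equal(unname(regk@thresholds), unname(3 * reg@thresholds))

  ## raising the threshold never grows a mask
  speed <- sqrt(mag)
  for (thr in c(reg@thresholds["contraction"] + c(0.1, 0.5, 1))) {
    higher <- sgn == -1 & speed > thr
    expect_true(all(which(higher) %in% which(reg@contractingMask)))
  }
  ## masks disjoint and inside the lesion
  expect_false(any(reg@contractingMask & reg@expandingMask))
  expect_true(all(mask[reg@contractingMask | reg@expandingMask]))
})

test_that("volumetric proportions are exact percentages of the lesion volume", {
  mask <- array(FALSE, c(20, 20)); mask[1:200] <- TRUE
  full <- list(contracting = mask, expanding = array(FALSE, c(20, 20)))
  expect_equal(unname(volumetricProportions(full, mask)), c(100, 0))
  seven <- array(FALSE, c(20, 20)); seven[1:7] <- TRUE
  expect_equal(
    unname(volumetricProportions(list(contracting = seven,
                                      expanding = seven), mask)),
    c(3.5, 3.5))
  expect_error(volumetricProportions(full, array(FALSE, c(20, 20))), "empty")
})
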
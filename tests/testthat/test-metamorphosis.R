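test_that("advection: zero velocity and flat fields are fixed points; ramps transport analytically", {
  img <- diskImage(16, c(8, 8), 4)
  zeroV <- array(0, c(16, 16, 2))
  expect_identical(advectStep(img, zeroV, dt = 0.5), img)

  flat <- array(0.7, c(16, 16))
  anyV <- constantField2d(16, 1.3, -0.4)
  expect_equal(advectStep(flat, anyV, dt = 0.5), flat, tolerance = 1e-12)

  ## linear ramp I(x) = x under constant velocity c: I -> x - c dt
  ramp <- array(rep(1:16, times = 16), c(16, 16))
  out <- advectStep(ramp, constantField2d(16, 2, 0), dt = 0.5)
  interior <- 3:14
  expect_equal(out[interior, ], ramp[interior, ] - 1, tolerance = 1e-12)
})

test_that("flow integration: identity, exact translation, fine-step oracle", {
  zeroV <- list(array(0, c(16, 16, 2)))
  maps <- integrateFlow(zeroV, spacing = c(1, 1))
  expect_equal(max(abs(maps[[2]])), 0)

  ## constant velocity over unit time translates by exactly c
  v <- constantField2d(16, 1.5, -0.5)
  maps <- integrateFlow(rep(list(v), 4), spacing = c(1, 1))
  u <- maps[[5]]
  expect_lt(max(abs(u[, , 1] - 1.5)), 0.25)
  expect_lt(max(abs(u[, , 2] + 0.5)), 0.25)
  expect_gt(attr(maps, "minJacobian"), 0)

  ## random smooth field: coarse integration approaches a fine-step oracle
  vs <- randomSmoothField2d(24, scale = 2, seed = 9)
  fine <- integrateFlow(rep(list(vs), 128), spacing = c(1, 1),
                        stopOnFold = FALSE)
  uf <- fine[[129]]
  err <- vapply(c(2L, 8L, 32L), function(T) {
    m <- integrateFlow(rep(list(vs), T), spacing = c(1, 1),
                       stopOnFold = FALSE)
    max(abs(m[[T + 1L]] - uf))
  }, numeric(1))
  expect_true(all(diff(err) < 0))     # error shrinks as steps increase
  expect_lt(err[3], 0.05)
})

test_that("path energy: identity path, direct-summation oracle, sigma scaling", {
  d <- c(2, 2)  # 4-voxel image
  I0 <- array(c(0, 0.2, 0.4, 0.8), d)
  IT <- array(c(0.3, 0.2, 0.1, 1.0), d)
  T <- 4L
  params <- metamorphosisParams(sigma = 0.2, nTimesteps = T)

  ## identity path: both integrands vanish
  idPath <- metamorphosisPathFromFrames(rep(list(I0), T + 1L),
                                        params = params)
  expect_equal(as.numeric(pathEnergy(idPath, params)), 0)

  ## v = 0, linear interpolation: U = (1/sigma^2) sum_t ||dI/dt||^2 dt,
  ## hand-rolled independent sum (L2 norm carries the voxel volume = 1)
  frames <- lapply(0:T, function(t) I0 + (t / T) * (IT - I0))
  linPath <- metamorphosisPathFromFrames(frames, params = params)
  dI <- (IT - I0) / T
  oracle <- sum(vapply(1:T, function(t) sum((dI / (1 / T))^2) * (1 / T),
                       numeric(1))) / 0.2^2
  expect_equal(as.numeric(pathEnergy(linPath, params)), oracle,
               tolerance = 1e-12)

  ## doubling sigma divides the (pure-fidelity) energy by 4
  params2 <- metamorphosisParams(sigma = 0.4, nTimesteps = T)
  expect_equal(as.numeric(pathEnergy(linPath, params2)), oracle / 4,
               tolerance = 1e-12)
})

test_that("metamorphosis of an image onto itself is the zero path", {
  img <- diskImage(24, c(12, 12), 6)
  p <- metamorphosisParams(sigma = 0.1, kernelWidth = 4, nTimesteps = 4L,
                           maxIters = 10L)
  path <- metamorphose(img, img, p)
  expect_true(isConverged(path))
  expect_equal(as.numeric(pathEnergy(path)), 0, tolerance = 1e-12)
  expect_equal(max(vapply(velocities(path), function(v) max(abs(v)),
                          numeric(1))), 0)
  expect_equal(max(path@endpointResiduals), 0, tolerance = 1e-12)
})

test_that("a huge sigma buys no deformation: the path stays photometric", {
  src <- diskImage(24, c(10, 12), 5)
  tgt <- diskImage(24, c(14, 12), 5)
  p <- metamorphosisParams(sigma = 1e6, kernelWidth = 4, nTimesteps = 4L,
                           maxIters = 40L)
  path <- metamorphose(src, tgt, p)
  U <- pathEnergy(path)
  expect_lt(attr(U, "kinetic"), 1e-6 * max(as.numeric(U), 1e-300))
})

test_that("translated disk: the recovered flow matches the true translation inside the disk", {
  n <- 32
  src <- diskImage(n, c(14, 16), 7)
  tgt <- diskImage(n, c(16, 16), 7)
  p <- metamorphosisParams(sigma = 0.05, kernelWidth = 7, nTimesteps = 8L,
                           maxIters = 250L)
  path <- metamorphose(src, tgt, p)
  u <- flowMaps(path)[[9]]
  inside <- diskMask(n, c(14, 16), 7)
  err <- sqrt((u[, , 1][inside] - 2)^2 + (u[, , 2][inside])^2)
  expect_lt(mean(err), 0.5)
  ## the energy trace never increases and the flow never folds
  expect_true(all(diff(energyTrace(path)) <= 1e-9 * energyTrace(path)[1]))
  jd <- vapply(flowMaps(path), function(m)
    min(strokemorph:::jacobianDet(m, c(1, 1))), numeric(1))
  expect_true(all(jd > 0))
})

test_that("morphing A->B and B->A both fit their targets (symmetry sanity)", {
  A <- diskImage(24, c(11, 12), 5)
  B <- diskImage(24, c(13, 12), 6)
  p <- metamorphosisParams(sigma = 0.1, kernelWidth = 4, nTimesteps = 4L,
                           maxIters = 60L)
  fwd <- metamorphose(A, B, p)
  bwd <- metamorphose(B, A, p)
  expect_lte(max(fwd@endpointResiduals), p@endpointTol)
  expect_lte(max(bwd@endpointResiduals), p@endpointTol)
  expect_true(all(diff(energyTrace(fwd)) <= 1e-9 * energyTrace(fwd)[1]))
  expect_true(all(diff(energyTrace(bwd)) <= 1e-9 * energyTrace(bwd)[1]))
})

test_that("halving the timestep changes the converged energy by a bounded factor", {
  src <- diskImage(24, c(11, 12), 5)
  tgt <- diskImage(24, c(13, 12), 5)
  U <- vapply(c(3L, 6L), function(T) {
    p <- metamorphosisParams(sigma = 0.1, kernelWidth = 4, nTimesteps = T,
                             maxIters = 120L)
    as.numeric(pathEnergy(metamorphose(src, tgt, p)))
  }, numeric(1))
  expect_lt(max(U) / min(U), 2)
})

test_that("multi-target reduces to the two-image problem and chains exactly through observations", {
  A <- diskImage(24, c(11, 12), 4)
  B <- diskImage(24, c(12, 12), 5)
  C <- diskImage(24, c(13, 12), 6)
  p <- metamorphosisParams(sigma = 0.1, kernelWidth = 4, nTimesteps = 3L,
                           maxIters = 50L)

  two <- multiTargetMetamorphose(list(A, B), p)
  ref <- metamorphose(A, B, p)
  expect_equal(two@velocities, ref@velocities, tolerance = 1e-12)
  expect_equal(utils::tail(energyTrace(two), 1),
               utils::tail(energyTrace(ref), 1), tolerance = 1e-12)

  ## identical observations: nothing moves
  idchain <- multiTargetMetamorphose(list(A, A, A), p)
  expect_equal(max(vapply(velocities(idchain), function(v) max(abs(v)),
                          numeric(1))), 0)

  ## growing three-frame disk: every observation is hit within tolerance,
  ## checked by direct image differencing against the normalized inputs
  chain <- multiTargetMetamorphose(list(A, B, C), p)
  expect_equal(length(velocities(chain)), 6L)
  expect_equal(length(intensities(chain)), 7L)
  nrm <- chain@normalization
  obsN <- lapply(list(A, B, C), function(o) (o - nrm$offset) / nrm$scale)
  for (i in 1:3) {
    res <- max(abs(intensities(chain)[[chain@obsIndex[i]]] - obsN[[i]]))
    expect_lte(res, p@endpointTol)
  }
  ## the accumulated map is continuous across the segment boundary
  expect_equal(length(flowMaps(chain)), 7L)
})
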
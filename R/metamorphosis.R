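## Metamorphosis core: joint geometric + photometric registration.
##
## The model estimates, between a source and a target image, a discrete path
## of intensity frames I_0..I_T and piecewise-constant velocity fields
## v_1..v_T minimizing
##
##   U(I, v) = sum_t |v_t|_V^2 dt + (1/sigma^2) sum_t ||r_t||_L2^2 dt ,
##   r_t = (I_{t+1} - I_t)/dt + grad(I_t) . v_t ,
##
## where |v|_V^2 is the smoothness (V-)norm realized by a Gaussian kernel K
## acting on a momentum field m (v = K m, |v|_V^2 = <m, v>), and r_t is the
## residual of the advection relation: the part of the intensity change not
## explained by transport, i.e. the photometric (intensity-creation) path.
## Endpoints I_0 and I_T are fixed to the observed images, so the path fits
## the observations exactly; the optimizer alternates backtracking gradient
## steps on all momenta (intensities fixed) and on the interior intensity
## frames (velocities fixed).

#' Advect an intensity field one time step under a velocity field
#'
#' Semi-Lagrangian transport: the returned image at voxel x takes the value
#' of the input at `x - dt * v(x)` (clamped multilinear interpolation), the
#' pure-transport solution of `dI/dt + grad(I) . v = 0` over one step.
#'
#' @param intensity a [ScalarVolume-class] or numeric array.
#' @param velocity a vector field array of dim `c(dim(intensity), D)`, mm per
#'   unit time.
#' @param dt time step (> 0).
#' @param spacing voxel spacing in mm (ignored when `intensity` is a
#'   `ScalarVolume`).
#' @return Transported intensity, same container type as the input.
#' @examples
#' img <- array(rep(1:8, each = 8), c(8, 8))  # ramp along axis 2
#' v <- array(0, c(8, 8, 2)); v[, , 2] <- 1
#' out <- advectStep(img, v, dt = 1)
#' out[4, 5] == img[4, 4]
#' @export
advectStep <- function(intensity, velocity, dt, spacing = 1) {
  isVol <- is(intensity, "ScalarVolume")
  img <- asVolumeArray(intensity)
  if (isVol) spacing <- intensity@spacing
  d <- dim(img)
  spacing <- rep_len(spacing, length(d))
  if (!identical(dim(velocity)[seq_along(d)], d) ||
      length(dim(velocity)) != length(d) + 1L)
    stop("velocity field shape does not match the intensity grid")
  if (dt <= 0) stop("dt must be > 0")
  pts <- gridCoords(d)
  for (k in seq_along(d)) {
    pts[, k] <- pts[, k] - dt * as.vector(fieldComponent(velocity, k)) / spacing[k]
  }
  out <- array(interpScalar(img, pts), d)
  if (isVol) scalarVolume(out, spacing) else out
}

#' Integrate a time-dependent velocity field into a diffeomorphic flow
#'
#' Forward-Euler integration of the flow equation `dphi/dt = v_t(phi)`,
#' `phi_0(x) = x`, with the velocities piecewise constant over `length(v)`
#' uniform steps on one unit of path time. The accumulated maps are returned
#' as displacement fields in mm.
#'
#' @param velocities list of vector-field arrays sharing one grid.
#' @param spacing voxel spacing in mm.
#' @param duration total integration time (default 1; each velocity then acts
#'   for `duration / length(velocities)`).
#' @param stopOnFold error when the final map's Jacobian determinant is not
#'   positive everywhere (a too-large step; reduce the step size or increase
#'   the number of timesteps). When `FALSE` the fold is reported via the
#'   `minJacobian` attribute only.
#' @return List of `length(velocities) + 1` displacement arrays
#'   (first = identity, i.e. all zero), with attribute `minJacobian`.
#' @examples
#' v <- array(0, c(16, 16, 2)); v[, , 1] <- 2  # 2 mm/unit time along axis 1
#' maps <- integrateFlow(list(v, v), spacing = c(1, 1))
#' range(maps[[3]][, , 1])  # ~2 mm displacement after unit time
#' @export
integrateFlow <- function(velocities, spacing = 1, duration = 1,
                          stopOnFold = TRUE) {
  stopifnot(length(velocities) >= 1L)
  fd <- dim(velocities[[1]])
  D <- length(fd) - 1L
  d <- fd[seq_len(D)]
  spacing <- rep_len(spacing, D)
  for (v in velocities) if (!identical(dim(v), fd))
    stop("all velocity fields must share one grid")
  dt <- duration / length(velocities)
  id <- gridCoords(d)
  maps <- vector("list", length(velocities) + 1L)
  maps[[1L]] <- zeroField(d)
  u <- matrix(0, nrow(id), D)  # displacement in mm at each grid point
  for (t in seq_along(velocities)) {
    pos <- id
    for (k in seq_len(D)) pos[, k] <- pos[, k] + u[, k] / spacing[k]
    u <- u + dt * interpField(velocities[[t]], pos)
    m <- zeroField(d)
    for (k in seq_len(D)) m <- setFieldComponent(m, k, array(u[, k], d))
    maps[[t + 1L]] <- m
  }
  minJ <- min(jacobianDet(maps[[length(maps)]], spacing))
  if (stopOnFold && minJ <= 0)
    stop(sprintf(paste0("flow integration produced a folded map ",
                        "(min Jacobian determinant %.3g <= 0); reduce the ",
                        "step size or increase n_timesteps"), minJ))
  attr(maps, "minJacobian") <- minJ
  maps
}

## ---------------------------------------------------------------------------
## Energy
## ---------------------------------------------------------------------------

## Energy of a state given intensity frames, velocities and momenta.
## L2 norms carry the voxel-volume weight so values are grid-resolution
## consistent. Returns total, kinetic and fidelity parts.
#' @keywords internal
#' @noRd
energyParts <- function(I, v, m, sigma, dt, spacing, grads = NULL) {
  vol <- prod(spacing)
  kinetic <- 0
  fidelity <- 0
  for (t in seq_along(v)) {
    if (length(m)) kinetic <- kinetic + dt * vol * sum(m[[t]] * v[[t]])
    g <- if (is.null(grads)) imageGradient(I[[t]], spacing) else grads[[t]]
    r <- (I[[t + 1L]] - I[[t]]) / dt + fieldDot(g, v[[t]])
    fidelity <- fidelity + dt * vol * sum(r * r)
  }
  fidelity <- fidelity / sigma^2
  list(total = kinetic + fidelity, kinetic = kinetic, fidelity = fidelity)
}

#' Cost of a metamorphosis path
#'
#' Evaluates the discrete metamorphosis functional: the kinetic term (V-norm
#' of the velocities, integrated over path time) plus `1/sigma^2` times the
#' fidelity term (squared L2 norm of the advection residual
#' `(I_{t+1} - I_t)/dt + grad(I_t) . v_t`, integrated over path time). L2
#' norms include the voxel-volume weight.
#'
#' @param path a [MetamorphosisPath-class]. Paths built by [metamorphose()]
#'   carry the momentum fields needed for the kinetic term; hand-built paths
#'   must either carry momenta or have all-zero velocities.
#' @param params a [MetamorphosisParams-class]; `sigma` is taken from here.
#' @return Numeric total energy, with attributes `kinetic` and `fidelity`.
#' @export
pathEnergy <- function(path, params = path@params) {
  stopifnot(is(path, "MetamorphosisPath"))
  m <- path@momenta
  if (!length(m)) {
    vmax <- max(vapply(path@velocities, function(v) max(abs(v)), numeric(1)))
    if (vmax > 0)
      stop("path carries no momenta; the kinetic term is only defined for ",
           "paths built by metamorphose() or zero-velocity paths")
  }
  dt <- 1 / params@nTimesteps
  e <- energyParts(path@intensities, path@velocities, m, params@sigma, dt,
                   path@spacing)
  structure(e$total, kinetic = e$kinetic, fidelity = e$fidelity)
}

#' Build a metamorphosis path from explicit frames
#'
#' Assembles a [MetamorphosisPath-class] from given intensity frames and
#' velocity fields without optimization — useful for constructing reference
#' paths (e.g. a zero-velocity, linearly interpolated photometric path).
#'
#' @param intensities list of T+1 scalar arrays.
#' @param velocities list of T vector fields; `NULL` for all-zero.
#' @param params a [MetamorphosisParams-class] (its `nTimesteps` must equal T).
#' @param spacing voxel spacing in mm.
#' @return A [MetamorphosisPath-class] with empty energy trace.
#' @export
metamorphosisPathFromFrames <- function(intensities, velocities = NULL,
                                        params = metamorphosisParams(
                                          nTimesteps = length(intensities) - 1L),
                                        spacing = 1) {
  d <- dim(intensities[[1L]])
  spacing <- rep_len(spacing, length(d))
  T <- length(intensities) - 1L
  if (is.null(velocities))
    velocities <- replicate(T, zeroField(d), simplify = FALSE)
  maps <- integrateFlow(velocities, spacing, stopOnFold = FALSE)
  attr(maps, "minJacobian") <- NULL
  new("MetamorphosisPath", intensities = intensities,
      velocities = velocities, maps = maps, energyTrace = numeric(0),
      converged = TRUE, spacing = spacing, params = params,
      obsIndex = c(1L, T + 1L), endpointResiduals = c(0, 0),
      momenta = list(), normalization = list(offset = 0, scale = 1))
}

## ---------------------------------------------------------------------------
## Optimizer
## ---------------------------------------------------------------------------

## gradient of U with respect to every momentum field
#' @keywords internal
#' @noRd
gradMomenta <- function(I, v, m, sigma, dt, spacing, kernelWidth,
                        grads = NULL) {
  vol <- prod(spacing)
  lapply(seq_along(v), function(t) {
    g <- if (is.null(grads)) imageGradient(I[[t]], spacing) else grads[[t]]
    r <- (I[[t + 1L]] - I[[t]]) / dt + fieldDot(g, v[[t]])
    rg <- g
    D <- length(spacing)
    for (k in seq_len(D))
      rg <- setFieldComponent(rg, k, r * fieldComponent(g, k))
    2 * dt * vol * (v[[t]] + smoothField(rg, kernelWidth, spacing) / sigma^2)
  })
}

## gradient of U with respect to the interior intensity frames (2..T)
#' @keywords internal
#' @noRd
gradInterior <- function(I, v, sigma, dt, spacing, grads = NULL) {
  T <- length(v)
  if (T < 2L) return(list())
  vol <- prod(spacing)
  r <- lapply(seq_len(T), function(t) {
    g <- if (is.null(grads)) imageGradient(I[[t]], spacing) else grads[[t]]
    (I[[t + 1L]] - I[[t]]) / dt + fieldDot(g, v[[t]])
  })
  lapply(2:T, function(j) {
    rv <- v[[j]]
    D <- length(spacing)
    for (k in seq_len(D))
      rv <- setFieldComponent(rv, k, r[[j]] * fieldComponent(v[[j]], k))
    (2 * dt * vol / sigma^2) *
      (r[[j - 1L]] / dt - r[[j]] / dt - fieldDivergence(rv, spacing))
  })
}

#' @keywords internal
#' @noRd
flowIsDiffeomorphic <- function(v, spacing) {
  maps <- integrateFlow(v, spacing, stopOnFold = FALSE)
  attr(maps, "minJacobian") > 0
}

## core two-image solver on normalized arrays; returns optimizer state
#' @keywords internal
#' @noRd
metamorphoseCore <- function(source, target, params, spacing) {
  d <- dim(source)
  D <- length(d)
  T <- params@nTimesteps
  dt <- 1 / T
  sigma <- params@sigma
  kw <- params@kernelWidth

  ## initialization: photometric-only path (linear intensity interpolation)
  I <- lapply(0:T, function(t) source + (t / T) * (target - source))
  m <- replicate(T, zeroField(d), simplify = FALSE)
  v <- m

  grads <- lapply(I[seq_len(T)], imageGradient, spacing = spacing)
  e <- energyParts(I, v, m, sigma, dt, spacing, grads)
  U <- e$total
  trace <- U
  stepV <- params@stepSize
  stepI <- params@stepSize
  converged <- FALSE
  maxBacktrack <- 25L

  for (iter in seq_len(params@maxIters)) {
    Uprev <- U

    ## --- velocity sweep: one backtracking gradient step on all momenta ----
    gm <- gradMomenta(I, v, m, sigma, dt, spacing, kw, grads)
    for (bt in seq_len(maxBacktrack)) {
      mNew <- lapply(seq_len(T), function(t) m[[t]] - stepV * gm[[t]])
      vNew <- lapply(mNew, smoothField, widthMm = kw, spacing = spacing)
      eNew <- energyParts(I, vNew, mNew, sigma, dt, spacing, grads)
      if (!is.finite(eNew$total))
        stop(sprintf(paste0("non-finite energy in velocity update at ",
                            "iteration %d (step %.3g); the problem is ",
                            "ill-scaled"), iter, stepV))
      if (eNew$total <= U) {
        if (flowIsDiffeomorphic(vNew, spacing)) {
          m <- mNew; v <- vNew; U <- eNew$total
          stepV <- min(stepV * 1.5, params@stepSize * 64)
          break
        }
      }
      stepV <- stepV / 2
    }

    ## --- intensity sweep: one backtracking step on interior frames --------
    if (T >= 2L) {
      gI <- gradInterior(I, v, sigma, dt, spacing, grads)
      for (bt in seq_len(maxBacktrack)) {
        INew <- I
        for (j in 2:T) INew[[j]] <- I[[j]] - stepI * gI[[j - 1L]]
        gradsNew <- c(grads[1L],
                      lapply(INew[2:T], imageGradient, spacing = spacing))
        eNew <- energyParts(INew, v, m, sigma, dt, spacing, gradsNew)
        if (!is.finite(eNew$total))
          stop(sprintf(paste0("non-finite energy in intensity update at ",
                              "iteration %d (step %.3g)"), iter, stepI))
        if (eNew$total <= U) {
          I <- INew; U <- eNew$total; grads <- gradsNew
          stepI <- min(stepI * 1.5, params@stepSize * 64)
          break
        }
        stepI <- stepI / 2
      }
    }

    trace <- c(trace, U)
    if (Uprev - U <= params@tol * max(abs(Uprev), .Machine$double.eps)) {
      converged <- TRUE
      break
    }
  }
  list(I = I, v = v, m = m, trace = trace, converged = converged)
}

#' Metamorphose a source image into a target image
#'
#' Estimates the optimal metamorphosis path from `source` to `target` by
#' alternating steepest gradient descent on the discrete cost functional (one
#' backtracking step on all momentum fields with intensities fixed, then one
#' on the interior intensity frames with velocities fixed). The endpoint
#' frames are the observed images, so the path fits both exactly; all
#' accepted iterates keep the flow diffeomorphic (positive Jacobian
#' determinant), with steps that would fold the grid rejected and the step
#' size halved.
#'
#' Intensities are jointly min-max normalized to [0, 1] before optimization;
#' the constants are stored in the returned path.
#'
#' @param source,target [ScalarVolume-class] objects or numeric arrays on one
#'   grid.
#' @param params a [MetamorphosisParams-class].
#' @param spacing voxel spacing in mm (ignored for `ScalarVolume` input).
#' @return A [MetamorphosisPath-class]. `isConverged(path)` is `FALSE` when
#'   the iteration cap was reached before the relative energy decrease fell
#'   below `tol` (the best path found is still returned).
#' @examples
#' src <- array(0, c(16, 16)); src[6:11, 6:11] <- 1
#' path <- metamorphose(src, src,
#'                      metamorphosisParams(nTimesteps = 2L, maxIters = 5L))
#' pathEnergy(path)  # identity problem: zero energy
#' @export
metamorphose <- function(source, target, params = metamorphosisParams(),
                         spacing = 1) {
  if (is(source, "ScalarVolume")) spacing <- source@spacing
  src <- asVolumeArray(source)
  tgt <- asVolumeArray(target)
  if (!identical(dim(src), dim(tgt)))
    stop("source and target must share one grid")
  d <- dim(src)
  spacing <- rep_len(spacing, length(d))

  nrm <- minMaxNormalize(array(c(src, tgt), c(d, 2L)))
  srcN <- (src - nrm$offset) / nrm$scale
  tgtN <- (tgt - nrm$offset) / nrm$scale

  st <- metamorphoseCore(srcN, tgtN, params, spacing)
  maps <- integrateFlow(st$v, spacing, stopOnFold = FALSE)
  minJ <- attr(maps, "minJacobian")
  attr(maps, "minJacobian") <- NULL
  if (minJ <= 0)
    warning(sprintf("final flow map has min Jacobian determinant %.3g", minJ))
  T <- params@nTimesteps
  res <- c(max(abs(st$I[[1L]] - srcN)), max(abs(st$I[[T + 1L]] - tgtN)))
  new("MetamorphosisPath", intensities = st$I, velocities = st$v,
      maps = maps, energyTrace = st$trace, converged = st$converged,
      spacing = spacing, params = params, obsIndex = c(1L, T + 1L),
      endpointResiduals = res, momenta = st$m,
      normalization = list(offset = nrm$offset, scale = nrm$scale))
}

#' Metamorphose through an ordered sequence of observations
#'
#' Estimates one metamorphosis path constrained to pass exactly through every
#' observation in order. Because observations are fixed path knots, the
#' problem decouples into independent two-image segments whose velocity and
#' intensity sequences are concatenated; the accumulated diffeomorphism is
#' continued across segment boundaries so `flowMaps()` is continuous. Each
#' segment spans one unit of path time (`nTimesteps` steps).
#'
#' @param observations list of >= 2 images ([ScalarVolume-class] or arrays)
#'   on one grid, in time order.
#' @param params a [MetamorphosisParams-class].
#' @param spacing voxel spacing in mm (ignored for `ScalarVolume` input).
#' @return A [MetamorphosisPath-class]; `obsIndex` marks the frames pinned to
#'   the observations and `endpointResiduals` their max-abs residuals.
#' @export
multiTargetMetamorphose <- function(observations, params = metamorphosisParams(),
                                    spacing = 1) {
  if (length(observations) < 2L) stop("need at least two observations")
  if (is(observations[[1L]], "ScalarVolume"))
    spacing <- observations[[1L]]@spacing
  obs <- lapply(observations, asVolumeArray)
  d <- dim(obs[[1L]])
  for (o in obs) if (!identical(dim(o), d))
    stop("all observations must share one grid")
  spacing <- rep_len(spacing, length(d))

  nrm <- minMaxNormalize(array(unlist(obs), c(d, length(obs))))
  obsN <- lapply(obs, function(o) (o - nrm$offset) / nrm$scale)

  T <- params@nTimesteps
  nSeg <- length(obs) - 1L
  I <- list(obsN[[1L]])
  v <- list(); m <- list()
  traces <- vector("list", nSeg)
  conv <- logical(nSeg)
  for (s in seq_len(nSeg)) {
    st <- metamorphoseCore(obsN[[s]], obsN[[s + 1L]], params, spacing)
    I <- c(I, st$I[-1L])
    v <- c(v, st$v)
    m <- c(m, st$m)
    traces[[s]] <- st$trace
    conv[s] <- st$converged
  }
  len <- max(lengths(traces))
  trace <- rowSums(vapply(traces, function(tr)
    c(tr, rep(tr[length(tr)], len - length(tr))), numeric(len)))
  maps <- integrateFlow(v, spacing, duration = nSeg, stopOnFold = FALSE)
  minJ <- attr(maps, "minJacobian")
  attr(maps, "minJacobian") <- NULL
  if (minJ <= 0)
    warning(sprintf("final flow map has min Jacobian determinant %.3g", minJ))
  obsIdx <- as.integer(seq(1L, nSeg * T + 1L, by = T))
  res <- vapply(seq_along(obsN), function(i)
    max(abs(I[[obsIdx[i]]] - obsN[[i]])), numeric(1))
  new("MetamorphosisPath", intensities = I, velocities = v, maps = maps,
      energyTrace = trace, converged = all(conv), spacing = spacing,
      params = params, obsIndex = obsIdx, endpointResiduals = res,
      momenta = m, normalization = list(offset = nrm$offset, scale = nrm$scale))
}
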
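## Low-level grid operators shared by all modules.
##
## Conventions used throughout the package:
##  * scalar images are plain numeric arrays, 2D (nx, ny) or 3D (nx, ny, nz);
##    axis 1 is the left-right (sagittal) axis used for mirror reflection;
##  * vector fields are numeric arrays of dim c(dim(image), D) where
##    D = length(dim(image)); component k is displacement/velocity along axis
##    k, in millimetres;
##  * `spacing` is the voxel size in mm per axis (length D);
##  * sampling positions are 1-based voxel-index coordinates; out-of-grid
##    samples clamp to the boundary value.

#' @keywords internal
#' @noRd
spatialDims <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array, got a vector")
  d
}

## n x D matrix of the voxel-centre index coordinates of a grid, in array order
#' @keywords internal
#' @noRd
gridCoords <- function(d) {
  D <- length(d)
  out <- matrix(0, prod(d), D)
  each <- 1L
  for (k in seq_len(D)) {
    out[, k] <- rep(rep(seq_len(d[k]), each = each), length.out = prod(d))
    each <- each * d[k]
  }
  out
}

## Multilinear interpolation of a scalar array at fractional index positions.
## pts: n x D matrix. Clamped (replicate) boundary handling.
#' @keywords internal
#' @noRd
interpScalar <- function(img, pts) {
  d <- dim(img)
  D <- length(d)
  stopifnot(ncol(pts) == D)
  f <- floor(pts)
  w <- pts - f
  n <- nrow(pts)
  out <- numeric(n)
  for (corner in 0:(2^D - 1L)) {
    idx <- matrix(0L, n, D)
    wt <- rep(1, n)
    for (k in seq_len(D)) {
      hi <- bitwAnd(corner, bitwShiftL(1L, k - 1L)) > 0L
      ik <- f[, k] + if (hi) 1 else 0
      wt <- wt * (if (hi) w[, k] else 1 - w[, k])
      idx[, k] <- pmin.int(pmax.int(as.integer(ik), 1L), d[k])
    }
    out <- out + wt * img[idx]
  }
  out
}

## Interpolate each component of a vector field at fractional positions.
## Returns an n x D matrix.
#' @keywords internal
#' @noRd
interpField <- function(field, pts) {
  fd <- dim(field)
  D <- length(fd) - 1L
  vapply(seq_len(D), function(k) {
    comp <- array(fieldComponent(field, k), dim = fd[seq_len(D)])
    interpScalar(comp, pts)
  }, numeric(nrow(pts)))
}

#' @keywords internal
#' @noRd
fieldComponent <- function(field, k) {
  fd <- dim(field)
  D <- length(fd) - 1L
  nk <- prod(fd[seq_len(D)])
  array(field[(k - 1L) * nk + seq_len(nk)], dim = fd[seq_len(D)])
}

#' @keywords internal
#' @noRd
setFieldComponent <- function(field, k, value) {
  fd <- dim(field)
  D <- length(fd) - 1L
  nk <- prod(fd[seq_len(D)])
  field[(k - 1L) * nk + seq_len(nk)] <- value
  field
}

#' @keywords internal
#' @noRd
zeroField <- function(d) array(0, dim = c(d, length(d)))

## Shift an array along one axis with replicate padding (used by finite
## differences and separable convolution).
#' @keywords internal
#' @noRd
shiftAxis <- function(a, k, off) {
  d <- dim(a)
  src <- pmin.int(pmax.int(seq_len(d[k]) + off, 1L), d[k])
  if (length(d) == 2L) {
    if (k == 1L) a[src, , drop = FALSE] else a[, src, drop = FALSE]
  } else if (length(d) == 3L) {
    if (k == 1L) a[src, , , drop = FALSE]
    else if (k == 2L) a[, src, , drop = FALSE]
    else a[, , src, drop = FALSE]
  } else {
    idx <- lapply(d, seq_len)
    idx[[k]] <- src
    do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
}

## Central-difference gradient of a scalar array; one-sided at the borders
## (replicate padding makes border derivatives one-sided up to a factor 2,
## which is harmless for the energies computed here). Units: 1/mm.
#' @keywords internal
#' @noRd
imageGradient <- function(img, spacing) {
  d <- dim(img)
  D <- length(d)
  g <- zeroField(d)
  for (k in seq_len(D)) {
    gk <- (shiftAxis(img, k, 1L) - shiftAxis(img, k, -1L)) / (2 * spacing[k])
    g <- setFieldComponent(g, k, gk)
  }
  g
}

## Central-difference divergence of a vector field (adjoint pair of
## imageGradient up to boundary rows). Units: field units / mm.
#' @keywords internal
#' @noRd
fieldDivergence <- function(field, spacing) {
  fd <- dim(field)
  D <- length(fd) - 1L
  out <- array(0, dim = fd[seq_len(D)])
  for (k in seq_len(D)) {
    comp <- fieldComponent(field, k)
    out <- out + (shiftAxis(comp, k, 1L) - shiftAxis(comp, k, -1L)) /
      (2 * spacing[k])
  }
  out
}

## Pointwise dot product of two vector fields -> scalar array.
#' @keywords internal
#' @noRd
fieldDot <- function(a, b) {
  fd <- dim(a)
  D <- length(fd) - 1L
  out <- array(0, dim = fd[seq_len(D)])
  for (k in seq_len(D)) out <- out + fieldComponent(a, k) * fieldComponent(b, k)
  out
}

## ---- separable Gaussian smoothing ------------------------------------------

## DFT of a circularly wrapped, normalized 1D Gaussian kernel (real by
## symmetry). Cached per (n, sigma) pair.
.kernelCache <- new.env(parent = emptyenv())

## The transfer function is the sampled continuous Gaussian transform
## exp(-2 pi^2 sigma^2 nu^2) (unit DC gain), which is strictly positive, so
## the kernel is symmetric positive definite — required for |v|^2_V =
## <m, K m> to be a norm.
#' @keywords internal
#' @noRd
gaussKernelFT <- function(n, sigmaVox) {
  key <- sprintf("%d_%.8g", n, sigmaVox)
  hit <- .kernelCache[[key]]
  if (!is.null(hit)) return(hit)
  j <- 0:(n - 1L)
  nu <- pmin(j, n - j) / n
  ft <- exp(-2 * pi^2 * sigmaVox^2 * nu^2)
  .kernelCache[[key]] <- ft
  ft
}

## Gaussian smoothing of a scalar array, width in mm, as a circular
## (periodic) convolution via the FFT: exact separable Gaussian weights,
## cost independent of the kernel width, and exactly self-adjoint (needed
## for the V-norm quadratic form v = K m, |v|^2_V = <m, v>).
#' @keywords internal
#' @noRd
smoothScalar <- function(img, widthMm, spacing) {
  d <- dim(img)
  sig <- widthMm / spacing
  if (all(sig <= 0)) return(img)
  ft <- gaussKernelFT(d[1L], sig[1L])
  for (k in seq_along(d)[-1L]) ft <- outer(ft, gaussKernelFT(d[k], sig[k]))
  array(Re(stats::fft(stats::fft(img) * ft, inverse = TRUE)) / prod(d), d)
}

## Componentwise Gaussian smoothing of a vector field (the kernel realizing
## the V-norm: velocity = kernel * momentum).
#' @keywords internal
#' @noRd
smoothField <- function(field, widthMm, spacing) {
  fd <- dim(field)
  D <- length(fd) - 1L
  for (k in seq_len(D)) {
    comp <- smoothScalar(fieldComponent(field, k), widthMm, spacing)
    field <- setFieldComponent(field, k, comp)
  }
  field
}

## ---- exact Euclidean distance transform ------------------------------------

## 1D squared-distance transform on sample positions x (Felzenszwalb &
## Huttenlocher lower-envelope-of-parabolas algorithm). f holds squared
## distances (large where no seed).
#' @keywords internal
#' @noRd
edt1d <- function(f, x) {
  n <- length(f)
  if (n == 1L) return(f)
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 1L
  v[1L] <- 1L
  z[1L] <- -Inf
  z[2L] <- Inf
  for (q in 2:n) {
    s <- ((f[q] + x[q]^2) - (f[v[k]] + x[v[k]]^2)) / (2 * x[q] - 2 * x[v[k]])
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + x[q]^2) - (f[v[k]] + x[v[k]]^2)) / (2 * x[q] - 2 * x[v[k]])
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  d <- numeric(n)
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < x[q]) k <- k + 1L
    d[q] <- (x[q] - x[v[k]])^2 + f[v[k]]
  }
  d
}

## Squared Euclidean distance (mm^2) of every voxel to the nearest TRUE voxel
## of `mask`, anisotropic-spacing aware. All-FALSE masks return a large
## sentinel everywhere.
#' @keywords internal
#' @noRd
squaredDistanceTo <- function(mask, spacing) {
  d <- dim(mask)
  D <- length(d)
  big <- 4 * sum((d * spacing)^2) + 1
  f <- array(ifelse(mask, 0, big), dim = d)
  for (k in seq_len(D)) {
    x <- seq_len(d[k]) * spacing[k]
    f <- aperm(apply(f, setdiff(seq_len(D), k), edt1d, x = x),
               order(c(k, setdiff(seq_len(D), k))))
  }
  f
}

## Signed distance (mm): negative inside the mask, positive outside, so its
## gradient is the outward normal direction.
#' @keywords internal
#' @noRd
signedDistance <- function(mask, spacing) {
  sqrt(squaredDistanceTo(mask, spacing)) - sqrt(squaredDistanceTo(!mask, spacing))
}

## ---- Jacobian determinant ---------------------------------------------------

## Determinant of the Jacobian of phi(x) = x + u(x) at every voxel, u in mm.
#' @keywords internal
#' @noRd
jacobianDet <- function(disp, spacing) {
  fd <- dim(disp)
  D <- length(fd) - 1L
  J <- vector("list", D)
  for (i in seq_len(D)) {
    J[[i]] <- vector("list", D)
    ui <- fieldComponent(disp, i)
    for (j in seq_len(D)) {
      dij <- (shiftAxis(ui, j, 1L) - shiftAxis(ui, j, -1L)) / (2 * spacing[j])
      if (i == j) dij <- dij + 1
      J[[i]][[j]] <- dij
    }
  }
  if (D == 2L) {
    J[[1]][[1]] * J[[2]][[2]] - J[[1]][[2]] * J[[2]][[1]]
  } else if (D == 3L) {
    J[[1]][[1]] * (J[[2]][[2]] * J[[3]][[3]] - J[[2]][[3]] * J[[3]][[2]]) -
      J[[1]][[2]] * (J[[2]][[1]] * J[[3]][[3]] - J[[2]][[3]] * J[[3]][[1]]) +
      J[[1]][[3]] * (J[[2]][[1]] * J[[3]][[2]] - J[[2]][[2]] * J[[3]][[1]])
  } else {
    stop("only 2D and 3D grids are supported")
  }
}

## min-max normalization helper used before optimization
#' @keywords internal
#' @noRd
minMaxNormalize <- function(img) {
  r <- range(img, finite = TRUE)
  if (r[2] - r[1] < .Machine$double.eps) {
    list(data = array(0, dim(img)), offset = r[1], scale = 1)
  } else {
    list(data = (img - r[1]) / (r[2] - r[1]), offset = r[1], scale = r[2] - r[1])
  }
}
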
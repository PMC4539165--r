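## Perfusion analysis: contralateral mirror normalization of MTT maps,
## pairing of rMTT values with lesion deformation, and Gaussian
## least-squares fits with peak +/- sd intervals.

#' Mirror-reflect a volume about a sagittal plane
#'
#' Left-right flip about the plane at `midline` on axis 1: output voxel i
#' takes the input value at index `2*midline - i`. The default midline is the
#' grid centre `(n + 1)/2` (a half-integer on even grids), for which the
#' reflection maps the grid exactly onto itself and applying it twice
#' returns the input bitwise. For an off-centre midline, voxels whose mirror
#' image falls outside the grid become `NA` (`FALSE` for logical input).
#'
#' @param volume a [ScalarVolume-class], numeric array, or logical mask.
#' @param midline reflection plane index on axis 1; `2*midline` must be an
#'   integer, and the plane must lie within the grid.
#' @return Reflected object of the same type as the input.
#' @examples
#' m <- array(FALSE, c(8, 4)); m[2, 1] <- TRUE
#' which(mirrorReflect(m), arr.ind = TRUE)  # lands at row 7
#' @export
mirrorReflect <- function(volume, midline = NULL) {
  isVol <- is(volume, "ScalarVolume")
  a <- if (isVol) volume@data else volume
  d <- dim(a)
  if (is.null(d)) stop("expected an array")
  n1 <- d[1L]
  if (is.null(midline)) midline <- (n1 + 1) / 2
  if (midline < 1 || midline > n1) stop("midline outside grid")
  if (abs(2 * midline - round(2 * midline)) > 1e-9)
    stop("2 * midline must be an integer so voxels map onto voxels")
  src <- round(2 * midline) - seq_len(n1)
  valid <- src >= 1L & src <= n1
  idx <- lapply(d, seq_len)
  out <- array(if (is.logical(a)) FALSE else NA_real_, d)
  idxOut <- idx; idxOut[[1L]] <- which(valid)
  idxIn <- idx; idxIn[[1L]] <- src[valid]
  out <- do.call(`[<-`, c(list(out), idxOut,
                          list(do.call(`[`, c(list(a), idxIn,
                                              list(drop = FALSE))))))
  if (isVol) scalarVolume(out, volume@spacing) else out
}

#' Relative MTT map by contralateral mirror normalization
#'
#' Reflects the lesion mask into the unaffected hemisphere, takes the mean
#' MTT over the mirrored region (finite, strictly positive voxels only) as
#' the contralateral normalizer, and divides every lesion voxel's MTT by it.
#' The resulting ratio is unitless.
#'
#' @param mtt a [ScalarVolume-class] or numeric array of MTT values.
#' @param lesionMask logical/binary array on the same grid.
#' @param midline reflection plane (default: grid centre on axis 1).
#' @param spacing voxel spacing (ignored for `ScalarVolume` input).
#' @return An [RMTTMap-class]; the number of mirrored voxels excluded as
#'   non-finite or non-positive is recorded in attribute `nExcluded`.
#' @export
computeRMTT <- function(mtt, lesionMask, midline = NULL, spacing = 1) {
  if (is(mtt, "ScalarVolume")) spacing <- mtt@spacing
  a <- asVolumeArray(mtt)
  mask <- asMaskArray(lesionMask, "lesionMask")
  if (!identical(dim(a), dim(mask)))
    stop("MTT map and lesion mask must share one grid")
  spacing <- rep_len(spacing, length(dim(a)))
  if (is.null(midline)) midline <- (dim(a)[1L] + 1) / 2
  mirrored <- mirrorReflect(mask, midline)
  if (!any(mirrored)) stop("mirrored lesion mask is empty")
  vals <- a[mirrored]
  ok <- is.finite(vals) & vals > 0
  if (!any(ok)) stop("no finite positive contralateral MTT values")
  cmean <- mean(vals[ok])
  if (cmean <= 0) stop("contralateral mean MTT is not positive")
  values <- array(NA_real_, dim(a))
  values[mask] <- a[mask] / cmean
  obj <- new("RMTTMap", values = values, regionMask = mask,
             contralateralMean = cmean, midline = midline, spacing = spacing)
  attr(obj, "nExcluded") <- sum(!ok)
  obj
}

#' Pair rMTT values with mean lesion deformation
#'
#' Selects the lesion voxels deforming in one direction (contracting or
#' expanding, per the deformation map's sign field), bins their rMTT values
#' at `binWidth`, and returns the mean deformation speed per bin. Speed is
#' the square root of the map's time-integrated squared speed (mm per unit
#' path time). Empty bins are dropped.
#'
#' @param rmtt an [RMTTMap-class].
#' @param defMap a [DeformationMap-class] on the same grid.
#' @param direction `"contraction"` or `"expansion"`.
#' @param binWidth rMTT bin width (default 0.01).
#' @return A [DeformationPerfusionSamples-class]; empty when no voxel
#'   deforms in the requested direction.
#' @export
deformationVsRMTT <- function(rmtt, defMap,
                              direction = c("contraction", "expansion"),
                              binWidth = 0.01) {
  stopifnot(is(rmtt, "RMTTMap"), is(defMap, "DeformationMap"))
  direction <- match.arg(direction)
  if (!identical(dim(rmtt@values), dim(defMap@magnitude)))
    stop("rMTT map and deformation map must share one grid")
  if (binWidth <= 0) stop("binWidth must be > 0")
  want <- if (direction == "contraction") -1 else 1
  sel <- defMap@lesionMask & rmtt@regionMask & defMap@sign == want
  if (!any(sel)) {
    return(new("DeformationPerfusionSamples", bins = numeric(0),
               meanDeformation = numeric(0), counts = integer(0),
               direction = direction, binWidth = binWidth))
  }
  r <- rmtt@values[sel]
  s <- sqrt(defMap@magnitude[sel])
  centre <- round(r / binWidth) * binWidth
  agg <- tapply(s, centre, mean)
  cnt <- tapply(s, centre, length)
  bins <- as.numeric(names(agg))
  o <- order(bins)
  new("DeformationPerfusionSamples", bins = bins[o],
      meanDeformation = as.numeric(agg)[o],
      counts = as.integer(cnt)[o], direction = direction,
      binWidth = binWidth)
}

#' Gaussian least-squares fit of mean deformation versus rMTT
#'
#' Fits `a * exp(-(x - mu)^2 / (2 s^2))` to the binned mean deformation by
#' nonlinear least squares (Levenberg–Marquardt). The peak `mu` is the rMTT
#' value associated with the largest mean deformation; the interval
#' `[p1, p2] = [mu - s, mu + s]` is the range of perfusion values associated
#' with the most rapidly deforming areas. RMSE is the root of the mean
#' squared residual over bins (0 for an exact fit).
#'
#' @param samples a [DeformationPerfusionSamples-class] with >= 3 bins.
#' @param weighted weight bins by voxel counts (default unweighted, one point
#'   per rMTT bin).
#' @return A [GaussianFit-class]. Non-convergence is reported with a warning
#'   and `isConverged(fit) = FALSE`.
#' @export
fitDeformationGaussian <- function(samples, weighted = FALSE) {
  stopifnot(is(samples, "DeformationPerfusionSamples"))
  x <- samples@bins
  y <- samples@meanDeformation
  if (length(x) < 3L)
    stop("Gaussian fit needs at least 3 rMTT bins, got ", length(x))
  a0 <- max(y)
  w0 <- pmax(y, 0)
  if (sum(w0) == 0) w0 <- rep(1, length(y))
  mu0 <- sum(x * w0) / sum(w0)
  s0 <- sqrt(sum(w0 * (x - mu0)^2) / sum(w0))
  s0 <- max(s0, samples@binWidth, diff(range(x)) / 50)
  wts <- if (weighted) as.numeric(samples@counts) else rep(1, length(x))

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-(x - mu)^2 / (2 * s^2)),
                      start = list(a = a0, mu = mu0, s = s0),
                      weights = wts,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    warning("Gaussian fit did not converge: ", conditionMessage(fit),
            "; returning the moment-based initial estimate flagged as ",
            "unconverged")
    pred <- a0 * exp(-(x - mu0)^2 / (2 * s0^2))
    return(new("GaussianFit", amplitude = a0, mean = mu0, sd = s0,
               rmse = sqrt(mean((y - pred)^2)), p1 = mu0 - s0, p2 = mu0 + s0,
               direction = samples@direction, converged = FALSE,
               nBins = length(x)))
  }
  cf <- stats::coef(fit)
  s <- abs(unname(cf["s"]))
  mu <- unname(cf["mu"])
  pred <- stats::predict(fit)
  new("GaussianFit", amplitude = unname(cf["a"]), mean = mu, sd = s,
      rmse = sqrt(mean((y - pred)^2)), p1 = mu - s, p2 = mu + s,
      direction = samples@direction, converged = TRUE, nBins = length(x))
}
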
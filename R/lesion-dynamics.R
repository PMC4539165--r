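## Lesion dynamics: signed total deformation maps over the DWI lesion and
## extraction of highly contracting / expanding regions.

#' Sign lesion deformation as expansion or contraction
#'
#' Assigns each lesion voxel a deformation direction from the time-averaged
#' projection of the path's velocity onto the outward normal of the lesion
#' boundary (the gradient of the signed Euclidean distance to the mask):
#' +1 where the tissue moves outward (expansion), -1 where it moves inward
#' (contraction), and 0 where the mean projection magnitude is below a
#' dead-band.
#'
#' @param path a [MetamorphosisPath-class].
#' @param lesionMask logical/binary array on the path's grid; must be
#'   non-empty.
#' @param deadBand projection magnitude (mm per unit path time) below which a
#'   voxel is left unsigned.
#' @return Array over the full grid with values in \{-1, 0, +1\}, zero
#'   outside the lesion mask.
#' @export
signDeformation <- function(path, lesionMask, deadBand = 1e-6) {
  stopifnot(is(path, "MetamorphosisPath"))
  mask <- asMaskArray(lesionMask, "lesionMask")
  d <- dim(path@intensities[[1L]])
  if (!identical(dim(mask), d)) stop("lesion mask grid mismatch")
  if (!any(mask)) stop("lesion mask is empty")
  spacing <- path@spacing
  D <- length(d)

  ## one-voxel smoothing of the signed distance gives subvoxel-accurate
  ## normals on rasterized masks (raw EDT normals are axis-quantized at the
  ## boundary)
  sdist <- smoothScalar(signedDistance(mask, spacing), min(spacing), spacing)
  n <- imageGradient(sdist, spacing)
  nn <- sqrt(fieldDot(n, n))
  nn[nn == 0] <- 1
  for (k in seq_len(D))
    n <- setFieldComponent(n, k, fieldComponent(n, k) / nn)

  vbar <- Reduce(`+`, path@velocities) / length(path@velocities)
  proj <- fieldDot(vbar, n)
  sgn <- array(0, d)
  sgn[proj > deadBand] <- 1
  sgn[proj < -deadBand] <- -1
  sgn[!mask] <- 0
  sgn
}

#' Total signed deformation map of a lesion over a metamorphosis path
#'
#' The magnitude at voxel x is the time-integrated squared speed along the
#' path, `sum_t ||v_t(x)||^2 * dt` (mm^2 per unit path time), restricted to
#' the lesion mask; the sign marks expansion (+1) versus contraction (-1) via
#' [signDeformation()].
#'
#' @param path a converged [MetamorphosisPath-class] (an unconverged path is
#'   accepted with a warning, recorded on the map).
#' @param lesionMask logical/binary array on the path's grid.
#' @param phase `"acute-subacute"` or `"subacute-final"`.
#' @param deadBand dead-band passed to [signDeformation()].
#' @return A [DeformationMap-class].
#' @export
totalDeformationMap <- function(path, lesionMask,
                                phase = c("acute-subacute", "subacute-final"),
                                deadBand = 1e-6) {
  stopifnot(is(path, "MetamorphosisPath"))
  phase <- match.arg(phase)
  mask <- asMaskArray(lesionMask, "lesionMask")
  d <- dim(path@intensities[[1L]])
  if (!identical(dim(mask), d)) stop("lesion mask grid mismatch")
  if (!path@converged)
    warning("deformation map computed from an unconverged metamorphosis path")
  dt <- 1 / path@params@nTimesteps
  mag <- array(0, d)
  for (v in path@velocities) mag <- mag + fieldDot(v, v) * dt
  mag[!mask] <- 0
  sgn <- signDeformation(path, mask, deadBand)
  new("DeformationMap", magnitude = mag, sign = sgn, lesionMask = mask,
      phase = phase, spacing = path@spacing, converged = path@converged)
}

#' @keywords internal
#' @noRd
sdOrZero <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

#' Extract highly contracting and expanding lesion regions
#'
#' Thresholds a signed deformation map with the mean +/- standard-deviation
#' speed rule, where speed is the square root of the map's time-integrated
#' squared speed. Highly contracting voxels are contracting voxels whose
#' speed strictly exceeds the mean speed of contraction within the lesion
#' minus its standard deviation. Under the default `"corrected"` rule, highly
#' expanding voxels are expanding voxels whose speed strictly exceeds the
#' mean speed of expansion plus its standard deviation; the `"as-printed"`
#' variant instead thresholds expansion against the contraction field's
#' mean plus standard deviation (the rule text as literally printed, which
#' references the contraction speed for both directions).
#'
#' @param defMap a [DeformationMap-class].
#' @param rule `"corrected"` (default) or `"as-printed"`.
#' @param boundaryOnly restrict the rule to a boundary shell of the lesion
#'   (the mask minus its erosion by `boundaryDepthMm`).
#' @param boundaryDepthMm shell depth in mm when `boundaryOnly = TRUE`.
#' @return A [DynamicRegions-class]; a direction with no voxels yields an
#'   empty mask and an `NA` threshold.
#' @export
thresholdDynamicRegions <- function(defMap,
                                    rule = c("corrected", "as-printed"),
                                    boundaryOnly = FALSE,
                                    boundaryDepthMm = 2) {
  stopifnot(is(defMap, "DeformationMap"))
  rule <- match.arg(rule)
  mask <- defMap@lesionMask
  if (!any(mask)) stop("deformation map has an empty lesion mask")
  domain <- mask
  if (boundaryOnly) {
    interior <- squaredDistanceTo(!mask, defMap@spacing) > boundaryDepthMm^2
    domain <- mask & !interior
  }
  speed <- sqrt(defMap@magnitude)
  con <- domain & defMap@sign == -1
  exp <- domain & defMap@sign == +1

  thrC <- thrE <- NA_real_
  conMask <- array(FALSE, dim(mask))
  expMask <- array(FALSE, dim(mask))
  if (any(con)) {
    sc <- speed[con]
    thrC <- mean(sc) - sdOrZero(sc)
    conMask <- con & speed > thrC
  }
  refE <- if (rule == "as-printed") speed[con] else speed[exp]
  if (any(exp) && length(refE)) {
    thrE <- mean(refE) + sdOrZero(refE)
    expMask <- exp & speed > thrE
  }
  props <- volumetricProportions(
    list(contracting = conMask, expanding = expMask), mask)
  new("DynamicRegions", contractingMask = conMask, expandingMask = expMask,
      thresholds = c(contraction = thrC, expansion = thrE),
      proportions = props, rule = rule)
}

#' Volumetric proportions of dynamic regions within the lesion
#'
#' @param regions a [DynamicRegions-class], or a named list with elements
#'   `contracting` and `expanding` (logical arrays).
#' @param lesionMask non-empty logical/binary array.
#' @return Named numeric `c(contracting = , expanding = )`, percent of lesion
#'   volume.
#' @examples
#' m <- array(FALSE, c(10, 20)); m[, 1:10] <- TRUE       # 100 lesion voxels
#' sub <- array(FALSE, c(10, 20)); sub[1:7, 1] <- TRUE   # 7 flagged
#' volumetricProportions(list(contracting = sub, expanding = m & FALSE), m)
#' @export
volumetricProportions <- function(regions, lesionMask) {
  mask <- asMaskArray(lesionMask, "lesionMask")
  if (!any(mask)) stop("lesion mask is empty")
  if (is(regions, "DynamicRegions"))
    regions <- list(contracting = regions@contractingMask,
                    expanding = regions@expandingMask)
  n <- sum(mask)
  c(contracting = 100 * sum(regions$contracting) / n,
    expanding = 100 * sum(regions$expanding) / n)
}
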
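## Accessors and show methods.

#' @rdname ScalarVolume-class
#' @param object,x a `ScalarVolume`.
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' @rdname ScalarVolume-class
#' @export
setMethod("volData", "ScalarVolume", function(x) x@data)

#' @rdname ScalarVolume-class
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname ScalarVolume-class
#' @export
setMethod("voxelSpacing", "ScalarVolume", function(x) x@spacing)

#' @rdname ScalarVolume-class
#' @export
setMethod("dim", "ScalarVolume", function(x) dim(x@data))

setMethod("show", "ScalarVolume", function(object) {
  cat(sprintf("ScalarVolume %s, spacing %s mm, range [%.4g, %.4g]\n",
              paste(dim(object@data), collapse = "x"),
              paste(object@spacing, collapse = "x"),
              min(object@data), max(object@data)))
})

#' Accessors for metamorphosis paths
#'
#' `intensities()`, `velocities()` and `flowMaps()` return the discrete
#' frames of a path; `energyTrace()` the per-iteration cost values;
#' `isConverged()` the convergence flag.
#'
#' @param x a [MetamorphosisPath-class].
#' @return Lists of arrays, a numeric vector, or a logical flag.
#' @name path-accessors
NULL

#' @rdname path-accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname path-accessors
#' @export
setMethod("intensities", "MetamorphosisPath", function(x) x@intensities)

#' @rdname path-accessors
#' @export
setGeneric("velocities", function(x) standardGeneric("velocities"))
#' @rdname path-accessors
#' @export
setMethod("velocities", "MetamorphosisPath", function(x) x@velocities)

#' @rdname path-accessors
#' @export
setGeneric("flowMaps", function(x) standardGeneric("flowMaps"))
#' @rdname path-accessors
#' @export
setMethod("flowMaps", "MetamorphosisPath", function(x) x@maps)

#' @rdname path-accessors
#' @export
setGeneric("energyTrace", function(x) standardGeneric("energyTrace"))
#' @rdname path-accessors
#' @export
setMethod("energyTrace", "MetamorphosisPath", function(x) x@energyTrace)

#' @rdname path-accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))
#' @rdname path-accessors
#' @export
setMethod("isConverged", "MetamorphosisPath", function(x) x@converged)
#' @rdname path-accessors
#' @export
setMethod("isConverged", "GaussianFit", function(x) x@converged)

setMethod("show", "MetamorphosisPath", function(object) {
  cat(sprintf(paste0(
    "MetamorphosisPath: %d timesteps, grid %s\n",
    "  energy %.6g -> %.6g over %d accepted iterates (%s)\n",
    "  max endpoint residual %.3g\n"),
    length(object@velocities),
    paste(dim(object@intensities[[1]]), collapse = "x"),
    object@energyTrace[1], utils::tail(object@energyTrace, 1),
    length(object@energyTrace),
    if (object@converged) "converged" else "NOT converged",
    max(object@endpointResiduals)))
})

#' Signed deformation values of a deformation map
#'
#' @param x a [DeformationMap-class].
#' @return An array `magnitude * sign` (mm^2 per unit path time, negative in
#'   contracting voxels).
#' @export
setGeneric("signedValue", function(x) standardGeneric("signedValue"))
#' @rdname signedValue
#' @export
setMethod("signedValue", "DeformationMap", function(x) x@magnitude * x@sign)

setMethod("show", "DeformationMap", function(object) {
  n <- sum(object@lesionMask)
  cat(sprintf(paste0(
    "DeformationMap (%s): %d lesion voxels, %d contracting, %d expanding\n",
    "  magnitude range in lesion [%.4g, %.4g] mm^2/unit time\n"),
    object@phase, n,
    sum(object@sign == -1), sum(object@sign == 1),
    if (n) min(object@magnitude[object@lesionMask]) else NA,
    if (n) max(object@magnitude[object@lesionMask]) else NA))
})

setMethod("show", "DynamicRegions", function(object) {
  cat(sprintf(paste0(
    "DynamicRegions (rule: %s)\n",
    "  highly contracting: %d voxels (%.2f%%), speed threshold %s\n",
    "  highly expanding:   %d voxels (%.2f%%), speed threshold %s\n"),
    object@rule,
    sum(object@contractingMask), object@proportions["contracting"],
    format(object@thresholds["contraction"], digits = 4),
    sum(object@expandingMask), object@proportions["expanding"],
    format(object@thresholds["expansion"], digits = 4)))
})

setMethod("show", "RMTTMap", function(object) {
  v <- object@values[object@regionMask]
  cat(sprintf(paste0(
    "RMTTMap: %d voxels, contralateral mean %.4g (midline index %.1f)\n",
    "  rMTT range [%.3g, %.3g]\n"),
    sum(object@regionMask), object@contralateralMean, object@midline,
    min(v), max(v)))
})

#' Interval limits of a Gaussian fit
#'
#' Returns the perfusion interval `(p1, p2) = (mu - s, mu + s)` around the
#' fitted peak — the vertical-bar limits of the per-case interval plots.
#'
#' @param fit a [GaussianFit-class].
#' @return Named numeric vector `c(p1, p2)`.
#' @examples
#' f <- new("GaussianFit", amplitude = 1, mean = 1, sd = 0.2, rmse = 0,
#'          p1 = 0.8, p2 = 1.2, direction = "contraction", converged = TRUE,
#'          nBins = 5L)
#' confidenceInterval(f)
#' @export
confidenceInterval <- function(fit) {
  stopifnot(is(fit, "GaussianFit"))
  c(p1 = fit@mean - fit@sd, p2 = fit@mean + fit@sd)
}

setMethod("show", "GaussianFit", function(object) {
  cat(sprintf(paste0(
    "GaussianFit (%s): a = %.4g, mu = %.4g, s = %.4g, RMSE = %.3g\n",
    "  interval [p1, p2] = [%.4g, %.4g], %d bins%s\n"),
    object@direction, object@amplitude, object@mean, object@sd, object@rmse,
    object@p1, object@p2, object@nBins,
    if (object@converged) "" else " (fit NOT converged)"))
})

setMethod("show", "SyntheticCase", function(object) {
  cfg <- object@config
  cat(sprintf(paste0(
    "SyntheticCase: grid %s, %d lesion component(s), seed %d\n",
    "  acute/subacute/final lesion voxels: %d / %d / %d\n",
    "  subacute MTT available: %s\n"),
    paste(cfg@gridShape, collapse = "x"), cfg@nComponents, cfg@seed,
    sum(object@masks$acute), sum(object@masks$subacute),
    sum(object@masks$final),
    cfg@includeSubacuteMtt))
})

setMethod("show", "PhaseResult", function(object) {
  if (object@skipped) {
    cat(sprintf("PhaseResult (%s): skipped — %s\n", object@phase,
                paste(object@notes, collapse = "; ")))
    return(invisible(NULL))
  }
  cat(sprintf("PhaseResult (%s)\n", object@phase))
  show(object@regions)
  for (dir in names(object@fits)) {
    f <- object@fits[[dir]]
    if (is.null(f)) cat(sprintf("  %s fit: not computable\n", dir))
    else cat(sprintf("  %s fit: peak rMTT %.3f, interval [%.3f, %.3f]\n",
                     dir, f@mean, f@p1, f@p2))
  }
})
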
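#' @import methods
NULL

## ---------------------------------------------------------------------------
## ScalarVolume
## ---------------------------------------------------------------------------

#' A scalar image volume on a regular grid
#'
#' Container for a 2D or 3D scalar field (DWI, T2-w, MTT, or a derived map)
#' with its voxel spacing in millimetres. Axis 1 is the left-right (sagittal)
#' axis used for contralateral mirror reflection.
#'
#' @slot data numeric array, 2D or 3D.
#' @slot spacing numeric, voxel size in mm per axis.
#' @export
setClass("ScalarVolume",
  representation(data = "array", spacing = "numeric"),
  validity = function(object) {
    d <- dim(object@data)
    if (is.null(d) || !(length(d) %in% c(2L, 3L)))
      return("data must be a 2D or 3D array")
    if (length(object@spacing) != length(d))
      return("spacing length must match the number of array dimensions")
    if (any(object@spacing <= 0)) return("spacing must be strictly positive")
    TRUE
  }
)

#' Construct a ScalarVolume
#'
#' @param data a 2D or 3D numeric array.
#' @param spacing voxel size in mm per axis; recycled scalar allowed.
#' @return A [ScalarVolume-class] object.
#' @examples
#' v <- scalarVolume(array(0, c(8, 8)), spacing = 1)
#' dim(volData(v))
#' @export
scalarVolume <- function(data, spacing = 1) {
  data <- as.array(data)
  storage.mode(data) <- "double"
  spacing <- rep_len(as.numeric(spacing), length(dim(data)))
  new("ScalarVolume", data = data, spacing = spacing)
}

## accept either a ScalarVolume or a bare array
#' @keywords internal
#' @noRd
asVolumeArray <- function(x) {
  if (is(x, "ScalarVolume")) x@data else as.array(x)
}

#' @keywords internal
#' @noRd
asMaskArray <- function(x, what = "mask") {
  a <- asVolumeArray(x)
  u <- unique(as.vector(a[!is.na(a)]))
  if (!all(u %in% c(0, 1, TRUE, FALSE)))
    stop(what, " must be binary (0/1 or logical); found other values")
  array(a > 0, dim(a))
}

## ---------------------------------------------------------------------------
## Metamorphosis
## ---------------------------------------------------------------------------

#' Parameters of the metamorphosis optimizer
#'
#' @slot sigma positive trade-off weight between deformation smoothness and
#'   fidelity to the advection relation (larger sigma buys less deformation).
#' @slot kernelWidth spatial scale (mm) of the Gaussian kernel realizing the
#'   V-norm on velocity fields.
#' @slot nTimesteps number of uniform time steps per path segment.
#' @slot maxIters optimizer iteration cap.
#' @slot stepSize initial gradient step size.
#' @slot tol relative energy-decrease stopping threshold.
#' @slot endpointTol maximum allowed max-abs residual to a target image.
#' @export
setClass("MetamorphosisParams",
  representation(sigma = "numeric", kernelWidth = "numeric",
                 nTimesteps = "integer", maxIters = "integer",
                 stepSize = "numeric", tol = "numeric",
                 endpointTol = "numeric"),
  validity = function(object) {
    if (object@sigma <= 0) return("sigma must be > 0")
    if (object@kernelWidth <= 0) return("kernelWidth must be > 0")
    if (object@nTimesteps < 1L) return("nTimesteps must be >= 1")
    if (object@tol <= 0) return("tol must be > 0")
    if (object@stepSize <= 0) return("stepSize must be > 0")
    TRUE
  }
)

#' Construct metamorphosis optimizer parameters
#'
#' @param sigma trade-off weight (unitless, > 0). Small values favour
#'   geometric deformation over photometric change.
#' @param kernelWidth Gaussian V-norm kernel width in mm.
#' @param nTimesteps discrete time steps per segment.
#' @param maxIters iteration cap of the alternating descent.
#' @param stepSize initial gradient step.
#' @param tol relative energy-decrease stopping threshold.
#' @param endpointTol maximum allowed residual to the target at segment ends.
#' @return A [MetamorphosisParams-class] object.
#' @export
metamorphosisParams <- function(sigma = 0.1, kernelWidth = 4, nTimesteps = 10L,
                                maxIters = 500L, stepSize = 0.5, tol = 1e-6,
                                endpointTol = 1e-2) {
  new("MetamorphosisParams", sigma = sigma, kernelWidth = kernelWidth,
      nTimesteps = as.integer(nTimesteps), maxIters = as.integer(maxIters),
      stepSize = stepSize, tol = tol, endpointTol = endpointTol)
}

#' A discrete metamorphosis path
#'
#' The optimal joint geometric + photometric path between images: intensity
#' frames I_0..I_T, piecewise-constant-in-time velocity fields v_t (mm per
#' unit path time), and the accumulated diffeomorphisms phi_t stored as
#' displacement fields (mm).
#'
#' @slot intensities list of T+1 scalar arrays.
#' @slot velocities list of T vector-field arrays.
#' @slot maps list of T+1 displacement-field arrays (phi_0 = identity).
#' @slot energyTrace numeric, energy of every accepted iterate (non-increasing).
#' @slot converged logical.
#' @slot spacing voxel spacing (mm).
#' @slot params the [MetamorphosisParams-class] used.
#' @slot obsIndex integer time indices (1-based into `intensities`) at which
#'   observation images were fixed.
#' @slot endpointResiduals max-abs residual to each fixed observation.
#' @slot momenta list of T momentum fields (velocity = kernel * momentum);
#'   may be empty for hand-built zero-velocity paths.
#' @slot normalization list(offset, scale) of the min-max intensity rescaling.
#' @export
setClass("MetamorphosisPath",
  representation(intensities = "list", velocities = "list", maps = "list",
                 energyTrace = "numeric", converged = "logical",
                 spacing = "numeric", params = "MetamorphosisParams",
                 obsIndex = "integer", endpointResiduals = "numeric",
                 momenta = "list", normalization = "list"),
  validity = function(object) {
    if (length(object@intensities) != length(object@velocities) + 1L)
      return("need length(intensities) == length(velocities) + 1")
    if (length(object@maps) != length(object@intensities))
      return("need one accumulated map per intensity frame")
    if (is.unsorted(rev(object@energyTrace), strictly = FALSE) &&
        any(diff(object@energyTrace) > 1e-9 * abs(object@energyTrace[1])))
      return("energyTrace must be non-increasing")
    TRUE
  }
)

## ---------------------------------------------------------------------------
## Lesion dynamics
## ---------------------------------------------------------------------------

#' A signed lesion deformation map
#'
#' Per-voxel time-integrated squared speed along a metamorphosis path
#' (mm^2 per unit path time) over a lesion mask, signed +1 where the lesion
#' boundary moves outward (expansion) and -1 where it moves inward
#' (contraction).
#'
#' @slot magnitude non-negative scalar array, zero outside the lesion mask.
#' @slot sign array with values in \{-1, 0, 1\}, zero outside the mask.
#' @slot lesionMask logical array.
#' @slot phase `"acute-subacute"` or `"subacute-final"`.
#' @slot spacing voxel spacing (mm).
#' @slot converged whether the generating path converged.
#' @export
setClass("DeformationMap",
  representation(magnitude = "array", sign = "array", lesionMask = "array",
                 phase = "character", spacing = "numeric",
                 converged = "logical"),
  validity = function(object) {
    if (!object@phase %in% c("acute-subacute", "subacute-final"))
      return("phase must be 'acute-subacute' or 'subacute-final'")
    if (any(object@magnitude < 0)) return("magnitude must be >= 0")
    if (any(object@magnitude[!object@lesionMask] != 0))
      return("magnitude must be zero outside lesionMask")
    if (!all(object@sign %in% c(-1, 0, 1)))
      return("sign must take values in {-1, 0, 1}")
    TRUE
  }
)

#' Highly contracting and expanding lesion regions
#'
#' @slot contractingMask,expandingMask disjoint logical arrays, subsets of the
#'   lesion mask.
#' @slot thresholds named numeric (contraction, expansion) speed thresholds;
#'   `NA` where undefined (no voxels of that direction).
#' @slot proportions named numeric, percent of lesion volume per mask.
#' @slot rule `"corrected"` or `"as-printed"` threshold variant.
#' @export
setClass("DynamicRegions",
  representation(contractingMask = "array", expandingMask = "array",
                 thresholds = "numeric", proportions = "numeric",
                 rule = "character"),
  validity = function(object) {
    if (any(object@contractingMask & object@expandingMask))
      return("contracting and expanding masks must be disjoint")
    p <- object@proportions
    if (any(p < 0 | p > 100)) return("proportions must lie in [0, 100]")
    TRUE
  }
)

## ---------------------------------------------------------------------------
## Perfusion
## ---------------------------------------------------------------------------

#' A relative MTT (rMTT) map
#'
#' Each lesion voxel's MTT divided by the mean MTT over the mirror-reflected
#' (contralateral) lesion region; unitless.
#'
#' @slot values numeric array, `NA` outside `regionMask`.
#' @slot regionMask logical array where the ratio is defined.
#' @slot contralateralMean scalar normalizer (MTT units).
#' @slot midline sagittal reflection plane index (may be half-integer).
#' @slot spacing voxel spacing (mm).
#' @export
setClass("RMTTMap",
  representation(values = "array", regionMask = "array",
                 contralateralMean = "numeric", midline = "numeric",
                 spacing = "numeric"),
  validity = function(object) {
    if (object@contralateralMean <= 0)
      return("contralateralMean must be > 0")
    v <- object@values[object@regionMask]
    if (any(!is.na(v) & v <= 0))
      return("rMTT values must be > 0 where defined")
    TRUE
  }
)

#' Binned deformation-vs-rMTT samples
#'
#' Mean deformation magnitude per rMTT bin, for one deformation direction.
#'
#' @slot bins strictly increasing rMTT bin centres.
#' @slot meanDeformation mean deformation magnitude per bin.
#' @slot counts voxels per bin (>= 1).
#' @slot direction `"contraction"` or `"expansion"`.
#' @slot binWidth bin width in rMTT units.
#' @export
setClass("DeformationPerfusionSamples",
  representation(bins = "numeric", meanDeformation = "numeric",
                 counts = "integer", direction = "character",
                 binWidth = "numeric"),
  validity = function(object) {
    if (length(object@bins) != length(object@meanDeformation) ||
        length(object@bins) != length(object@counts))
      return("bins, meanDeformation and counts must have equal length")
    if (length(object@bins) > 1L && any(diff(object@bins) <= 0))
      return("bins must be strictly increasing")
    if (length(object@counts) && any(object@counts < 1L))
      return("every retained bin must hold at least one voxel")
    if (!object@direction %in% c("contraction", "expansion"))
      return("direction must be 'contraction' or 'expansion'")
    TRUE
  }
)

#' A Gaussian least-squares fit of deformation versus rMTT
#'
#' @slot amplitude fitted peak height.
#' @slot mean fitted peak location mu (rMTT units).
#' @slot sd fitted spread s (>= 0).
#' @slot rmse root-mean-square deviation of the fit over bins.
#' @slot p1,p2 interval limits mu - s and mu + s.
#' @slot direction `"contraction"` or `"expansion"`.
#' @slot converged logical fit-convergence flag.
#' @slot nBins number of bins the fit used.
#' @export
setClass("GaussianFit",
  representation(amplitude = "numeric", mean = "numeric", sd = "numeric",
                 rmse = "numeric", p1 = "numeric", p2 = "numeric",
                 direction = "character", converged = "logical",
                 nBins = "integer"),
  validity = function(object) {
    if (object@sd < 0) return("sd must be >= 0")
    if (object@rmse < 0) return("rmse must be >= 0")
    if (!(object@p1 <= object@mean && object@mean <= object@p2))
      return("need p1 <= mean <= p2")
    TRUE
  }
)

## ---------------------------------------------------------------------------
## Synthetic data
## ---------------------------------------------------------------------------

#' Configuration of a synthetic longitudinal stroke case
#'
#' @slot gridShape voxel counts per axis (2D or 3D).
#' @slot voxelSize spacing in mm per axis.
#' @slot nComponents number of lesion components (>= 1).
#' @slot centers nComponents x D matrix of component centres (voxel indices).
#' @slot radii acute radius (voxels) per component.
#' @slot growth nComponents x 2 matrix of signed radial change (voxels) per
#'   phase (acute->subacute, subacute->final).
#' @slot rmttSpec list with elements `contraction = c(mu, sd)` and
#'   `expansion = c(mu, sd)`: generating Gaussians of rMTT in the zones around
#'   contracting and expanding lesion boundaries.
#' @slot noiseSd additive image-noise standard deviation (intensity units).
#' @slot lesionContrast lesion intensity elevation above brain tissue.
#' @slot includeSubacuteMtt whether a subacute MTT map is generated (emulates
#'   cases lacking subacute perfusion imaging).
#' @slot seed RNG seed; a fixed seed makes the case byte-identical.
#' @export
setClass("CaseConfig",
  representation(gridShape = "integer", voxelSize = "numeric",
                 nComponents = "integer", centers = "matrix",
                 radii = "numeric", growth = "matrix", rmttSpec = "list",
                 noiseSd = "numeric", lesionContrast = "numeric",
                 includeSubacuteMtt = "logical", seed = "integer"),
  validity = function(object) {
    if (any(object@gridShape <= 0L)) return("gridShape must be positive")
    if (object@nComponents < 1L) return("need nComponents >= 1")
    if (nrow(object@centers) != object@nComponents ||
        ncol(object@centers) != length(object@gridShape))
      return("centers must be nComponents x D")
    if (length(object@radii) != object@nComponents)
      return("radii must have one entry per component")
    if (nrow(object@growth) != object@nComponents || ncol(object@growth) != 2L)
      return("growth must be nComponents x 2 (one column per phase)")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    for (dir in c("contraction", "expansion")) {
      sp <- object@rmttSpec[[dir]]
      if (is.null(sp) || length(sp) != 2L || sp[1] <= 0 || sp[2] < 0)
        return(sprintf("rmttSpec$%s must be c(mu > 0, sd >= 0)", dir))
    }
    ## every component, maximally grown, must stay inside the grid
    maxr <- object@radii + pmax(0, object@growth[, 1L]) +
      pmax(0, object@growth[, 1L] + object@growth[, 2L] - pmax(0, object@growth[, 1L]))
    for (i in seq_len(object@nComponents)) {
      lo <- object@centers[i, ] - maxr[i]
      hi <- object@centers[i, ] + maxr[i]
      if (any(lo < 1) || any(hi > object@gridShape))
        return(sprintf("component %d exceeds grid bounds once grown", i))
    }
    TRUE
  }
)

#' A generated synthetic longitudinal case
#'
#' @slot images named list (acute, subacute, final) of [ScalarVolume-class].
#' @slot masks named list of logical lesion masks per timepoint.
#' @slot mtt named list of MTT maps per phase start (`acute`, and `subacute`
#'   when configured).
#' @slot truthExpansion,truthContraction named lists (per phase) of logical
#'   ground-truth masks of voxels entering / leaving the lesion.
#' @slot truthDisplacement named list (per phase) of ground-truth displacement
#'   fields (mm).
#' @slot rmttZones named list (per phase) of lists of logical masks: the
#'   designated zones in which rMTT values were drawn from the configured
#'   contraction / expansion Gaussians.
#' @slot config the generating [CaseConfig-class].
#' @export
setClass("SyntheticCase",
  representation(images = "list", masks = "list", mtt = "list",
                 truthExpansion = "list", truthContraction = "list",
                 truthDisplacement = "list", rmttZones = "list",
                 config = "CaseConfig"),
  validity = function(object) {
    d <- dim(object@images$acute@data)
    for (m in object@masks) if (!identical(dim(m), d))
      return("all masks must share the image grid")
    for (ph in names(object@truthExpansion)) {
      if (any(object@truthExpansion[[ph]] & object@truthContraction[[ph]]))
        return("truth expansion and contraction masks must be disjoint")
    }
    TRUE
  }
)

## ---------------------------------------------------------------------------
## Pipeline
## ---------------------------------------------------------------------------

#' Result of one analysis phase of one case
#'
#' @slot phase `"acute-subacute"` or `"subacute-final"`.
#' @slot skipped TRUE when the phase could not run (e.g. missing subacute
#'   MTT); then only `notes` is meaningful.
#' @slot defMap the [DeformationMap-class] (or NULL-like empty when skipped).
#' @slot regions the [DynamicRegions-class].
#' @slot fits named list (contraction, expansion) of [GaussianFit-class] or
#'   `NULL` where not computable.
#' @slot rmttSummary data.frame of min/max/mean/sd of rMTT inside each
#'   direction's highly dynamic area.
#' @slot notes character annotations (skip reasons, convergence warnings).
#' @export
setClass("PhaseResult",
  representation(phase = "character", skipped = "logical", defMap = "ANY",
                 regions = "ANY", fits = "list", rmttSummary = "data.frame",
                 notes = "character"),
  validity = function(object) {
    if (!object@phase %in% c("acute-subacute", "subacute-final"))
      return("phase must be 'acute-subacute' or 'subacute-final'")
    TRUE
  }
)
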
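## Synthetic longitudinal stroke cases with known ground truth.
##
## The generator emulates the structure the analysis needs: a two-hemisphere
## background phantom symmetric about the central sagittal plane (so mirror
## reflection is exact by construction), one or more smoothed spherical
## lesion components with elevated intensity, per-component signed radial
## growth across the two phases, an MTT map whose hypoperfused region
## overlaps the lesion, and — in zones around each moving lesion boundary —
## rMTT values coupled to the expected local deformation so that the
## deformation-vs-rMTT relation is a Gaussian centred on the configured mean.

#' Configure a synthetic longitudinal stroke case
#'
#' @param gridShape voxel counts per axis (2D or 3D).
#' @param voxelSize spacing in mm per axis (recycled scalar allowed).
#' @param centers nComponents x D matrix of component centres (voxel
#'   indices); all centres must lie in one (affected) hemisphere.
#' @param radii acute lesion radius (voxels) per component.
#' @param growth nComponents x 2 matrix of signed radial change (voxels) for
#'   the acute->subacute and subacute->final phases.
#' @param rmttSpec list with `contraction = c(mu, sd)` and
#'   `expansion = c(mu, sd)`: generating Gaussian parameters of rMTT around
#'   contracting and expanding lesion boundaries.
#' @param noiseSd additive Gaussian image-noise sd (intensities are clipped
#'   back to \[0, 1\]).
#' @param lesionContrast lesion intensity elevation above brain tissue.
#' @param includeSubacuteMtt generate a subacute MTT map (set `FALSE` to
#'   emulate cases lacking subacute perfusion imaging).
#' @param seed RNG seed; a fixed seed makes [generateCase()] byte-identical.
#' @return A [CaseConfig-class].
#' @export
caseConfig <- function(gridShape = c(64L, 64L), voxelSize = 1,
                       centers = rbind(c(46, 18), c(46, 46)),
                       radii = c(8, 7),
                       growth = rbind(c(2, 1), c(-2, -1)),
                       rmttSpec = list(contraction = c(mu = 1.5, sd = 0.1),
                                       expansion = c(mu = 0.8, sd = 0.1)),
                       noiseSd = 0.01, lesionContrast = 0.45,
                       includeSubacuteMtt = TRUE, seed = 1L) {
  centers <- rbind(centers)
  growth <- rbind(growth)
  new("CaseConfig", gridShape = as.integer(gridShape),
      voxelSize = rep_len(as.numeric(voxelSize), length(gridShape)),
      nComponents = nrow(centers), centers = centers,
      radii = as.numeric(radii), growth = growth, rmttSpec = rmttSpec,
      noiseSd = noiseSd, lesionContrast = lesionContrast,
      includeSubacuteMtt = includeSubacuteMtt, seed = as.integer(seed))
}

## radial distance (voxel units) of every grid point to a component centre
#' @keywords internal
#' @noRd
radialDistance <- function(d, centre) {
  pts <- gridCoords(d)
  rho <- 0
  for (k in seq_along(d)) rho <- rho + (pts[, k] - centre[k])^2
  array(sqrt(rho), d)
}

## reference MTT of healthy tissue (seconds); the analysis normalizes it
## away, so only the symmetric structure matters
.baselineMTT <- 6

#' Generate a synthetic longitudinal case
#'
#' Builds acute/subacute/final lesion images and masks, per-phase MTT maps,
#' and ground truth: expansion/contraction masks (voxels entering or leaving
#' the lesion between timepoints) and an approximate radial displacement
#' field per phase. In a zone around each moving component boundary the
#' assigned rMTT deviates from the configured mean in proportion to the
#' voxel's distance from that boundary (with a random, balanced sign), so
#' voxels expected to deform most carry rMTT near the configured `mu` and
#' the binned deformation-vs-rMTT relation is Gaussian by construction.
#'
#' @param config a [CaseConfig-class].
#' @return A [SyntheticCase-class].
#' @examples
#' case <- generateCase(caseConfig(seed = 7L))
#' sum(case@truthExpansion[["acute-subacute"]])
#' @export
generateCase <- function(config) {
  stopifnot(is(config, "CaseConfig"))
  validObject(config)
  if (exists(".Random.seed", envir = .GlobalEnv)) {
    oldSeed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", oldSeed, envir = .GlobalEnv), add = TRUE)
  }
  set.seed(config@seed)

  d <- config@gridShape
  sp <- config@voxelSize
  D <- length(d)
  nC <- config@nComponents
  midline <- (d[1L] + 1) / 2
  affectedRight <- all(config@centers[, 1L] > midline)
  if (!affectedRight && !all(config@centers[, 1L] < midline))
    stop("all lesion components must lie in one hemisphere")

  pts <- gridCoords(d)
  sideMask <- array(if (affectedRight) pts[, 1L] > midline
                    else pts[, 1L] < midline, d)

  ## two-hemisphere brain phantom: ellipse/ellipsoid symmetric about midline
  centreVox <- (d + 1) / 2
  semi <- 0.45 * d
  q <- 0
  for (k in seq_len(D)) q <- q + ((pts[, k] - centreVox[k]) / semi[k])^2
  brain <- array(q <= 1, d)

  rho <- lapply(seq_len(nC), function(i) radialDistance(d, config@centers[i, ]))

  radiiAt <- function(tp) {  # tp: 0 acute, 1 subacute, 2 final
    r <- config@radii
    if (tp >= 1) r <- pmax(r + config@growth[, 1L], 0)
    if (tp >= 2) r <- pmax(r + config@growth[, 2L], 0)
    r
  }
  maskAt <- function(tp) {
    r <- radiiAt(tp)
    m <- array(FALSE, d)
    for (i in seq_len(nC)) m <- m | (rho[[i]] <= r[i])
    m
  }
  masks <- list(acute = maskAt(0), subacute = maskAt(1), final = maskAt(2))

  renderImage <- function(mask) {
    img <- array(0.02, d)
    img[brain] <- 0.28
    img <- img + config@lesionContrast *
      smoothScalar(array(as.numeric(mask), d), min(sp), sp)
    if (config@noiseSd > 0)
      img <- img + array(stats::rnorm(prod(d), 0, config@noiseSd), d)
    array(pmin(pmax(img, 0), 1), d)
  }
  images <- lapply(masks, function(m) scalarVolume(renderImage(m), sp))

  ## MTT with per-phase rMTT assignment around each moving boundary
  zoneHalf <- 3   # designated-zone half width, voxels
  proxyW <- 2     # deformation-proxy width, voxels
  makeMTT <- function(phaseCol, rStart) {
    mtt <- array(.baselineMTT, d)
    zones <- list(contraction = array(FALSE, d), expansion = array(FALSE, d))
    for (i in seq_len(nC)) {
      g <- config@growth[i, phaseCol]
      if (g == 0) next
      dir <- if (g > 0) "expansion" else "contraction"
      spec <- config@rmttSpec[[dir]]
      rEnd <- max(rStart[i] + g, 0)
      region <- (rho[[i]] <= max(rStart[i], rEnd) + zoneHalf) & sideMask
      zones[[dir]] <- zones[[dir]] |
        (abs(rho[[i]] - rStart[i]) <= zoneHalf & sideMask)
      z <- pmin(abs(rho[[i]][region] - rStart[i]) / proxyW, 2.5)
      sgn <- sample(c(-1, 1), sum(region), replace = TRUE)
      mtt[region] <- pmax(spec[1] + spec[2] * z * sgn, 0.05) * .baselineMTT
    }
    list(mtt = scalarVolume(mtt, sp), zones = zones)
  }
  acuteMTT <- makeMTT(1L, radiiAt(0))
  mtt <- list(acute = acuteMTT$mtt)
  zones <- list("acute-subacute" = acuteMTT$zones)
  if (config@includeSubacuteMtt) {
    subMTT <- makeMTT(2L, radiiAt(1))
    mtt$subacute <- subMTT$mtt
    zones[["subacute-final"]] <- subMTT$zones
  }

  ## ground truth per phase
  phases <- list("acute-subacute" = c("acute", "subacute"),
                 "subacute-final" = c("subacute", "final"))
  truthExp <- truthCon <- truthDisp <- list()
  for (ph in names(phases)) {
    m1 <- masks[[phases[[ph]][1L]]]
    m2 <- masks[[phases[[ph]][2L]]]
    truthExp[[ph]] <- m2 & !m1
    truthCon[[ph]] <- m1 & !m2
    phaseCol <- if (ph == "acute-subacute") 1L else 2L
    rStart <- radiiAt(phaseCol - 1L)
    disp <- zeroField(d)
    for (i in seq_len(nC)) {
      g <- config@growth[i, phaseCol]
      if (g == 0) next
      bump <- exp(-(rho[[i]] - rStart[i])^2 / (2 * proxyW^2))
      rr <- pmax(rho[[i]], 1e-6)
      for (k in seq_len(D)) {
        unit <- (array(pts[, k], d) - config@centers[i, k]) / rr
        disp <- setFieldComponent(
          disp, k, fieldComponent(disp, k) + g * sp[k] * unit * bump)
      }
    }
    truthDisp[[ph]] <- disp
  }

  new("SyntheticCase", images = images, masks = masks, mtt = mtt,
      truthExpansion = truthExp, truthContraction = truthCon,
      truthDisplacement = truthDisp, rmttZones = zones, config = config)
}

#' Resample a volume under a known displacement field
#'
#' Warps a volume by a displacement field `u` (mm) with the package's single
#' interpolation convention: the output at voxel x takes the input value at
#' `x - u(x)` (clamped multilinear interpolation), i.e. content is pushed
#' forward by `+u`. Used as the ground-truth generator for registration
#' recovery tests.
#'
#' @param volume a [ScalarVolume-class] or numeric array.
#' @param displacement vector-field array, dim `c(dim(volume), D)`, mm.
#' @param spacing voxel spacing (ignored for `ScalarVolume` input).
#' @return Warped volume, same container type as the input.
#' @export
applyKnownDisplacement <- function(volume, displacement, spacing = 1) {
  isVol <- is(volume, "ScalarVolume")
  img <- asVolumeArray(volume)
  if (isVol) spacing <- volume@spacing
  d <- dim(img)
  spacing <- rep_len(spacing, length(d))
  if (!identical(dim(displacement), c(d, length(d))))
    stop("displacement field shape does not match the volume grid")
  pts <- gridCoords(d)
  for (k in seq_along(d))
    pts[, k] <- pts[, k] - as.vector(fieldComponent(displacement, k)) / spacing[k]
  out <- array(interpScalar(img, pts), d)
  if (isVol) scalarVolume(out, spacing) else out
}
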
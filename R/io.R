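## NIfTI case I/O. One directory per case with fixed filenames plus a YAML
## sidecar recording spacing and, for synthetic cases, the generating
## configuration.

.caseFiles <- c(acute_dwi = "acute_dwi.nii.gz",
                acute_dwi_mask = "acute_dwi_mask.nii.gz",
                acute_mtt = "acute_mtt.nii.gz",
                subacute_dwi = "subacute_dwi.nii.gz",
                subacute_dwi_mask = "subacute_dwi_mask.nii.gz",
                subacute_mtt = "subacute_mtt.nii.gz",
                final_t2 = "final_t2.nii.gz",
                final_t2_mask = "final_t2_mask.nii.gz")

#' @keywords internal
#' @noRd
writeNiftiVol <- function(x, file, spacing) {
  a <- if (is(x, "ScalarVolume")) x@data else x
  if (is.logical(a)) a <- array(as.numeric(a), dim(a))
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, file)
}

#' Write a case directory
#'
#' Writes the volumes of a case (images, lesion masks, per-phase MTT maps;
#' for a [SyntheticCase-class] also the ground-truth expansion/contraction
#' masks) as NIfTI files with fixed names, plus a `case.yaml` sidecar.
#'
#' @param case a [SyntheticCase-class] or a list as accepted by [runCase()].
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
writeCaseDir <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cd <- asCaseData(case)
  sp <- cd$spacing
  writeNiftiVol(cd$images$acute, file.path(dir, .caseFiles["acute_dwi"]), sp)
  writeNiftiVol(cd$images$subacute,
                file.path(dir, .caseFiles["subacute_dwi"]), sp)
  if (!is.null(cd$images$final))
    writeNiftiVol(cd$images$final, file.path(dir, .caseFiles["final_t2"]), sp)
  writeNiftiVol(cd$masks$acute,
                file.path(dir, .caseFiles["acute_dwi_mask"]), sp)
  writeNiftiVol(cd$masks$subacute,
                file.path(dir, .caseFiles["subacute_dwi_mask"]), sp)
  writeNiftiVol(cd$masks$final,
                file.path(dir, .caseFiles["final_t2_mask"]), sp)
  writeNiftiVol(cd$mtt$acute, file.path(dir, .caseFiles["acute_mtt"]), sp)
  if (!is.null(cd$mtt$subacute))
    writeNiftiVol(cd$mtt$subacute,
                  file.path(dir, .caseFiles["subacute_mtt"]), sp)
  side <- list(spacing = as.numeric(sp))
  if (is(case, "SyntheticCase")) {
    cfg <- case@config
    side$config <- list(gridShape = as.integer(cfg@gridShape),
                        voxelSize = as.numeric(cfg@voxelSize),
                        nComponents = cfg@nComponents,
                        centers = apply(cfg@centers, 1L, as.numeric,
                                        simplify = FALSE),
                        radii = as.numeric(cfg@radii),
                        growth = apply(cfg@growth, 1L, as.numeric,
                                       simplify = FALSE),
                        rmttSpec = lapply(cfg@rmttSpec, as.numeric),
                        noiseSd = cfg@noiseSd,
                        lesionContrast = cfg@lesionContrast,
                        includeSubacuteMtt = cfg@includeSubacuteMtt,
                        seed = cfg@seed)
    for (ph in names(case@truthExpansion)) {
      tag <- gsub("[^a-z]", "_", ph)
      writeNiftiVol(case@truthExpansion[[ph]],
                    file.path(dir, sprintf("truth_expansion_%s.nii.gz", tag)),
                    sp)
      writeNiftiVol(case@truthContraction[[ph]],
                    file.path(dir, sprintf("truth_contraction_%s.nii.gz", tag)),
                    sp)
    }
  }
  yaml::write_yaml(side, file.path(dir, "case.yaml"))
  invisible(dir)
}

#' Read a case directory
#'
#' Reads the fixed-name NIfTI volumes written by [writeCaseDir()] (or
#' assembled by hand in the same layout). Missing optional volumes
#' (subacute MTT, final image) are returned as `NULL`.
#'
#' @param dir case directory.
#' @return A list with elements `images`, `masks`, `mtt`, `spacing` suitable
#'   for [runCase()].
#' @export
readCaseDir <- function(dir) {
  rd <- function(name, mask = FALSE) {
    f <- file.path(dir, .caseFiles[name])
    if (!file.exists(f)) return(NULL)
    img <- RNifti::readNifti(f)
    a <- array(as.numeric(img), dim(img))
    if (mask) array(a > 0.5, dim(a)) else a
  }
  sideFile <- file.path(dir, "case.yaml")
  acute <- rd("acute_dwi")
  if (is.null(acute)) stop("no acute DWI image found in ", dir)
  spacing <- if (file.exists(sideFile))
    as.numeric(yaml::read_yaml(sideFile)$spacing)
  else RNifti::pixdim(RNifti::readNifti(file.path(dir,
                                                  .caseFiles["acute_dwi"])))
  spacing <- rep_len(spacing, length(dim(acute)))
  mk <- function(a) if (is.null(a)) NULL else scalarVolume(a, spacing)
  list(images = list(acute = mk(acute), subacute = mk(rd("subacute_dwi")),
                     final = mk(rd("final_t2"))),
       masks = list(acute = rd("acute_dwi_mask", mask = TRUE),
                    subacute = rd("subacute_dwi_mask", mask = TRUE),
                    final = rd("final_t2_mask", mask = TRUE)),
       mtt = list(acute = mk(rd("acute_mtt")),
                  subacute = mk(rd("subacute_mtt"))),
       spacing = spacing)
}
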
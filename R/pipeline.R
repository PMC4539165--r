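## Per-case two-phase orchestration and cohort aggregation.

#' Analysis configuration for the two-phase pipeline
#'
#' Bundles every tunable of the per-case analysis.
#'
#' @param params a [MetamorphosisParams-class].
#' @param rule threshold-rule variant, `"corrected"` or `"as-printed"` (see
#'   [thresholdDynamicRegions()]).
#' @param binWidth rMTT bin width for [deformationVsRMTT()].
#' @param deadBand sign dead-band for [signDeformation()].
#' @param midline sagittal reflection plane; `NULL` for the grid centre.
#' @param weightedFit count-weight the Gaussian fit (see
#'   [fitDeformationGaussian()]).
#' @return A named list of class `"strokemorphConfig"`.
#' @export
analysisConfig <- function(params = metamorphosisParams(),
                           rule = c("corrected", "as-printed"),
                           binWidth = 0.01, deadBand = 1e-6,
                           midline = NULL, weightedFit = FALSE) {
  structure(list(params = params, rule = match.arg(rule),
                 binWidth = binWidth, deadBand = deadBand,
                 midline = midline, weightedFit = weightedFit),
            class = "strokemorphConfig")
}

## normalize case input (SyntheticCase or plain list) to a named list
#' @keywords internal
#' @noRd
asCaseData <- function(case) {
  if (is(case, "SyntheticCase")) {
    list(images = case@images, masks = case@masks, mtt = case@mtt,
         spacing = case@images$acute@spacing)
  } else {
    stopifnot(is.list(case), !is.null(case$images), !is.null(case$masks))
    sp <- case$spacing
    if (is.null(sp) && is(case$images$acute, "ScalarVolume"))
      sp <- case$images$acute@spacing
    if (is.null(sp)) sp <- 1
    case$spacing <- sp
    case
  }
}

## target image for the subacute-final phase when only the final lesion mask
## is on disk: a pseudo T2-w rendered from the mask at the source image's
## background and lesion levels
#' @keywords internal
#' @noRd
renderTargetFromMask <- function(srcImg, srcMask, finalMask, spacing) {
  bg <- mean(srcImg[!srcMask])
  fg <- if (any(srcMask)) mean(srcImg[srcMask]) else max(srcImg)
  sm <- smoothScalar(array(as.numeric(finalMask), dim(finalMask)),
                     min(spacing), spacing)
  bg + (fg - bg) * sm
}

#' @keywords internal
#' @noRd
skippedPhase <- function(phase, why) {
  new("PhaseResult", phase = phase, skipped = TRUE, defMap = NULL,
      regions = NULL, fits = list(), rmttSummary = data.frame(),
      notes = why)
}

#' Run one analysis phase of a case
#'
#' Chains the full per-phase analysis: metamorphose the phase's source image
#' into its target, integrate the signed total deformation map over the
#' phase-start lesion mask, threshold the highly dynamic regions, build the
#' rMTT map from the phase-start MTT, bin deformation against rMTT per
#' direction, and fit the Gaussians with their peak +/- sd intervals.
#'
#' @param case a [SyntheticCase-class], or a list with elements `images`,
#'   `masks`, `mtt` (named as in [readCaseDir()]) and optionally `spacing`.
#' @param phase `"acute-subacute"` or `"subacute-final"`.
#' @param config an [analysisConfig()] list.
#' @return A [PhaseResult-class]. A phase whose required inputs are missing
#'   (e.g. no subacute MTT for the second phase) is returned with
#'   `skipped = TRUE` and an explicit note, never silently dropped.
#' @export
runPhase <- function(case, phase = c("acute-subacute", "subacute-final"),
                     config = analysisConfig()) {
  phase <- match.arg(phase)
  cd <- asCaseData(case)
  sp <- rep_len(cd$spacing, length(dim(asVolumeArray(cd$images$acute))))

  if (phase == "acute-subacute") {
    src <- cd$images$acute; tgt <- cd$images$subacute
    lesion <- cd$masks$acute; mtt <- cd$mtt$acute
    if (is.null(tgt) || is.null(lesion))
      return(skippedPhase(phase, "acute/subacute images or mask missing"))
    if (is.null(mtt))
      return(skippedPhase(phase, "acute MTT not available"))
  } else {
    src <- cd$images$subacute
    lesion <- cd$masks$subacute
    mtt <- cd$mtt$subacute
    if (is.null(mtt))
      return(skippedPhase(phase, "subacute MTT not available"))
    if (is.null(src) || is.null(lesion))
      return(skippedPhase(phase, "subacute image or mask missing"))
    tgt <- cd$images$final
    if (is.null(tgt)) {
      if (is.null(cd$masks$final))
        return(skippedPhase(phase, "final image and mask both missing"))
      tgt <- renderTargetFromMask(asVolumeArray(src),
                                  asMaskArray(cd$masks$subacute),
                                  asMaskArray(cd$masks$final), sp)
    }
  }
  lesionMask <- asMaskArray(lesion, "lesion mask")
  if (!identical(dim(asVolumeArray(src)), dim(asVolumeArray(tgt))))
    stop("phase source and target images must share one grid")

  notes <- character(0)
  path <- metamorphose(src, tgt, config$params, spacing = sp)
  if (!isConverged(path))
    notes <- c(notes, sprintf("metamorphosis not converged after %d iters",
                              config$params@maxIters))
  defMap <- withCallingHandlers(
    totalDeformationMap(path, lesionMask, phase, config$deadBand),
    warning = function(w) invokeRestart("muffleWarning"))
  regions <- thresholdDynamicRegions(defMap, config$rule)
  rmtt <- computeRMTT(mtt, lesionMask, config$midline, spacing = sp)

  fits <- list(contraction = NULL, expansion = NULL)
  rows <- list()
  dynMask <- list(contraction = regions@contractingMask,
                  expansion = regions@expandingMask)
  for (dir in c("contraction", "expansion")) {
    samples <- deformationVsRMTT(rmtt, defMap, dir, config$binWidth)
    if (length(samples@bins) >= 3L) {
      fits[[dir]] <- withCallingHandlers(
        fitDeformationGaussian(samples, config$weightedFit),
        warning = function(w) {
          notes <<- c(notes, sprintf("%s fit: %s", dir, conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
    } else {
      notes <- c(notes, sprintf("%s fit not computable (%d bins)", dir,
                                length(samples@bins)))
    }
    v <- rmtt@values[dynMask[[dir]]]
    rows[[dir]] <- data.frame(
      direction = dir, n = length(v),
      min = if (length(v)) min(v) else NA_real_,
      max = if (length(v)) max(v) else NA_real_,
      mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) > 1L) stats::sd(v) else NA_real_)
  }
  new("PhaseResult", phase = phase, skipped = FALSE, defMap = defMap,
      regions = regions, fits = fits,
      rmttSummary = do.call(rbind, unname(rows)), notes = notes)
}

#' Run the two-phase analysis of one case
#'
#' Phase 1 (acute -> subacute) is always attempted; phase 2 (subacute ->
#' final) is attempted iff a subacute MTT map exists, mirroring cohorts in
#' which subacute perfusion imaging is available for only part of the
#' patients. Input masks are validated (binary) before any computation.
#'
#' @param case,config as in [runPhase()].
#' @return Named list of two [PhaseResult-class] objects
#'   (`"acute-subacute"`, `"subacute-final"`); a missing-input phase carries
#'   `skipped = TRUE` with the reason in its notes.
#' @export
runCase <- function(case, config = analysisConfig()) {
  cd <- asCaseData(case)
  for (nm in names(cd$masks)) asMaskArray(cd$masks[[nm]], paste(nm, "mask"))
  list("acute-subacute" = runPhase(cd, "acute-subacute", config),
       "subacute-final" = runPhase(cd, "subacute-final", config))
}

## per-case scalar metrics used by the cohort summary
#' @keywords internal
#' @noRd
phaseMetrics <- function(pr) {
  if (pr@skipped) return(NULL)
  peak <- function(dir) {
    f <- pr@fits[[dir]]
    if (is.null(f) || !f@converged) NA_real_ else f@mean
  }
  data.frame(phase = pr@phase,
             metric = c("contraction rMTT peak", "expansion rMTT peak",
                        "pct lesion highly contracting",
                        "pct lesion highly expanding"),
             value = c(peak("contraction"), peak("expansion"),
                       pr@regions@proportions[["contracting"]],
                       pr@regions@proportions[["expanding"]]))
}

#' Cohort summary of per-case phase results
#'
#' Aggregates per-case metrics (fitted rMTT peaks per direction, volumetric
#' proportions of highly dynamic areas) across cases, per phase: min, max,
#' mean, sd and median, computed only over cases where the metric is defined
#' (n reported per row).
#'
#' @param results list of per-case results as returned by [runCase()] (or a
#'   flat list of [PhaseResult-class] objects).
#' @return A data.frame with one row per metric x phase.
#' @export
cohortSummary <- function(results) {
  if (!length(results)) stop("empty result collection")
  flat <- list()
  for (r in results) {
    if (is(r, "PhaseResult")) flat <- c(flat, list(r))
    else flat <- c(flat, unname(r))
  }
  rows <- do.call(rbind, Filter(Negate(is.null), lapply(flat, phaseMetrics)))
  if (is.null(rows)) stop("no non-skipped phase results to summarize")
  out <- do.call(rbind, lapply(split(rows, list(rows$phase, rows$metric),
                                     drop = TRUE), function(g) {
    v <- g$value[!is.na(g$value)]
    data.frame(phase = g$phase[1L], metric = g$metric[1L], n = length(v),
               min = if (length(v)) min(v) else NA_real_,
               max = if (length(v)) max(v) else NA_real_,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1L) stats::sd(v)
                    else if (length(v) == 1L) 0 else NA_real_,
               median = if (length(v)) stats::median(v) else NA_real_)
  }))
  rownames(out) <- NULL
  out[order(out$phase, out$metric), , drop = FALSE]
}

## per-case interval table used for reporting and plotting
#' @keywords internal
#' @noRd
intervalTable <- function(results, orderBy = NULL) {
  rows <- list()
  ids <- names(results)
  if (is.null(ids)) ids <- sprintf("case%02d", seq_along(results))
  for (i in seq_along(results)) {
    for (pr in results[[i]]) {
      if (!is(pr, "PhaseResult") || pr@skipped) next
      for (dir in names(pr@fits)) {
        f <- pr@fits[[dir]]
        if (is.null(f)) next
        rows[[length(rows) + 1L]] <- data.frame(
          case = ids[i], phase = pr@phase, direction = dir,
          peak = f@mean, p1 = f@p1, p2 = f@p2, rmse = f@rmse,
          converged = f@converged,
          orderBy = if (is.null(orderBy)) i else orderBy[i])
      }
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

#' Export a cohort report
#'
#' Writes the cohort summary as CSV, a machine-readable JSON report
#' (summary, per-case fitted intervals, proportions and notes), and —
#' optionally — per-phase interval plots (cases on the x axis ordered by a
#' covariate, one vertical `[p1, p2]` bar per direction with a dot at the
#' fitted peak).
#'
#' @param summary data.frame from [cohortSummary()].
#' @param results list of per-case results from [runCase()].
#' @param outDir output directory (created if needed).
#' @param orderBy optional numeric covariate per case used to order the
#'   plots (e.g. an admission severity score); cases are ordered by index
#'   when absent.
#' @param plots write interval plots (PDF) per phase.
#' @return Invisibly, the named character vector of files written.
#' @export
exportReport <- function(summary, results, outDir, orderBy = NULL,
                         plots = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- c(csv = file.path(outDir, "cohort_summary.csv"),
             json = file.path(outDir, "report.json"))
  utils::write.csv(summary, files["csv"], row.names = FALSE)
  if (!nrow(summary)) warning("empty results: header-only CSV written")

  iv <- intervalTable(results, orderBy)
  perCase <- lapply(seq_along(results), function(i) {
    lapply(results[[i]], function(pr) {
      if (pr@skipped)
        list(skipped = TRUE, notes = pr@notes)
      else
        list(skipped = FALSE,
             proportions = as.list(pr@regions@proportions),
             thresholds = as.list(pr@regions@thresholds),
             rule = pr@regions@rule,
             notes = pr@notes)
    })
  })
  names(perCase) <- if (is.null(names(results)))
    sprintf("case%02d", seq_along(results)) else names(results)
  jsonlite::write_json(list(summary = summary, intervals = iv,
                            cases = perCase),
                       files["json"], auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  if (plots && nrow(iv)) {
    for (ph in unique(iv$phase)) {
      f <- file.path(outDir, paste0("intervals_", gsub("[^a-z]", "_", ph),
                                    ".pdf"))
      ggplot2::ggsave(f, plotIntervals(iv[iv$phase == ph, , drop = FALSE]),
                      width = 7, height = 4)
      files[paste0("plot_", ph)] <- f
    }
  }
  invisible(files)
}

#' Interval plot of fitted rMTT peaks per case
#'
#' One vertical bar per case and direction spanning `[p1, p2]` with a dot at
#' the fitted peak, cases ordered by the `orderBy` column.
#'
#' @param iv data.frame with columns case, direction, peak, p1, p2, orderBy
#'   (as built by [exportReport()]).
#' @return A ggplot object.
#' @export
plotIntervals <- function(iv) {
  iv$case <- factor(iv$case, levels = unique(iv$case[order(iv$orderBy)]))
  ggplot2::ggplot(iv, ggplot2::aes(x = case, colour = direction)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = p1, ymax = p2),
                            position = ggplot2::position_dodge(width = 0.5),
                            linewidth = 1) +
    ggplot2::geom_point(ggplot2::aes(y = peak),
                        position = ggplot2::position_dodge(width = 0.5),
                        size = 2) +
    ggplot2::scale_colour_manual(values = c(contraction = "#3355bb",
                                            expansion = "#cc3344")) +
    ggplot2::labs(x = "case", y = "rMTT",
                  title = "rMTT associated with rapidly deforming lesion areas") +
    ggplot2::theme_minimal()
}
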
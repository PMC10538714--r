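#' @include AllClasses.R synth-cohort.R synth-acquisitions.R pet-kinetics.R
#' @include dce-tofts.R qc.R stats-longitudinal.R
NULL

#' Configuration of an end-to-end pipeline run
#'
#' Bundles every knob of a full run with defaults reproducing the study's
#' stated constants: bolus ratio 10, inter-bolus delay 25 s, hematocrit
#' 0.45, extraction fraction 0.5, 4-minute PET fit window, 16-frame
#' binning schedule, 5-SD LGE threshold.
#'
#' @param seed master RNG seed (default 1).
#' @param cohort a [cohortSimConfig()].
#' @param curveLevel logical: simulate and fit per-territory PET and DCE
#'   curves for every animal-visit (TRUE, the full pipeline) or carry the
#'   tabular draws through directly (FALSE).
#' @param petEvents expected list-mode events per PET curve, or NULL for
#'   noise-free curves.
#' @param dceNoiseSd additive noise SD on DCE signal curves (default 0).
#' @param petK2,dceKep true clearance/efflux rates used for curve
#'   generation, 1/min.
#' @param fitWindow PET fit window, seconds (default 240).
#' @param rc [RenkinCroneParams-class] (default a = 0).
#' @param hematocrit,extractionFraction DCE conversion constants.
#' @param qcResidualThreshold residual-contrast threshold (default 0.1).
#' @param lgeNSd LGE threshold in reference SDs (default 5).
#' @return list of class \code{"RunConfig"}.
#' @export
pipelineConfig <- function(seed = 1, cohort = cohortSimConfig(),
                           curveLevel = TRUE, petEvents = NULL,
                           dceNoiseSd = 0, petK2 = 0.4, dceKep = 0.8,
                           fitWindow = 240, rc = RenkinCroneParams(),
                           hematocrit = 0.45, extractionFraction = 0.5,
                           qcResidualThreshold = 0.1, lgeNSd = 5) {
  cfg <- list(seed = seed, cohort = cohort, curveLevel = curveLevel,
              petEvents = petEvents, dceNoiseSd = dceNoiseSd,
              petK2 = petK2, dceKep = dceKep, fitWindow = fitWindow,
              rc = rc, hematocrit = hematocrit,
              extractionFraction = extractionFraction,
              qcResidualThreshold = qcResidualThreshold, lgeNSd = lgeNSd)
  class(cfg) <- "RunConfig"
  cfg
}

# per-visit curve-level measurement: simulate PET and DCE acquisitions
# from the visit's ground-truth territory MBF and fit them back
.measureVisit <- function(truthMbf, config, visitSeed) {
  set.seed(visitSeed)
  rc <- config$rc
  ef <- config$extractionFraction
  outNh3 <- numeric(length(truthMbf))
  names(outNh3) <- names(truthMbf)
  for (tr in names(truthMbf)) {
    p <- OneTissueParams(renkinCroneK1(truthMbf[[tr]], rc), config$petK2)
    sim <- simulatePET(params = p,
                       totalEvents = config$petEvents %||% 1e5,
                       noiseFree = is.null(config$petEvents))
    fit <- fitOneTissue(sim$tissue, sim$lvRef,
                        fitWindow = config$fitWindow, rc = rc)
    outNh3[[tr]] <- fittedMBF(fit)
  }
  tparams <- lapply(truthMbf, function(m) ToftsParams(ef * m, config$dceKep))
  acq <- simulateDualBolus(tissueParams = tparams,
                           noiseSd = config$dceNoiseSd,
                           hematocrit = config$hematocrit)
  qc <- qcReport(acq, residualThreshold = config$qcResidualThreshold)
  outDce <- rep(NA_real_, length(truthMbf))
  names(outDce) <- names(truthMbf)
  if (!qc$excluded) {
    q <- quantifyDCE(acq, hematocrit = config$hematocrit,
                     extractionFraction = ef)
    outDce <- vapply(q$fits, fittedMBF, numeric(1))[names(truthMbf)]
  }
  list(nh3 = outNh3, dce = outDce, qc = qc)
}

#' Run the full pipeline
#'
#' Orchestrates an end-to-end run: simulate the ground-truth cohort,
#' (optionally) simulate and fit per-territory PET and dual-bolus DCE
#' curves for every animal-visit, apply the dual-bolus QC checks,
#' assemble the measured cohort, run the statistics battery, and write
#' every stage's output under \code{outDir} (no timestamps: the directory
#' contents are a pure function of the configuration and seed).
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory, or NULL to skip writing files.
#' @return (invisibly) list with \code{truth} and \code{measured} cohort
#'   data.frames, \code{qc} (data.frame of per-visit QC outcomes),
#'   \code{report} (the [buildStatReport()] output) and \code{outDir}.
#' @examples
#' \donttest{
#' res <- runPipeline(pipelineConfig(
#'   seed = 7, cohort = cohortSimConfig(nAnimals = 2),
#'   curveLevel = FALSE))
#' }
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  if (config$curveLevel) {
    # curve-level runs measure DCE by fitting simulated curves; the
    # tabular DCE measurement noise would double-count that error, so the
    # truth table carries the shared ground-truth MBF in both modalities
    config$cohort$dceNoiseCv <- 0
  }
  truth <- simulateCohort(config$cohort, seed = config$seed)
  measured <- truth
  qcRows <- NULL

  if (config$curveLevel) {
    keys <- unique(truth[, c("animal_id", "timepoint")])
    for (r in seq_len(nrow(keys))) {
      a <- keys$animal_id[r]; tp <- keys$timepoint[r]
      sel <- truth$animal_id == a & truth$timepoint == tp
      nh3sel <- sel & truth$modality == "NH3"
      truthMbf <- stats::setNames(as.list(truth$mbf[nh3sel]),
                                  truth$territory[nh3sel])
      visitSeed <- (config$seed * 1000L + r) %% .Machine$integer.max
      m <- tryCatch(.measureVisit(truthMbf, config, visitSeed),
                    error = function(e) e)
      if (inherits(m, "error")) {
        # per-unit failure: record and continue with the remaining visits
        measured$mbf[sel] <- NA_real_
        qcRows <- rbind(qcRows, data.frame(
          animal_id = a, timepoint = tp, excluded = TRUE,
          reason = conditionMessage(m), stringsAsFactors = FALSE))
        next
      }
      for (tr in names(m$nh3)) {
        measured$mbf[sel & measured$modality == "NH3" &
                       measured$territory == tr] <- m$nh3[[tr]]
        measured$mbf[sel & measured$modality == "DCE" &
                       measured$territory == tr] <- m$dce[[tr]]
      }
      qcRows <- rbind(qcRows, data.frame(
        animal_id = a, timepoint = tp, excluded = m$qc$excluded,
        reason = NA_character_, stringsAsFactors = FALSE))
    }
  }

  exclusions <- if (!is.null(qcRows))
    qcRows[qcRows$excluded, c("animal_id", "timepoint"), drop = FALSE]
  else NULL
  report <- buildStatReport(measured, qcExclusions = exclusions)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeCohort(truth, file.path(outDir, "cohort_truth.csv"))
    writeCohort(measured, file.path(outDir, "cohort_measured.csv"))
    if (!is.null(qcRows))
      utils::write.csv(qcRows, file.path(outDir, "qc_summary.csv"),
                       row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed,
           nAnimals = config$cohort$nAnimals,
           curveLevel = config$curveLevel,
           constants = list(bolusRatio = 10, interBolusDelay = 25,
                            hematocrit = config$hematocrit,
                            extractionFraction = config$extractionFraction,
                            fitWindow = config$fitWindow,
                            lgeNSd = config$lgeNSd)),
      file.path(outDir, "config.json"), auto_unbox = TRUE)
    jsonlite::write_json(
      list(omnibus = report$omnibus, contrasts = report$contrasts,
           pearson = report$pearson,
           pairedModality = report$pairedModality, rpp = report$rpp,
           nExcluded = report$nExcluded),
      file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
  }
  invisible(list(truth = truth, measured = measured, qc = qcRows,
                 report = report, outDir = outDir))
}

#' Read / write a time curve as CSV
#'
#' Columns \code{time_s}, \code{value} and (optionally)
#' \code{duration_s}.
#'
#' @param curve a [TimeCurve-class].
#' @param path file path.
#' @return \code{readTimeCurve}: a [TimeCurve-class];
#'   \code{writeTimeCurve}: the path, invisibly.
#' @export
writeTimeCurve <- function(curve, path) {
  stopifnot(is(curve, "TimeCurve"))
  df <- data.frame(time_s = curve@times, value = curve@values)
  if (length(curve@durations)) df$duration_s <- curve@durations
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTimeCurve
#' @export
readTimeCurve <- function(path) {
  df <- utils::read.csv(path)
  TimeCurve(df$time_s, df$value,
            durations = if ("duration_s" %in% names(df)) df$duration_s
                        else numeric(0))
}
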
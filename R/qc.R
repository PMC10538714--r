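#' @include AllClasses.R dce-tofts.R
NULL

.preWindowMean <- function(curve, injectionTime) {
  v <- curve@values[curve@times < injectionTime]
  if (!length(v)) stop("empty pre-injection baseline window")
  mean(v)
}

#' Detect residual contrast before the high-dose injection
#'
#' Flags acquisitions whose high-dose pre-injection baseline is elevated
#' above the small-bolus pre-injection baseline — residual contrast in the
#' LV from an earlier injection, which breaks the dual-bolus baseline
#' assumption. The metric is
#' (pre-large baseline - pre-small baseline) / small-bolus peak;
#' the check fails when it strictly exceeds \code{threshold} (a value
#' exactly at the threshold passes). The 0.1 default is an explicit
#' surrogate for the study's visual exclusion call.
#'
#' @param acq a [DualBolusAcquisition-class].
#' @param threshold failure threshold on the baseline-elevation ratio.
#' @return list with \code{pass} (logical) and \code{metric}.
#' @export
detectResidualContrast <- function(acq, threshold = 0.1) {
  stopifnot(is(acq, "DualBolusAcquisition"))
  preSmall <- .preWindowMean(acq@smallAIF, acq@smallInjectionTime)
  preLarge <- .preWindowMean(acq@largeAIF, acq@largeInjectionTime)
  peak <- max(acq@smallAIF@values) - preSmall
  if (peak <= 0) stop("no detectable small-bolus peak")
  metric <- (preLarge - preSmall) / peak
  list(pass = !(metric > threshold), metric = metric)
}

#' Detect a reversed bolus injection order
#'
#' The dual-bolus scheme injects the low-dose bolus first; an acquisition
#' whose first-pass peak exceeds the second-pass peak indicates the
#' high-dose bolus was injected first in error. Equal peaks pass with a
#' warning (ambiguous order). Both passes must contain a detectable bolus.
#'
#' @param acq a [DualBolusAcquisition-class].
#' @return list with \code{pass} (logical) and \code{metric}
#'   (first-pass peak / second-pass peak).
#' @export
detectReversedBolus <- function(acq) {
  stopifnot(is(acq, "DualBolusAcquisition"))
  preSmall <- .preWindowMean(acq@smallAIF, acq@smallInjectionTime)
  preLarge <- .preWindowMean(acq@largeAIF, acq@largeInjectionTime)
  peak1 <- max(acq@smallAIF@values) - preSmall
  peak2 <- max(acq@largeAIF@values) - preLarge
  if (peak1 <= 0 || peak2 <= 0)
    stop("could not identify two bolus passes")
  if (peak1 == peak2)
    warning("first- and second-pass peaks are equal; order ambiguous")
  list(pass = !(peak1 > peak2), metric = peak1 / peak2)
}

#' Run all dual-bolus QC checks on an acquisition
#'
#' Applies [detectResidualContrast()] and [detectReversedBolus()];
#' detector errors (e.g. a missing baseline window) count as failed
#' checks. The acquisition is excluded iff any check fails.
#'
#' @param acq a [DualBolusAcquisition-class].
#' @param id acquisition identifier carried into the report.
#' @param residualThreshold passed to [detectResidualContrast()].
#' @return list of class \code{"QCReport"} with \code{acquisition_id},
#'   \code{checks} (named pass/fail), \code{metrics}, \code{errors} and
#'   \code{excluded}.
#' @examples
#' qcReport(makeQCFixtures("clean", seed = 1))$excluded   # FALSE
#' @export
qcReport <- function(acq, id = "acq", residualThreshold = 0.1) {
  run <- function(f) tryCatch(f(), error = function(e)
    list(pass = FALSE, metric = NA_real_, error = conditionMessage(e)))
  res <- run(function() detectResidualContrast(acq, residualThreshold))
  rev <- run(function() suppressWarnings(detectReversedBolus(acq)))
  checks <- c(residual_contrast = res$pass, reversed_order = rev$pass)
  out <- list(acquisition_id = id, checks = checks,
              metrics = c(baseline_elevation_ratio = res$metric,
                          peak_ratio = rev$metric),
              errors = c(residual_contrast = res$error %||% NA_character_,
                         reversed_order = rev$error %||% NA_character_),
              excluded = any(!checks))
  class(out) <- "QCReport"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
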
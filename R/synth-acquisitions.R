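#' @include AllClasses.R synth-aif.R dce-tofts.R pet-kinetics.R curves.R
NULL

# first- and second-bolus blood signal on a common grid
.dualBolusSignal <- function(grid, firstAmp, secondAmp, firstInj, secondInj,
                             alpha, beta) {
  first <- .gammaShape(grid, firstInj, firstAmp, alpha, beta)
  second <- .gammaShape(grid, secondInj, secondAmp, alpha, beta)
  list(first = first, second = second, combined = first + second)
}

.makeDualBolus <- function(aif, tissueParams, bolusRatio, interBolusDelay,
                           noiseSd, hematocrit, preInjectionWindow,
                           totalTime, dt, seed, reversed = FALSE,
                           residualLevel = 0) {
  stopifnot(is(aif, "GammaVariateAIF"))
  if (interBolusDelay <= 0) stop("'interBolusDelay' must be > 0")
  if (bolusRatio <= 1) stop("'bolusRatio' must be > 1")
  if (noiseSd < 0) stop("'noiseSd' must be >= 0")
  if (!is.null(seed)) set.seed(seed)

  grid <- seq(0, totalTime, by = dt)
  smallInj <- aif@onset
  largeInj <- smallInj + interBolusDelay
  splitT <- largeInj - preInjectionWindow
  if (splitT <= smallInj)
    stop("pre-injection window leaves no room for the small bolus")

  smallAmp <- aif@amplitude / bolusRatio
  largeAmp <- aif@amplitude
  sig <- if (reversed)
    .dualBolusSignal(grid, largeAmp, smallAmp, smallInj, largeInj,
                     aif@alpha, aif@beta)
  else
    .dualBolusSignal(grid, smallAmp, largeAmp, smallInj, largeInj,
                     aif@alpha, aif@beta)

  blood <- sig$combined
  # residual contrast: elevated baseline persisting into the high-dose pass
  inLarge <- grid >= splitT
  if (residualLevel > 0)
    blood[inLarge] <- blood[inLarge] + residualLevel * max(sig$first)

  # idealized per-pass tissue curves driven by each pass's own plasma input
  cpFirst <- TimeCurve(grid, sig$first / (1 - hematocrit))
  cpSecond <- TimeCurve(grid, sig$second / (1 - hematocrit))
  tisFirst <- lapply(tissueParams, function(p)
    toftsForward(p, cpFirst, grid)@values)
  tisSecond <- lapply(tissueParams, function(p)
    toftsForward(p, cpSecond, grid)@values)

  addNoise <- function(v) if (noiseSd > 0)
    v + stats::rnorm(length(v), 0, noiseSd) else v
  blood <- addNoise(blood)
  inSmall <- !inLarge

  new("DualBolusAcquisition",
      smallAIF = TimeCurve(grid[inSmall], blood[inSmall]),
      largeAIF = TimeCurve(grid[inLarge], blood[inLarge]),
      smallTissue = lapply(tisFirst, function(v)
        TimeCurve(grid[inSmall], addNoise(v[inSmall]))),
      largeTissue = lapply(tisSecond, function(v)
        TimeCurve(grid[inLarge], addNoise(v[inLarge]))),
      bolusRatio = bolusRatio, interBolusDelay = interBolusDelay,
      preInjectionWindow = preInjectionWindow,
      smallInjectionTime = smallInj, largeInjectionTime = largeInj)
}

#' Simulate a dual-bolus DCE-MRI acquisition
#'
#' Generates the paired low-dose / high-dose acquisition of the dual-bolus
#' scheme: the low-dose arterial bolus is the high-dose gamma-variate shape
#' scaled by \code{1/bolusRatio} (linearity premise), injected
#' \code{interBolusDelay} seconds earlier; myocardial tissue curves are the
#' Tofts forward model driven by each pass's own plasma-corrected arterial
#' input (idealized, non-saturating signal proportional to concentration);
#' optional additive Gaussian noise on every sampled value.
#'
#' @param aif [GammaVariateAIF-class]; \code{onset} is the low-dose
#'   injection time and \code{amplitude} the high-dose peak.
#' @param tissueParams named list of [ToftsParams-class], one tissue curve
#'   per entry (default one global curve with Ktrans 0.45 ml/min/g,
#'   kep 0.8 /min — resting flow 0.9 ml/min/g at extraction 0.5).
#' @param bolusRatio large:small contrast volume ratio (default 10).
#' @param interBolusDelay seconds between injections (default 25).
#' @param noiseSd additive Gaussian noise SD in signal units (default 0).
#' @param hematocrit assumed hematocrit used for the plasma-corrected
#'   tissue forward model (default 0.45).
#' @param preInjectionWindow baseline seconds before each injection
#'   (default 10).
#' @param totalTime acquisition length, seconds (default 100).
#' @param dt sampling interval, seconds (default 0.5).
#' @param seed optional RNG seed for the noise.
#' @return A [DualBolusAcquisition-class].
#' @examples
#' acq <- simulateDualBolus(noiseSd = 0)
#' @export
simulateDualBolus <- function(aif = GammaVariateAIF(onset = 8,
                                                    amplitude = 40,
                                                    alpha = 3, beta = 4),
                              tissueParams = list(
                                global = ToftsParams(0.45, 0.8, 0)),
                              bolusRatio = 10, interBolusDelay = 25,
                              noiseSd = 0, hematocrit = 0.45,
                              preInjectionWindow = 8, totalTime = 100,
                              dt = 0.5, seed = NULL) {
  .makeDualBolus(aif, tissueParams, bolusRatio, interBolusDelay, noiseSd,
                 hematocrit, preInjectionWindow, totalTime, dt, seed)
}

#' Simulate a dynamic PET acquisition
#'
#' Generates LV blood-pool and myocardial tissue curves for the one-tissue
#' model: the LV curve is a gamma-variate bolus, the tissue curve its
#' one-tissue forward model. In noise-free mode the exact frame-averaged
#' forward curves are returned; otherwise list-mode event streams are drawn
#' from inhomogeneous Poisson processes with intensity proportional to each
#' curve (expected \code{totalEvents} events per curve), binned with
#' [binListMode()], and rescaled back to curve units, so the noise-free
#' limit of the binned curve is the frame-averaged model.
#'
#' @param aif [GammaVariateAIF-class] for the LV input.
#' @param params [OneTissueParams-class] tissue kinetics.
#' @param schedule [FrameSchedule-class] (default the 16-frame dynamic
#'   ammonia schedule).
#' @param totalEvents expected list-mode events per curve (default 1e5).
#' @param seed RNG seed.
#' @param noiseFree logical; return exact frame-averaged curves instead of
#'   Poisson realizations.
#' @return list with [TimeCurve-class] elements \code{lv} and
#'   \code{tissue} (frame-binned data products), \code{lvRef} (the densely
#'   sampled noiseless arterial input — fitting against the frame-binned
#'   LV instead adds a few percent of peak-flattening bias), and (Poisson
#'   mode) integer \code{nEventsLv}, \code{nEventsTissue}.
#' @export
simulatePET <- function(aif = GammaVariateAIF(onset = 5, amplitude = 40,
                                              alpha = 3, beta = 8,
                                              recircFraction = 0.15),
                        params = OneTissueParams(0.8, 0.4),
                        schedule = nh3FrameSchedule(),
                        totalEvents = 1e5, seed = NULL, noiseFree = FALSE) {
  stopifnot(is(schedule, "FrameSchedule"))
  if (!noiseFree && totalEvents <= 0) stop("'totalEvents' must be > 0")
  Ttot <- totalDuration(schedule)
  dense <- seq(0, Ttot, by = 0.05)
  lvDense <- gammaVariateAIF(aif, dense)
  ctDense <- oneTissueForward(params, lvDense, dense)
  # reference input for fitting: 0.25 s sampling is ample for the smooth
  # bolus and keeps the convolution grid small
  lvRef <- gammaVariateAIF(aif, seq(0, Ttot, by = 0.25))

  mids <- frameMids(schedule)
  durs <- frameDurations(schedule)
  frameAvg <- function(curve) {
    f <- function(t) .curveAt(curve, t)
    .frameAveragedModel(f, mids, durs)
  }
  if (noiseFree) {
    return(list(
      lv = TimeCurve(mids, frameAvg(lvDense), durs),
      tissue = TimeCurve(mids, frameAvg(ctDense), durs),
      lvRef = lvRef))
  }

  if (!is.null(seed)) set.seed(seed)
  drawCurve <- function(curve) {
    v <- pmax(curve@values, 0)
    cum <- c(0, cumsum((v[-1L] + v[-length(v)]) / 2 * diff(curve@times)))
    total <- cum[length(cum)]
    if (total <= 0) {
      events <- numeric(0)
    } else {
      n <- stats::rpois(1L, totalEvents)
      u <- sort(stats::runif(n)) * total
      events <- stats::approx(cum, curve@times, xout = u,
                              ties = "ordered")$y
    }
    binned <- binListMode(events, schedule)
    scale <- if (total > 0) total / totalEvents else 1
    list(curve = TimeCurve(binned@times, binned@values * scale,
                           binned@durations),
         n = length(events))
  }
  lvDraw <- drawCurve(lvDense)
  ctDraw <- drawCurve(ctDense)
  list(lv = lvDraw$curve, tissue = ctDraw$curve, lvRef = lvRef,
       nEventsLv = lvDraw$n, nEventsTissue = ctDraw$n)
}

#' Dual-bolus quality-control fixtures
#'
#' Builds acquisitions with known QC status: \code{"clean"} is a nominal
#' acquisition; \code{"residual_contrast"} has an elevated baseline in the
#' high-dose pre-injection window (residual contrast from an earlier
#' injection, 25\% of the small-bolus peak); \code{"reversed_order"} has
#' the high-dose bolus injected first by mistake.
#'
#' @param kind one of \code{"clean"}, \code{"residual_contrast"},
#'   \code{"reversed_order"}.
#' @param seed RNG seed for the noise.
#' @param noiseSd additive Gaussian noise SD in signal units
#'   (default 0.05, ~1.2\% of the small-bolus peak at default amplitude).
#' @param ... further arguments passed to the generator (see
#'   [simulateDualBolus()]).
#' @return A [DualBolusAcquisition-class].
#' @export
makeQCFixtures <- function(kind = c("clean", "residual_contrast",
                                    "reversed_order"),
                           seed = NULL, noiseSd = 0.05, ...) {
  kind <- match.arg(kind)
  args <- list(aif = GammaVariateAIF(onset = 8, amplitude = 40,
                                     alpha = 3, beta = 4),
               tissueParams = list(global = ToftsParams(0.45, 0.8, 0)),
               bolusRatio = 10, interBolusDelay = 25, noiseSd = noiseSd,
               hematocrit = 0.45, preInjectionWindow = 8,
               totalTime = 100, dt = 0.5, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  args$reversed <- kind == "reversed_order"
  args$residualLevel <- if (kind == "residual_contrast") 0.25 else 0
  do.call(.makeDualBolus, args)
}

#' Simulate a toy late-gadolinium-enhancement image
#'
#' A 2D Gaussian background N(refMean, refSd^2) with lesion pixels shifted
#' upward by \code{lesionDelta}, plus a reference-region mask drawn from
#' non-lesion remote myocardium (the left quarter of the image by default).
#'
#' @param shape integer c(rows, cols) (default c(64, 64)).
#' @param refMean,refSd background (reference myocardium) intensity mean
#'   and SD.
#' @param lesionMask logical matrix of lesion pixels, or NULL for no lesion.
#' @param lesionDelta intensity added to lesion pixels (>= 0).
#' @param seed RNG seed.
#' @return list with \code{image} (matrix), \code{referenceMask} and
#'   \code{lesionMask} (logical matrices).
#' @export
simulateLGEImage <- function(shape = c(64, 64), refMean = 100, refSd = 10,
                             lesionMask = NULL, lesionDelta = 0,
                             seed = NULL) {
  if (lesionDelta < 0) stop("'lesionDelta' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  img <- matrix(stats::rnorm(prod(shape), refMean, refSd),
                nrow = shape[1L], ncol = shape[2L])
  if (is.null(lesionMask))
    lesionMask <- matrix(FALSE, shape[1L], shape[2L])
  stopifnot(identical(dim(lesionMask), dim(img)))
  img[lesionMask] <- img[lesionMask] + lesionDelta
  refMask <- matrix(FALSE, shape[1L], shape[2L])
  refMask[, seq_len(max(1L, shape[2L] %/% 4L))] <- TRUE
  refMask <- refMask & !lesionMask
  list(image = img, referenceMask = refMask, lesionMask = lesionMask)
}
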
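#' @import methods
NULL

#' Sampled time curve
#'
#' A sampled time series of tracer activity or contrast signal intensity:
#' strictly increasing sample times in seconds, one value per time, and
#' (optionally, for frame-binned PET data) one frame duration per sample.
#' Frames must not overlap when durations are present.
#'
#' @slot times numeric, sample times or frame midpoints in seconds,
#'   strictly increasing.
#' @slot values numeric, activity (kBq/ml) or signal intensity (a.u.),
#'   all finite.
#' @slot durations numeric, per-frame durations in seconds (all positive),
#'   or \code{numeric(0)} for point-sampled curves.
#'
#' @seealso [TimeCurve()] for the constructor, [binListMode()],
#'   [readTimeCurve()].
#' @export
setClass("TimeCurve",
  representation(times = "numeric", values = "numeric",
                 durations = "numeric"),
  prototype(times = numeric(0), values = numeric(0), durations = numeric(0))
)

setValidity("TimeCurve", function(object) {
  t <- object@times; v <- object@values; d <- object@durations
  if (length(t) != length(v))
    return("'times' and 'values' must have the same length")
  if (any(!is.finite(t)))
    return("'times' must be finite")
  if (any(!is.finite(v)))
    return("'values' must be finite")
  if (length(t) > 1L && any(diff(t) <= 0))
    return("'times' must be strictly increasing")
  if (length(d)) {
    if (length(d) != length(t))
      return("'durations' must match 'times' in length")
    if (any(!is.finite(d)) || any(d <= 0))
      return("'durations' must be positive and finite")
    # frames [mid - d/2, mid + d/2] must not overlap
    if (length(t) > 1L) {
      ends <- t[-length(t)] + d[-length(d)] / 2
      starts <- t[-1L] - d[-1L] / 2
      if (any(starts - ends < -1e-9))
        return("frames overlap: check 'times' and 'durations'")
    }
  }
  TRUE
})

#' PET frame schedule
#'
#' An ordered list of frame durations (seconds) describing how a list-mode
#' acquisition is binned, e.g. the 16-frame schedule
#' 12 x 10 s, 2 x 30 s, 1 x 60 s, 1 x 360 s.
#'
#' @slot durations numeric, positive frame durations in seconds, in
#'   acquisition order.
#'
#' @seealso [makeFrameSchedule()], [binListMode()]
#' @export
setClass("FrameSchedule",
  representation(durations = "numeric"),
  prototype(durations = numeric(0))
)

setValidity("FrameSchedule", function(object) {
  d <- object@durations
  if (length(d) == 0L)
    return("a FrameSchedule needs at least one frame")
  if (any(!is.finite(d)) || any(d <= 0))
    return("frame durations must be positive and finite")
  TRUE
})

#' 16-segment heart model with coronary territories
#'
#' Maps each of the 16 segments of the canine heart model to the coronary
#' territory that perfuses it: LAD, LCX, or BOTH (supplied by both arteries).
#' All three territories must be non-empty.
#'
#' @slot territories named character vector of length 16; names are the
#'   segment ids \code{"1"}..\code{"16"}, values in
#'   \code{c("LAD","LCX","BOTH")}.
#'
#' @seealso [defaultSegmentModel()], [aggregateSegments()]
#' @export
setClass("SegmentModel",
  representation(territories = "character")
)

.TERRITORIES <- c("LAD", "LCX", "BOTH")

setValidity("SegmentModel", function(object) {
  tr <- object@territories
  if (length(tr) != 16L)
    return("exactly 16 segments are required")
  if (!identical(sort(as.integer(names(tr))), 1:16))
    return("segment names must be '1'..'16', each exactly once")
  if (!all(tr %in% .TERRITORIES))
    return("territories must be one of LAD, LCX, BOTH")
  if (!all(.TERRITORIES %in% tr))
    return("every territory (LAD, LCX, BOTH) must own at least one segment")
  TRUE
})

#' Gamma-variate bolus shape
#'
#' Parameters of a gamma-variate arterial bolus:
#' \deqn{C(t) = A \left(\frac{t-t_0}{\beta}\right)^\alpha
#'   e^{\alpha (1 - (t-t_0)/\beta)}, \quad t > t_0,}
#' zero before onset, so the peak value is \eqn{A} at \eqn{t_0 + \beta}.
#' An optional recirculation bump (same shape, delayed by \eqn{2\beta},
#' broadened to scale \eqn{2\beta}, amplitude \code{recircFraction * A})
#' emulates second-pass contrast.
#'
#' @slot onset numeric, bolus arrival time t0 in seconds.
#' @slot amplitude numeric, peak value A (signal or activity units).
#' @slot alpha numeric, unitless shape parameter, > 0.
#' @slot beta numeric, time-to-peak scale in seconds, > 0.
#' @slot recircFraction numeric in [0, 1), recirculation amplitude as a
#'   fraction of the first-pass peak.
#'
#' @seealso [gammaVariateAIF()]
#' @export
setClass("GammaVariateAIF",
  representation(onset = "numeric", amplitude = "numeric", alpha = "numeric",
                 beta = "numeric", recircFraction = "numeric"),
  prototype(onset = 0, amplitude = 1, alpha = 3, beta = 6, recircFraction = 0)
)

setValidity("GammaVariateAIF", function(object) {
  if (object@alpha <= 0) return("'alpha' must be > 0")
  if (object@beta <= 0) return("'beta' must be > 0")
  if (object@amplitude < 0) return("'amplitude' must be >= 0")
  if (object@recircFraction < 0 || object@recircFraction >= 1)
    return("'recircFraction' must be in [0, 1)")
  TRUE
})

#' One-tissue-compartment kinetic parameters
#'
#' Uptake and clearance parameters of the one-tissue compartment model
#' \eqn{C_t(t) = K_1 e^{-k_2 t} * C_{LV}(t)}: K1 in ml/min/g, k2 in 1/min.
#'
#' @slot K1 numeric, uptake rate constant, ml/min/g, >= 0.
#' @slot k2 numeric, clearance rate constant, 1/min, >= 0.
#' @export
setClass("OneTissueParams",
  representation(K1 = "numeric", k2 = "numeric")
)

setValidity("OneTissueParams", function(object) {
  if (!is.finite(object@K1) || object@K1 < 0)
    return("'K1' must be finite and >= 0")
  if (!is.finite(object@k2) || object@k2 < 0)
    return("'k2' must be finite and >= 0")
  TRUE
})

#' Renkin-Crone extraction parameters
#'
#' Parameters (a, b) of the Renkin-Crone relation
#' \eqn{K_1 = (1 - a e^{-b \cdot MBF}) \cdot MBF} linking the measured
#' uptake constant to flow. With \code{a = 0} the relation is the identity
#' K1 = MBF, the operating approximation for ammonia at resting canine flows
#' (extraction ~ 1 below 6 ml/min/g).
#'
#' @slot a numeric in [0, 1), unitless.
#' @slot b numeric >= 0, (ml/min/g)^-1.
#' @export
setClass("RenkinCroneParams",
  representation(a = "numeric", b = "numeric"),
  prototype(a = 0, b = 0)
)

setValidity("RenkinCroneParams", function(object) {
  if (!is.finite(object@a) || object@a < 0 || object@a >= 1)
    return("'a' must lie in [0, 1)")
  if (!is.finite(object@b) || object@b < 0)
    return("'b' must be >= 0")
  TRUE
})

#' Tofts model parameters
#'
#' Transfer constant, efflux rate and bolus-arrival delay of the Tofts
#' model \eqn{C_t(t - t_0) = K^{trans} \int_0^t C_p(\tau)
#' e^{-k_{ep}(t - t_0 - \tau)} d\tau}.
#'
#' @slot Ktrans numeric, ml/min/g, >= 0.
#' @slot kep numeric, 1/min, >= 0.
#' @slot t0 numeric, onset delay in seconds, >= 0.
#' @export
setClass("ToftsParams",
  representation(Ktrans = "numeric", kep = "numeric", t0 = "numeric"),
  prototype(t0 = 0)
)

setValidity("ToftsParams", function(object) {
  if (!is.finite(object@Ktrans) || object@Ktrans < 0)
    return("'Ktrans' must be finite and >= 0")
  if (!is.finite(object@kep) || object@kep < 0)
    return("'kep' must be finite and >= 0")
  if (!is.finite(object@t0) || object@t0 < 0)
    return("'t0' must be finite and >= 0")
  TRUE
})

#' Dual-bolus DCE-MRI acquisition
#'
#' Paired low-dose ("small", 0.4 ml) and high-dose ("large", 4 ml) bolus
#' passes of a dual-bolus perfusion acquisition: arterial (LV blood pool)
#' curves and per-segment myocardial tissue curves for each pass, plus the
#' injection scheme (dose ratio, inter-bolus delay, injection times).
#'
#' @slot smallAIF,largeAIF [TimeCurve] arterial curves of the two passes.
#' @slot smallTissue,largeTissue named lists of [TimeCurve], one per
#'   segment or territory.
#' @slot bolusRatio numeric > 1, large:small contrast volume ratio
#'   (default 10).
#' @slot interBolusDelay numeric > 0, seconds between injections
#'   (default 25).
#' @slot preInjectionWindow numeric > 0, seconds of baseline acquired
#'   before each injection.
#' @slot smallInjectionTime,largeInjectionTime numeric, injection times in
#'   seconds on the common acquisition clock.
#' @export
setClass("DualBolusAcquisition",
  representation(smallAIF = "TimeCurve", largeAIF = "TimeCurve",
                 smallTissue = "list", largeTissue = "list",
                 bolusRatio = "numeric", interBolusDelay = "numeric",
                 preInjectionWindow = "numeric",
                 smallInjectionTime = "numeric",
                 largeInjectionTime = "numeric")
)

setValidity("DualBolusAcquisition", function(object) {
  if (object@bolusRatio <= 1) return("'bolusRatio' must be > 1")
  if (object@interBolusDelay <= 0) return("'interBolusDelay' must be > 0")
  if (object@preInjectionWindow <= 0)
    return("'preInjectionWindow' must be > 0")
  if (!all(vapply(object@smallTissue, is, logical(1), "TimeCurve")) ||
      !all(vapply(object@largeTissue, is, logical(1), "TimeCurve")))
    return("tissue slots must be lists of TimeCurve objects")
  TRUE
})

#' Fractionated dose scheme
#'
#' A radiation scheme of \code{nFractions} fractions of
#' \code{dosePerFraction} Gy each, with the tissue's linear-quadratic
#' alpha/beta ratio in Gy.
#'
#' @slot nFractions integer >= 1.
#' @slot dosePerFraction numeric > 0, Gy.
#' @slot alphaBeta numeric > 0, Gy.
#' @export
setClass("DoseScheme",
  representation(nFractions = "numeric", dosePerFraction = "numeric",
                 alphaBeta = "numeric")
)

setValidity("DoseScheme", function(object) {
  n <- object@nFractions
  if (!is.finite(n) || n < 1 || n != round(n))
    return("'nFractions' must be a positive integer")
  if (!is.finite(object@dosePerFraction) || object@dosePerFraction <= 0)
    return("'dosePerFraction' must be > 0")
  if (!is.finite(object@alphaBeta) || object@alphaBeta <= 0)
    return("'alphaBeta' must be > 0")
  TRUE
})

#' One-tissue-compartment fit result
#'
#' @slot params [OneTissueParams] fitted (K1, k2).
#' @slot mbf numeric, flow from K1 via the Renkin-Crone inversion, ml/min/g.
#' @slot residualNorm numeric, weighted residual sum of squares.
#' @slot weights numeric, per-frame weights used.
#' @slot fitWindow numeric, fitted time window in seconds.
#' @slot rcParams [RenkinCroneParams] used for the K1 -> MBF conversion.
#' @export
setClass("PETFitResult",
  representation(params = "OneTissueParams", mbf = "numeric",
                 residualNorm = "numeric", weights = "numeric",
                 fitWindow = "numeric", rcParams = "RenkinCroneParams")
)

setValidity("PETFitResult", function(object) {
  K1 <- object@params@K1; a <- object@rcParams@a
  if (is.finite(object@mbf)) {
    if (a == 0 && abs(object@mbf - K1) > 1e-6 * max(1, K1))
      return("with a = 0 the Renkin-Crone inversion must give mbf = K1")
    if (a > 0 && object@mbf < K1 - 1e-9)
      return("mbf must be >= K1 when extraction < 1")
  }
  TRUE
})

#' Tofts fit result
#'
#' @slot params [ToftsParams] fitted (Ktrans, kep, t0).
#' @slot mbf numeric, Ktrans / extraction fraction, ml/min/g.
#' @slot extractionFraction numeric, the assumed extraction fraction.
#' @slot residualNorm numeric, residual sum of squares.
#' @export
setClass("ToftsFitResult",
  representation(params = "ToftsParams", mbf = "numeric",
                 extractionFraction = "numeric", residualNorm = "numeric")
)

# ---- constructors ---------------------------------------------------------

#' Construct a TimeCurve
#'
#' @param times numeric vector of sample times (s), strictly increasing.
#' @param values numeric vector of the same length.
#' @param durations optional numeric vector of frame durations (s).
#' @return A [TimeCurve-class] object.
#' @examples
#' tc <- TimeCurve(times = c(5, 15, 25), values = c(0, 10, 4),
#'                 durations = c(10, 10, 10))
#' @export
TimeCurve <- function(times, values, durations = numeric(0)) {
  new("TimeCurve", times = as.numeric(times), values = as.numeric(values),
      durations = as.numeric(durations))
}

#' Construct one-tissue-compartment parameters
#' @param K1 uptake rate, ml/min/g.
#' @param k2 clearance rate, 1/min.
#' @return An [OneTissueParams-class] object.
#' @export
OneTissueParams <- function(K1, k2) new("OneTissueParams", K1 = K1, k2 = k2)

#' Construct Renkin-Crone parameters
#' @param a unitless, in [0,1); 0 gives the identity K1 = MBF.
#' @param b (ml/min/g)^-1, >= 0.
#' @return A [RenkinCroneParams-class] object.
#' @export
RenkinCroneParams <- function(a = 0, b = 0) new("RenkinCroneParams", a = a, b = b)

#' Construct Tofts parameters
#' @param Ktrans transfer constant, ml/min/g.
#' @param kep efflux rate, 1/min.
#' @param t0 bolus-arrival delay, seconds.
#' @return A [ToftsParams-class] object.
#' @export
ToftsParams <- function(Ktrans, kep, t0 = 0)
  new("ToftsParams", Ktrans = Ktrans, kep = kep, t0 = t0)

#' Construct a gamma-variate bolus parameter set
#' @param onset bolus arrival time, seconds.
#' @param amplitude peak value.
#' @param alpha shape (> 0).
#' @param beta time-to-peak scale, seconds (> 0).
#' @param recircFraction recirculation amplitude fraction, in [0,1).
#' @return A [GammaVariateAIF-class] object.
#' @export
GammaVariateAIF <- function(onset = 0, amplitude = 1, alpha = 3, beta = 6,
                            recircFraction = 0)
  new("GammaVariateAIF", onset = onset, amplitude = amplitude, alpha = alpha,
      beta = beta, recircFraction = recircFraction)

#' Construct a fractionated dose scheme
#' @param nFractions number of fractions (positive integer).
#' @param dosePerFraction dose per fraction, Gy.
#' @param alphaBeta linear-quadratic alpha/beta ratio, Gy (default 2.5,
#'   the late-responding cardiac value used here).
#' @return A [DoseScheme-class] object.
#' @examples
#' DoseScheme(25, 30 / 25)        # ~30 Gy in 25 fractions
#' @export
DoseScheme <- function(nFractions, dosePerFraction, alphaBeta = 2.5)
  new("DoseScheme", nFractions = nFractions,
      dosePerFraction = dosePerFraction, alphaBeta = alphaBeta)

# ---- show methods ---------------------------------------------------------

setMethod("show", "TimeCurve", function(object) {
  n <- length(object@times)
  cat("TimeCurve with", n, "samples")
  if (length(object@durations)) cat(" (frame-binned)")
  if (n) {
    cat("\n  time range: [", format(min(object@times)), ",",
        format(max(object@times)), "] s\n", sep = " ")
    cat("  value range: [", format(min(object@values)), ",",
        format(max(object@values)), "]\n", sep = " ")
  } else cat("\n")
  invisible(NULL)
})

setMethod("show", "FrameSchedule", function(object) {
  cat("FrameSchedule:", length(object@durations), "frames, total",
      sum(object@durations), "s\n")
  rl <- rle(object@durations)
  cat("  ", paste(sprintf("%dx%gs", rl$lengths, rl$values),
                  collapse = ", "), "\n", sep = "")
  invisible(NULL)
})

setMethod("show", "SegmentModel", function(object) {
  cat("SegmentModel (16 segments):\n")
  for (tr in .TERRITORIES) {
    segs <- sort(as.integer(names(object@territories)[
      object@territories == tr]))
    cat(sprintf("  %-4s: %s\n", tr, paste(segs, collapse = ", ")))
  }
  invisible(NULL)
})

setMethod("show", "DualBolusAcquisition", function(object) {
  cat("DualBolusAcquisition\n")
  cat(sprintf("  bolus ratio 1:%g, inter-bolus delay %g s\n",
              object@bolusRatio, object@interBolusDelay))
  cat(sprintf("  injections at %g s (small) and %g s (large)\n",
              object@smallInjectionTime, object@largeInjectionTime))
  cat(sprintf("  tissue curves: %d (small pass), %d (large pass)\n",
              length(object@smallTissue), length(object@largeTissue)))
  invisible(NULL)
})

setMethod("show", "PETFitResult", function(object) {
  cat("One-tissue-compartment fit\n")
  cat(sprintf("  K1 = %.4f ml/min/g, k2 = %.4f /min\n",
              object@params@K1, object@params@k2))
  cat(sprintf("  MBF = %.4f ml/min/g (Renkin-Crone a = %g, b = %g)\n",
              object@mbf, object@rcParams@a, object@rcParams@b))
  cat(sprintf("  weighted RSS = %.4g over window 0-%g s\n",
              object@residualNorm, object@fitWindow))
  invisible(NULL)
})

setMethod("show", "ToftsFitResult", function(object) {
  cat("Tofts model fit\n")
  cat(sprintf("  Ktrans = %.4f ml/min/g, kep = %.4f /min, t0 = %.2f s\n",
              object@params@Ktrans, object@params@kep, object@params@t0))
  cat(sprintf("  MBF = %.4f ml/min/g (extraction fraction %.2f)\n",
              object@mbf, object@extractionFraction))
  cat(sprintf("  RSS = %.4g\n", object@residualNorm))
  invisible(NULL)
})
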
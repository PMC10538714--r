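#' @include AllClasses.R convolution.R pet-kinetics.R
NULL

#' Detect bolus arrival on a signal-intensity curve
#'
#' The onset is the first sample exceeding the pre-injection baseline mean
#' by \code{nSd} baseline standard deviations (for noise-free baselines a
#' small absolute guard of 1e-9 times the curve maximum is used instead of
#' the zero SD).
#'
#' @param curve a [TimeCurve-class].
#' @param baselineEnd seconds; samples strictly before this time form the
#'   baseline window.
#' @param nSd threshold in baseline standard deviations (default 5).
#' @return list with \code{onset} (time, s), \code{baselineMean},
#'   \code{baselineSd}.
#' @export
detectBolusOnset <- function(curve, baselineEnd, nSd = 5) {
  stopifnot(is(curve, "TimeCurve"))
  base <- curve@values[curve@times < baselineEnd]
  if (!length(base))
    stop("empty pre-injection baseline window")
  m <- mean(base)
  s <- stats::sd(base)
  if (!is.finite(s)) s <- 0
  thr <- m + max(nSd * s, 1e-9 * max(abs(curve@values), 1e-12))
  idx <- which(curve@values > thr & curve@times >= baselineEnd)
  if (!length(idx))
    stop("no detectable bolus peak above baseline")
  list(onset = curve@times[idx[1L]], baselineMean = m, baselineSd = s)
}

#' Construct the dual-bolus arterial input function
#'
#' Implements the dual-bolus AIF construction: the low-dose (small-bolus)
#' arterial curve is baseline-subtracted (mean of its pre-injection
#' window), magnified by the bolus volume ratio (10 by default), shifted
#' forward by the inter-bolus delay so that its onset coincides with the
#' high-dose injection, and truncated/resampled onto the high-dose
#' acquisition window. The result is the unsaturated arterial input, in
#' whole-blood signal units, to pair with the high-dose tissue curves.
#' Outside the shifted small-curve support the AIF is zero (the
#' first-pass bolus has decayed to well under 1\% of its mass there).
#'
#' @param acq a [DualBolusAcquisition-class].
#' @param shift \code{"delay"} (default) shifts by the nominal inter-bolus
#'   delay; \code{"none"} applies no shift (for acquisitions whose clocks
#'   are already aligned).
#' @param baselineTolerance warn when the post-subtraction baseline of the
#'   small curve is more negative than this fraction of its peak
#'   (default 0.05).
#' @return A [TimeCurve-class] on the high-dose window's time grid.
#' @export
buildDualBolusAIF <- function(acq, shift = c("delay", "none"),
                              baselineTolerance = 0.05) {
  stopifnot(is(acq, "DualBolusAcquisition"))
  shift <- match.arg(shift)
  small <- acq@smallAIF
  # onset must be detectable; errors here are QC failures
  detectBolusOnset(small, baselineEnd = acq@smallInjectionTime)
  pre <- small@times < acq@smallInjectionTime
  base <- mean(small@values[pre])
  baseSd <- stats::sd(small@values[pre])
  if (!is.finite(baseSd)) baseSd <- 0
  corrected <- small@values - base
  peak <- max(corrected)
  # systematic negative baseline (beyond what the noise level explains)
  if (stats::quantile(corrected[pre], 0.25) <
      -max(baselineTolerance * peak, 3 * baseSd))
    warning("small-bolus baseline subtraction leaves a systematically ",
            "negative baseline; check the baseline window")
  dt <- if (shift == "delay") acq@interBolusDelay else 0
  shiftedTimes <- small@times + dt
  outTimes <- acq@largeAIF@times
  vals <- stats::approx(shiftedTimes, corrected * acq@bolusRatio,
                        xout = outTimes, yleft = 0, yright = 0)$y
  TimeCurve(times = outTimes, values = vals)
}

#' Whole-blood to plasma correction
#'
#' Converts a whole-blood concentration curve to plasma concentration:
#' \eqn{C_p(t) = C_b(t) / (1 - Hct)} with an assumed hematocrit
#' (default 0.45).
#'
#' @param curve a [TimeCurve-class] in whole-blood units.
#' @param hematocrit numeric in [0, 1).
#' @return A [TimeCurve-class] in plasma units.
#' @examples
#' tc <- TimeCurve(0:3, c(0, 1, 2, 1))
#' curveValues(plasmaCorrect(tc))  # divided by 0.55
#' @export
plasmaCorrect <- function(curve, hematocrit = 0.45) {
  stopifnot(is(curve, "TimeCurve"))
  if (!is.finite(hematocrit) || hematocrit < 0 || hematocrit >= 1)
    stop("'hematocrit' must lie in [0, 1)")
  TimeCurve(times = curve@times, values = curve@values / (1 - hematocrit),
            durations = curve@durations)
}

#' Tofts model forward curve
#'
#' Predicts the tissue contrast curve
#' \deqn{C_t(t) = K^{trans} \int_0^{t - t_0} C_p(\tau)
#'   e^{-k_{ep}(t - t_0 - \tau)} d\tau,}
#' i.e. the plasma curve convolved with \eqn{K^{trans} e^{-k_{ep} s}} and
#' onset-shifted by t0. Shares the exact piecewise-linear exponential
#' convolution engine with [oneTissueForward()]; with \code{t0 = 0} the two
#' models coincide for (Ktrans, kep) = (K1, k2).
#'
#' @param params a [ToftsParams-class].
#' @param cp [TimeCurve-class], the plasma input curve.
#' @param evalTimes numeric, seconds.
#' @return A [TimeCurve-class].
#' @export
toftsForward <- function(params, cp, evalTimes) {
  stopifnot(is(params, "ToftsParams"), is(cp, "TimeCurve"))
  validObject(params)
  s <- evalTimes - params@t0
  t1 <- cp@times[1L]
  vals <- numeric(length(s))
  ok <- s >= t1
  if (any(s > cp@times[length(cp@times)] + 1e-9))
    stop("evaluation time beyond the plasma curve after the t0 shift")
  if (any(ok))
    vals[ok] <- params@Ktrans / 60 *
      .expConvolve(cp@times, cp@values, params@kep / 60, s[ok])
  TimeCurve(times = evalTimes, values = vals)
}

#' Fit the Tofts model to a tissue curve
#'
#' Least-squares estimation of (Ktrans, kep, t0) given a tissue curve and
#' a plasma input curve. t0 is initialized at \code{onsetInit} (default 0,
#' i.e. the plasma curve's own onset) and constrained within +/- 10 s of
#' it (never below 0); (Ktrans, kep) use the same physiologic-range
#' multi-start grid as the one-tissue fit.
#'
#' @param tissue [TimeCurve-class], observed tissue curve.
#' @param cp [TimeCurve-class], plasma input.
#' @param onsetInit initial t0 in seconds (default 0).
#' @param extractionFraction extraction fraction used to convert the fitted
#'   Ktrans to MBF (default 0.5).
#' @return A [ToftsFitResult-class].
#' @export
fitTofts <- function(tissue, cp, onsetInit = 0, extractionFraction = 0.5) {
  stopifnot(is(tissue, "TimeCurve"), is(cp, "TimeCurve"))
  nAfter <- sum(tissue@times >= cp@times[1L])
  if (nAfter < 5L)
    stop("need at least 5 tissue samples after the plasma-curve onset")
  obs <- tissue@values
  tt <- tissue@times

  if (all(abs(obs) < .Machine$double.eps^0.5)) {
    warning("tissue curve is identically zero; returning Ktrans = 0")
    return(new("ToftsFitResult", params = ToftsParams(0, 0, 0),
               mbf = 0, extractionFraction = extractionFraction,
               residualNorm = 0))
  }

  t0lo <- max(0, onsetInit - 10)
  t0hi <- onsetInit + 10
  cpT <- cp@times; cpV <- cp@values
  obj <- function(p) {
    # inlined toftsForward (avoids per-evaluation object construction)
    s <- tt - p[3L]
    ok <- s >= cpT[1L]
    m <- numeric(length(s))
    if (any(ok))
      m[ok] <- p[1L] / 60 * .expConvolve(cpT, cpV, p[2L] / 60, s[ok])
    r <- m - obs
    sum(r * r)
  }
  starts <- expand.grid(Ktrans = c(0.2, 0.8, 2.0), kep = c(0.1, 0.5, 2.0),
                        t0 = max(onsetInit, t0lo))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(stats::optim(as.numeric(starts[i, ]), obj,
                            method = "L-BFGS-B",
                            lower = c(0, 0, t0lo), upper = c(20, 20, t0hi),
                            control = list(factr = 1e4, maxit = 500)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("Tofts fit did not converge from any start: ",
         "input appears unidentifiable")
  params <- ToftsParams(best$par[1L], best$par[2L], best$par[3L])
  new("ToftsFitResult", params = params,
      mbf = mbfFromKtrans(params@Ktrans, extractionFraction),
      extractionFraction = extractionFraction,
      residualNorm = best$value)
}

#' Convert Ktrans to MBF via the extraction fraction
#'
#' \eqn{MBF = K^{trans} / EF}, with EF the first-pass extraction fraction
#' of the contrast agent (0.5 for Gd-DTPA in normal canine myocardium).
#'
#' @param Ktrans transfer constant, ml/min/g, >= 0 (vectorized).
#' @param extractionFraction numeric in (0, 1].
#' @return MBF in ml/min/g.
#' @examples
#' mbfFromKtrans(0.5)        # 1.0 with the default EF of 0.5
#' @export
mbfFromKtrans <- function(Ktrans, extractionFraction = 0.5) {
  if (!is.finite(extractionFraction) || extractionFraction <= 0 ||
      extractionFraction > 1)
    stop("'extractionFraction' must lie in (0, 1]")
  if (any(!is.finite(Ktrans)) || any(Ktrans < 0))
    stop("'Ktrans' must be finite and >= 0")
  Ktrans / extractionFraction
}

#' Back-calculate the extraction fraction from paired measurements
#'
#' Given a DCE-derived Ktrans and an independently measured (ammonia PET)
#' MBF of the same territory, the implied extraction fraction is
#' \eqn{EF = K^{trans} / MBF}. Non-positive or missing MBF yields NA with
#' a warning (flagged missing).
#'
#' @param ktransDce numeric, ml/min/g (vectorized).
#' @param mbfNh3 numeric, ml/min/g (vectorized).
#' @return numeric EF estimates; NA where MBF <= 0 or missing.
#' @export
extractionFractionFromPair <- function(ktransDce, mbfNh3) {
  out <- ktransDce / mbfNh3
  bad <- !is.finite(mbfNh3) | mbfNh3 <= 0
  if (any(bad)) {
    warning(sum(bad), " pair(s) with non-positive or missing MBF ",
            "flagged as missing")
    out[bad] <- NA_real_
  }
  out
}

#' Run the full dual-bolus DCE quantification
#'
#' Chains the DCE stages on one acquisition: dual-bolus AIF construction
#' ([buildDualBolusAIF()]), plasma correction ([plasmaCorrect()]), Tofts
#' fitting of every high-dose tissue curve ([fitTofts()]) and Ktrans to
#' MBF conversion ([mbfFromKtrans()]).
#'
#' @param acq a [DualBolusAcquisition-class].
#' @param hematocrit assumed blood hematocrit (default 0.45).
#' @param extractionFraction assumed extraction fraction (default 0.5).
#' @return list with elements \code{aif} (stitched blood AIF), \code{cp}
#'   (plasma curve) and \code{fits} (named list of
#'   [ToftsFitResult-class], one per tissue curve).
#' @export
quantifyDCE <- function(acq, hematocrit = 0.45, extractionFraction = 0.5) {
  stopifnot(is(acq, "DualBolusAcquisition"))
  aif <- buildDualBolusAIF(acq)
  cp <- plasmaCorrect(aif, hematocrit)
  fits <- lapply(acq@largeTissue, fitTofts, cp = cp,
                 extractionFraction = extractionFraction)
  list(aif = aif, cp = cp, fits = fits)
}
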
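#' @include AllClasses.R convolution.R
NULL

# raw gamma-variate shape, peak value `amplitude` at onset + beta
.gammaShape <- function(t, onset, amplitude, alpha, beta) {
  dt <- t - onset
  out <- numeric(length(t))
  pos <- dt > 0
  x <- dt[pos] / beta
  out[pos] <- amplitude * x^alpha * exp(alpha * (1 - x))
  out
}

#' Evaluate a gamma-variate bolus curve
#'
#' Samples the first-pass gamma-variate bolus (and, when
#' \code{recircFraction > 0}, a delayed, broadened recirculation bump —
#' same shape, onset shifted by \eqn{2\beta}, scale \eqn{2\beta}, amplitude
#' \code{recircFraction} times the first-pass peak) at the given times.
#' The curve is identically zero before onset and non-negative everywhere.
#'
#' @param params a [GammaVariateAIF-class].
#' @param times numeric vector of sample times (s), all >= 0.
#' @return A [TimeCurve-class].
#' @examples
#' aif <- GammaVariateAIF(onset = 10, amplitude = 5, alpha = 3, beta = 6)
#' tc <- gammaVariateAIF(aif, seq(0, 60, by = 0.5))
#' max(curveValues(tc))   # ~5, at ~16 s
#' @export
gammaVariateAIF <- function(params, times) {
  stopifnot(is(params, "GammaVariateAIF"))
  if (any(times < 0)) stop("sample times must be >= 0")
  validObject(params)
  v <- .gammaShape(times, params@onset, params@amplitude,
                   params@alpha, params@beta)
  if (params@recircFraction > 0) {
    v <- v + .gammaShape(times, params@onset + 2 * params@beta,
                         params@recircFraction * params@amplitude,
                         params@alpha, 2 * params@beta)
  }
  TimeCurve(times = times, values = v)
}

# closed-form integral of the first-pass bolus over (onset, Inf):
# A * exp(alpha) * (beta/alpha) * alpha^(-alpha) * Gamma(alpha + 1)
.gammaShapeIntegral <- function(amplitude, alpha, beta) {
  amplitude * exp(alpha + lgamma(alpha + 1) - alpha * log(alpha)) *
    beta / alpha
}
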
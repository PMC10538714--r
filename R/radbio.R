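#' @include AllClasses.R
NULL

#' Biologically effective dose of a fractionated scheme
#'
#' Linear-quadratic BED: \eqn{BED = n d (1 + d / (\alpha/\beta))} for
#' n fractions of d Gy.
#'
#' @param scheme a [DoseScheme-class].
#' @return BED in Gy.
#' @examples
#' bed(DoseScheme(25, 1.2, alphaBeta = 2.5))   # 44.4 Gy
#' @export
bed <- function(scheme) {
  stopifnot(is(scheme, "DoseScheme"))
  validObject(scheme)
  n <- scheme@nFractions; d <- scheme@dosePerFraction
  n * d * (1 + d / scheme@alphaBeta)
}

#' Single-fraction dose equivalent to a fractionated scheme
#'
#' Solves \eqn{d^* (1 + d^*/(\alpha/\beta)) = BED} for the single-fraction
#' dose with the same biologically effective dose, via the positive root
#' \deqn{d^* = \frac{-\alpha/\beta + \sqrt{(\alpha/\beta)^2 +
#'   4 (\alpha/\beta) BED}}{2}.}
#' The cardiac conversion used here takes ~30 Gy in 25 fractions at
#' alpha/beta = 2.5 Gy to ~9 Gy in one fraction.
#'
#' @param scheme a [DoseScheme-class].
#' @return the equivalent single-fraction dose in Gy.
#' @examples
#' equivalentSingleFractionDose(DoseScheme(25, 30 / 25))   # ~9.36 Gy
#' @export
equivalentSingleFractionDose <- function(scheme) {
  ab <- scheme@alphaBeta
  B <- bed(scheme)
  (-ab + sqrt(ab^2 + 4 * ab * B)) / 2
}

#' Rate-pressure product
#'
#' RPP = heart rate x systolic blood pressure, a proxy for myocardial
#' oxygen demand. Vectorized; missing inputs propagate to missing RPP.
#'
#' @param heartRate bpm, > 0.
#' @param systolicBP mmHg, > 0.
#' @return RPP in bpm x mmHg.
#' @examples
#' ratePressureProduct(80, 120)   # 9600
#' @export
ratePressureProduct <- function(heartRate, systolicBP) {
  if (any(heartRate <= 0, na.rm = TRUE) ||
      any(systolicBP <= 0, na.rm = TRUE))
    stop("heart rate and systolic blood pressure must be > 0")
  heartRate * systolicBP
}
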
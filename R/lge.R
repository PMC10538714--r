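#' @include AllClasses.R
NULL

#' Late-gadolinium-enhancement threshold mask
#'
#' Detects focal enhancement by the signal-threshold-versus-reference-
#' myocardium technique: pixels whose intensity strictly exceeds
#' mean + nSd x SD of a reference (remote, non-irradiated) myocardial
#' region are flagged as enhanced. The default of 5 SDs is the
#' conventional conservative scar threshold; enhancement is one-sided
#' (only hyperintense pixels count).
#'
#' @param image numeric matrix of signal intensities.
#' @param referenceMask logical matrix of reference-region pixels
#'   (>= 2 pixels required).
#' @param nSd threshold in reference SDs above the reference mean
#'   (default 5).
#' @return list with \code{mask} (logical matrix), \code{threshold},
#'   \code{enhancedCount} and \code{enhancedFraction} (fraction of all
#'   image pixels).
#' @examples
#' im <- simulateLGEImage(seed = 1)
#' lgeThresholdMask(im$image, im$referenceMask)$enhancedCount
#' @export
lgeThresholdMask <- function(image, referenceMask, nSd = 5) {
  stopifnot(is.matrix(image), is.logical(referenceMask),
            identical(dim(image), dim(referenceMask)))
  if (nSd < 0) stop("'nSd' must be >= 0")
  ref <- image[referenceMask]
  if (length(ref) < 2L)
    stop("reference region must contain at least 2 pixels")
  thr <- mean(ref) + nSd * stats::sd(ref)
  mask <- image > thr
  if (stats::sd(ref) == 0 && !any(mask))
    warning("zero-variance reference region and no pixel above its mean; ",
            "empty enhancement mask")
  list(mask = mask, threshold = thr,
       enhancedCount = sum(mask),
       enhancedFraction = mean(mask))
}
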
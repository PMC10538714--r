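#' @include AllClasses.R convolution.R curves.R
NULL

#' One-tissue-compartment forward model
#'
#' Computes the myocardial tissue curve predicted by the one-tissue
#' compartment model,
#' \deqn{C_t(t) = K_1 \int_0^t C_{LV}(\tau) e^{-k_2 (t-\tau)} d\tau,}
#' with K1 in ml/min/g and k2 in 1/min acting on a seconds time grid
#' (the per-minute rates are converted internally). The arterial curve is
#' interpolated piecewise-linearly and the convolution is evaluated in
#' closed form on each linear segment, so the result is exact for the
#' interpolant.
#'
#' @param params an [OneTissueParams-class].
#' @param lvCurve [TimeCurve-class], the LV blood-pool (arterial) input.
#' @param evalTimes numeric, seconds; must lie within the span of
#'   \code{lvCurve}.
#' @return A [TimeCurve-class] of model tissue concentrations at
#'   \code{evalTimes}.
#' @examples
#' aif <- gammaVariateAIF(GammaVariateAIF(onset = 5, amplitude = 40),
#'                        seq(0, 300, by = 0.5))
#' ct <- oneTissueForward(OneTissueParams(K1 = 0.8, k2 = 0.4), aif,
#'                        seq(0, 300, by = 5))
#' @export
oneTissueForward <- function(params, lvCurve, evalTimes) {
  stopifnot(is(params, "OneTissueParams"), is(lvCurve, "TimeCurve"))
  validObject(params)
  conv <- .expConvolve(lvCurve@times, lvCurve@values,
                       k = params@k2 / 60, evalTimes = evalTimes)
  TimeCurve(times = evalTimes, values = params@K1 / 60 * conv)
}

#' Renkin-Crone conversion: flow to uptake constant
#'
#' \eqn{K_1 = (1 - a e^{-b \cdot MBF}) \cdot MBF}. With \code{a = 0}
#' (the default resting-ammonia approximation, extraction ~ 1 below
#' 6 ml/min/g) this is the identity.
#'
#' @param mbf myocardial blood flow, ml/min/g, >= 0 (vectorized).
#' @param rc a [RenkinCroneParams-class].
#' @return K1 in ml/min/g.
#' @examples
#' renkinCroneK1(2, RenkinCroneParams(a = 0.5, b = 1))
#' @export
renkinCroneK1 <- function(mbf, rc = RenkinCroneParams()) {
  stopifnot(is(rc, "RenkinCroneParams"))
  validObject(rc)
  if (any(!is.finite(mbf)) || any(mbf < 0))
    stop("'mbf' must be finite and >= 0")
  (1 - rc@a * exp(-rc@b * mbf)) * mbf
}

#' Renkin-Crone inversion: uptake constant to flow
#'
#' Solves \eqn{K_1 = (1 - a e^{-b \cdot MBF}) \cdot MBF} for MBF.
#' The relation is strictly increasing for valid (a, b), so the root is
#' unique; it is bracketed in \code{[k1, k1/(1-a)]} and found by bisection
#' to an absolute tolerance of 1e-9. With \code{a = 0} the input is
#' returned unchanged.
#'
#' @param k1 uptake constant, ml/min/g, >= 0 (vectorized).
#' @param rc a [RenkinCroneParams-class].
#' @param tol bisection tolerance on MBF, ml/min/g.
#' @return MBF in ml/min/g.
#' @export
mbfFromK1 <- function(k1, rc = RenkinCroneParams(), tol = 1e-9) {
  stopifnot(is(rc, "RenkinCroneParams"))
  validObject(rc)
  if (any(!is.finite(k1)) || any(k1 < 0))
    stop("'k1' must be finite and >= 0")
  if (rc@a == 0) return(k1)
  vapply(k1, function(k) {
    if (k == 0) return(0)
    lo <- k; hi <- k / (1 - rc@a)
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (renkinCroneK1(mid, rc) < k) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

# Frame-averaged model evaluation: Simpson rule with 4 subintervals per
# frame, equivalent to evaluating the convolution at 5 nodes per frame.
.frameAveragedModel <- function(evalFun, mids, durs) {
  offs <- c(-0.5, -0.25, 0, 0.25, 0.5)
  nodes <- rep(mids, each = 5L) + rep(offs, times = length(mids)) *
    rep(durs, each = 5L)
  v <- evalFun(nodes)
  w <- c(1, 4, 2, 4, 1) / 12
  colSums(matrix(v, nrow = 5L) * w)
}

#' Fit the one-tissue model by weighted least squares
#'
#' Estimates (K1, k2) from a frame-binned tissue curve and an arterial
#' (LV blood-pool) curve by minimizing the weighted residual sum of squares
#' over the frames whose timestamps fall within the fit window (first
#' 4 minutes by default). Default weights are the frame durations; uniform
#' or user-supplied weights are accepted. When frame durations are present
#' the model is averaged within each frame (Simpson rule) to match binned
#' data; otherwise it is sampled at the frame timestamps. Optimization is
#' box-constrained (both rates >= 0) L-BFGS-B from a multi-start grid
#' K1 in \{0.2, 0.8, 2.0\} ml/min/g x k2 in \{0.1, 0.5, 2.0\} /min covering
#' the physiologic range. The fitted K1 is converted to MBF via
#' [mbfFromK1()].
#'
#' @param tissue [TimeCurve-class], observed tissue curve (frame-binned).
#' @param lv [TimeCurve-class], arterial input curve.
#' @param weights optional numeric per-frame weights (>= 0); default frame
#'   durations (or uniform when the tissue curve has no durations).
#' @param fitWindow seconds; frames with timestamp <= \code{fitWindow} are
#'   fitted (default 240 s).
#' @param rc [RenkinCroneParams-class] for the K1 -> MBF conversion
#'   (default a = 0: K1 = MBF).
#' @param frameAveraged logical; average the model within frames when
#'   durations are available (default TRUE).
#' @return A [PETFitResult-class].
#' @export
fitOneTissue <- function(tissue, lv, weights = NULL, fitWindow = 240,
                         rc = RenkinCroneParams(), frameAveraged = TRUE) {
  stopifnot(is(tissue, "TimeCurve"), is(lv, "TimeCurve"))
  inWin <- tissue@times <= fitWindow
  if (sum(inWin) < 4L)
    stop("need at least 4 frames inside the fit window")
  tt <- tissue@times[inWin]
  obs <- tissue@values[inWin]
  durs <- if (length(tissue@durations)) tissue@durations[inWin] else NULL
  if (is.null(weights)) {
    weights <- if (is.null(durs)) rep(1, length(tt)) else durs
  } else {
    weights <- weights[inWin]
  }
  if (any(weights < 0)) stop("weights must be >= 0")

  useAvg <- frameAveraged && !is.null(durs)
  # a frame-binned LV curve starts at the first frame midpoint; anchor the
  # interpolant at (0, 0) — blood activity is zero at acquisition start
  lvT <- lv@times; lvV <- lv@values
  if (lvT[1L] > 0) { lvT <- c(0, lvT); lvV <- c(0, lvV) }
  # the convolution only needs the input up to the last fitted node
  tmax <- max(tt) + (if (is.null(durs)) 0 else max(durs))
  keep <- seq_len(min(length(lvT), findInterval(tmax, lvT) + 1L))
  lvT <- lvT[keep]; lvV <- lvV[keep]
  modelVals <- function(K1, k2) {
    f <- function(times) .expConvolve(lvT, lvV, k2 / 60, times)
    conv <- if (useAvg) .frameAveragedModel(f, tt, durs) else f(tt)
    K1 / 60 * conv
  }

  if (all(abs(obs) < .Machine$double.eps^0.5)) {
    warning("tissue curve is identically zero; returning K1 = 0")
    params <- OneTissueParams(0, 0)
    return(new("PETFitResult", params = params, mbf = 0, residualNorm = 0,
               weights = weights, fitWindow = fitWindow, rcParams = rc))
  }

  obj <- function(p) {
    r <- modelVals(p[1L], p[2L]) - obs
    sum(weights * r * r)
  }
  starts <- expand.grid(K1 = c(0.2, 0.8, 2.0), k2 = c(0.1, 0.5, 2.0))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(stats::optim(as.numeric(starts[i, ]), obj,
                            method = "L-BFGS-B",
                            lower = c(0, 0), upper = c(20, 20),
                            control = list(factr = 1e4, maxit = 500)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("one-tissue fit did not converge from any start: ",
         "input appears unidentifiable")
  params <- OneTissueParams(K1 = best$par[1L], k2 = best$par[2L])
  new("PETFitResult", params = params,
      mbf = mbfFromK1(params@K1, rc),
      residualNorm = best$value, weights = weights,
      fitWindow = fitWindow, rcParams = rc)
}
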
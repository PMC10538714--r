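# Independent oracles used across the suite. These deliberately avoid the
# package's own numerical paths: brute-force quadrature for convolutions,
# full enumeration for the exact rank-sum null distribution.

# Riemann-sum convolution of the piecewise-linear interpolant of
# (times, values) with K1 * exp(-k2 * (t - tau)) (rates per minute,
# times in seconds).
bruteForceOneTissue <- function(times, values, K1, k2, evalTimes,
                                dt = 0.01) {
  vapply(evalTimes, function(t) {
    if (t <= times[1L]) return(0)
    tau <- seq(times[1L], t, by = dt)
    v <- stats::approx(times, values, xout = tau)$y
    sum(v * exp(-(k2 / 60) * (t - tau))) * dt * (K1 / 60)
  }, numeric(1))
}

# frame average of a function over each frame of a schedule, by dense
# trapezoidal quadrature
frameAverageOracle <- function(f, schedule, dt = 0.01) {
  starts <- cumsum(c(0, frameDurations(schedule)))
  vapply(seq_along(frameDurations(schedule)), function(i) {
    tt <- seq(starts[i], starts[i + 1L], by = dt)
    v <- f(tt)
    sum((v[-1L] + v[-length(v)]) / 2 * diff(tt)) / (starts[i + 1L] - starts[i])
  }, numeric(1))
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# rank configurations (no ties assumed).
enumerateMannWhitneyP <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  wObs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2   # U statistic of x
  combos <- utils::combn(n + m, n)
  ws <- apply(combos, 2L, function(idx)
    sum(rank(pooled)[idx]) - n * (n + 1) / 2)
  # note: ranks are of the fixed pooled sample; every subset of positions
  # gives one equally likely allocation under H0
  pLow <- mean(ws <= wObs)
  pHigh <- mean(ws >= wObs)
  min(1, 2 * min(pLow, pHigh))
}

# minimal cohort with one territory/modality and given values per timepoint
makeTinyCohort <- function(valuesByTimepoint, territory = "LAD",
                           modality = "NH3") {
  tps <- names(valuesByTimepoint)
  rows <- do.call(rbind, lapply(tps, function(tp) {
    v <- valuesByTimepoint[[tp]]
    if (!length(v)) return(NULL)
    data.frame(animal_id = paste0("A", seq_along(v)), timepoint = tp,
               territory = territory, modality = modality, mbf = v,
               suv = 1, heart_rate = 80, systolic_bp = 120,
               stringsAsFactors = FALSE)
  }))
  rows$timepoint <- factor(rows$timepoint, levels = tps)
  rows
}
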
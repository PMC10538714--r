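test_that("dual-bolus AIF construction amplifies, aligns and truncates", {
  acq <- simulateDualBolus(noiseSd = 0)
  aif <- buildDualBolusAIF(acq)
  expect_equal(max(curveValues(aif)) / max(curveValues(acq@smallAIF)), 10,
               tolerance = 1e-6)
  # stitched onset aligns with the high-dose injection
  tPeak <- curveTimes(aif)[which.max(curveValues(aif))]
  tSmallPeak <- curveTimes(acq@smallAIF)[which.max(
    curveValues(acq@smallAIF))]
  expect_equal(tPeak - tSmallPeak, acq@interBolusDelay)

  # manual oracle on a handcrafted acquisition: ratio x (small - base),
  # shifted by the delay, zero outside the shifted support
  small <- TimeCurve(0:19, c(rep(2, 8), 2 + c(1, 4, 9, 4, 1), rep(2, 7)))
  large <- TimeCurve(20:60, rep(0, 41))
  hand <- new("DualBolusAcquisition", smallAIF = small, largeAIF = large,
              smallTissue = list(), largeTissue = list(), bolusRatio = 4,
              interBolusDelay = 25, preInjectionWindow = 8,
              smallInjectionTime = 8, largeInjectionTime = 33)
  got <- buildDualBolusAIF(hand)
  manual <- stats::approx((0:19) + 25, (curveValues(small) - 2) * 4,
                          xout = 20:60, yleft = 0, yright = 0)$y
  expect_equal(curveValues(got), manual)

  # flat small curve: no detectable bolus
  flat <- new("DualBolusAcquisition",
              smallAIF = TimeCurve(0:19, rep(1, 20)), largeAIF = large,
              smallTissue = list(), largeTissue = list(), bolusRatio = 4,
              interBolusDelay = 25, preInjectionWindow = 8,
              smallInjectionTime = 8, largeInjectionTime = 33)
  expect_error(buildDualBolusAIF(flat), "no detectable bolus")
})

test_that("plasma correction divides by one minus hematocrit", {
  tc <- TimeCurve(0:3, c(0, 1, 2, 1))
  cp <- plasmaCorrect(tc, 0.45)
  expect_equal(curveValues(cp), c(0, 1, 2, 1) / 0.55)
  # implied hematocrit from the ratio
  expect_equal(1 - curveValues(tc)[3] / curveValues(cp)[3], 0.45)
  expect_equal(curveValues(plasmaCorrect(tc, 0)), curveValues(tc))
  twice <- TimeCurve(0:3, 2 * c(0, 1, 2, 1))
  expect_equal(curveValues(plasmaCorrect(twice, 0.45)),
               2 * curveValues(cp))
  expect_error(plasmaCorrect(tc, 1), "hematocrit")
})

test_that("Tofts forward shares the one-tissue kernel", {
  tt <- seq(0, 120, by = 0.1)
  cp <- gammaVariateAIF(GammaVariateAIF(onset = 5, amplitude = 30,
                                        alpha = 3, beta = 4), tt)
  eval <- seq(0, 120, by = 2)

  zero <- toftsForward(ToftsParams(0, 1, 0), cp, eval)
  expect_true(all(curveValues(zero) == 0))

  # t0 = 0 equivalence with the one-tissue model, machine precision
  a <- toftsForward(ToftsParams(0.5, 1.0, 0), cp, eval)
  b <- oneTissueForward(OneTissueParams(0.5, 1.0), cp, eval)
  expect_equal(curveValues(a), curveValues(b), tolerance = 1e-14)

  # brute-force quadrature oracle
  oracle <- bruteForceOneTissue(tt, curveValues(cp), 0.5, 1.0, eval)
  expect_lt(max(abs(curveValues(a) - oracle)) / max(oracle), 1e-3)

  # t0 shifts the response rigidly
  sh <- toftsForward(ToftsParams(0.5, 1.0, 10), cp, eval)
  expect_equal(curveValues(sh)[eval >= 10],
               curveValues(a)[match(eval[eval >= 10] - 10, eval)],
               tolerance = 1e-12)
})

test_that("Tofts fit recovers noise-free parameters end to end", {
  acq <- simulateDualBolus(noiseSd = 0)
  q <- quantifyDCE(acq)
  f <- q$fits$global
  expect_equal(fittedParams(f)@Ktrans, 0.45, tolerance = 0.01)
  expect_equal(fittedParams(f)@kep, 0.8, tolerance = 0.01)
  expect_equal(fittedMBF(f), 0.9, tolerance = 0.02)   # end-to-end 2%

  flat <- TimeCurve(curveTimes(q$cp), rep(0, length(q$cp)))
  expect_warning(fz <- fitTofts(flat, q$cp), "identically zero")
  expect_equal(fittedParams(fz)@Ktrans, 0)
})

test_that("pipeline output is invariant to joint intensity rescaling", {
  base <- simulateDualBolus(noiseSd = 0)
  scaled <- simulateDualBolus(
    aif = GammaVariateAIF(onset = 8, amplitude = 120, alpha = 3, beta = 4),
    noiseSd = 0)
  m1 <- fittedMBF(quantifyDCE(base)$fits$global)
  m2 <- fittedMBF(quantifyDCE(scaled)$fits$global)
  expect_equal(m1, m2, tolerance = 1e-6)
})

test_that("extraction-fraction conversions are exact", {
  expect_equal(mbfFromKtrans(0.5, 0.5), 1.0)
  expect_equal(mbfFromKtrans(0), 0)
  expect_equal(mbfFromKtrans(0.7, 1), 0.7)
  expect_error(mbfFromKtrans(0.5, 0), "extractionFraction")
  expect_error(mbfFromKtrans(-1), "Ktrans")

  expect_equal(extractionFractionFromPair(0.45, 0.9), 0.5)
  expect_equal(extractionFractionFromPair(0.9, 0.9), 1)
  expect_equal(extractionFractionFromPair(0.225, 0.9), 0.25)  # linearity
  expect_warning(out <- extractionFractionFromPair(0.5, 0), "flagged")
  expect_true(is.na(out))
})
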
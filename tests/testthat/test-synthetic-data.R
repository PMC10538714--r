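test_that("gamma-variate bolus has the stated onset, peak and integral", {
  p <- GammaVariateAIF(onset = 10, amplitude = 5, alpha = 3, beta = 6)
  tt <- seq(0, 120, by = 0.01)
  tc <- gammaVariateAIF(p, tt)
  expect_true(all(curveValues(tc)[tt <= 10] == 0))
  expect_true(all(curveValues(tc) >= 0))
  # dense-grid argmax at onset + beta with peak value = amplitude
  expect_equal(tt[which.max(curveValues(tc))], 16, tolerance = 1e-3)
  expect_equal(max(curveValues(tc)), 5, tolerance = 1e-6)

  # quadrature vs closed-form gamma integral (recirculation 0)
  quad <- sum(curveValues(tc)) * 0.01
  closed <- 5 * exp(3) * (6 / 3) * 3^(-3) * gamma(4)
  expect_equal(quad, closed, tolerance = 1e-3)

  expect_error(GammaVariateAIF(alpha = -1), "alpha")
  expect_error(GammaVariateAIF(beta = 0), "beta")
  expect_error(gammaVariateAIF(p, c(-1, 0)), ">= 0")
})

test_that("dual-bolus generator honours ratio, delay and uptake limits", {
  acq <- simulateDualBolus(noiseSd = 0)
  smallPeak <- max(curveValues(acq@smallAIF))
  largePeak <- max(curveValues(acq@largeAIF))
  expect_equal(largePeak / smallPeak, 10, tolerance = 1e-5)

  tSmall <- curveTimes(acq@smallAIF)[which.max(curveValues(acq@smallAIF))]
  tLarge <- curveTimes(acq@largeAIF)[which.max(curveValues(acq@largeAIF))]
  expect_equal(tLarge - tSmall, 25)

  # small AIF is the large bolus shape scaled by 1/ratio (linearity)
  acq2 <- simulateDualBolus(noiseSd = 0, bolusRatio = 5)
  expect_equal(max(curveValues(acq2@largeAIF)) /
                 max(curveValues(acq2@smallAIF)), 5, tolerance = 1e-5)

  flat <- simulateDualBolus(tissueParams = list(g = ToftsParams(0, 0.8, 0)),
                            noiseSd = 0)
  expect_true(all(curveValues(flat@largeTissue$g) == 0))

  expect_error(simulateDualBolus(noiseSd = -1), "noiseSd")
  expect_error(simulateDualBolus(interBolusDelay = 0), "interBolusDelay")
  expect_error(simulateDualBolus(bolusRatio = 1), "bolusRatio")
})

test_that("PET generator matches the frame-averaged model and is seeded", {
  aif <- GammaVariateAIF(onset = 5, amplitude = 40, alpha = 3, beta = 8,
                         recircFraction = 0.15)
  sim <- simulatePET(aif = aif, params = OneTissueParams(0.8, 0.4),
                     noiseFree = TRUE)
  # oracle: brute-force forward model, frame-averaged by dense quadrature
  dense <- seq(0, 600, by = 0.05)
  lv <- gammaVariateAIF(aif, dense)
  ct <- bruteForceOneTissue(dense, curveValues(lv), 0.8, 0.4,
                            seq(0, 600, by = 0.5), dt = 0.05)
  fCt <- stats::approxfun(seq(0, 600, by = 0.5), ct)
  oracle <- frameAverageOracle(fCt, nh3FrameSchedule(), dt = 0.05)
  expect_equal(curveValues(sim$tissue), oracle,
               tolerance = 1e-3)

  a <- simulatePET(seed = 7)
  b <- simulatePET(seed = 7)
  expect_identical(curveValues(a$tissue), curveValues(b$tissue))
  expect_identical(curveValues(a$lv), curveValues(b$lv))
  c <- simulatePET(seed = 8)
  expect_false(identical(curveValues(a$tissue), curveValues(c$tissue)))

  noK1 <- simulatePET(params = OneTissueParams(0, 0.4), seed = 1)
  expect_true(all(curveValues(noK1$tissue) == 0))
})

test_that("degenerate cohort configuration collapses to its means", {
  cfg <- cohortSimConfig(
    baselineMbfSd = 0,
    followupMultipliers = c(baseline = 1, "1wk" = 1, "1mo" = 1, "3mo" = 1,
                            "6mo" = 1, "12mo" = 1),
    suvBaselineSd = 0, suvFollowupSd = 0, mbfSuvCorrelation = 0,
    rppCv = 0, dceNoiseCv = 0, seed = 1)
  coh <- simulateCohort(cfg)
  expect_true(all(coh$mbf == 0.9))
  expect_equal(sort(unique(coh$suv)), c(1.1, 2.6))
  expect_true(all(coh$heart_rate == 80))
  expect_equal(nrow(coh), 5 * 6 * 3 * 2)
})

test_that("zero target correlation yields near-zero sample correlation", {
  # time-flat configuration so the latent coupling is the only possible
  # source of correlation
  cfg <- cohortSimConfig(
    nAnimals = 300,
    followupMultipliers = c(baseline = 1, "1wk" = 1, "1mo" = 1, "3mo" = 1,
                            "6mo" = 1, "12mo" = 1),
    suvFollowupMean = 1.1, suvFollowupSd = 0.03,
    mbfSuvCorrelation = 0, seed = 5)
  coh <- simulateCohort(cfg)
  g <- cohortWholeMyocardium(coh)
  g <- g[g$modality == "NH3", ]
  r <- stats::cor(g$mbf, g$suv)
  expect_lt(abs(r), 3 / sqrt(nrow(g)))    # within 3 SE of zero
})

test_that("the 3-month null effect gives a nominal rejection rate", {
  rejected <- vapply(1:200, function(s) {
    coh <- simulateCohort(cohortSimConfig(seed = s))
    mw <- mannWhitneyVsBaseline(coh, "GLOBAL", "NH3", "3mo")
    mw$p < 0.05
  }, logical(1))
  expect_lt(mean(rejected), 0.10)   # ~alpha given the discrete exact null
})

test_that("cohort generation is deterministic given a seed", {
  a <- simulateCohort(cohortSimConfig(seed = 3))
  b <- simulateCohort(cohortSimConfig(seed = 3))
  expect_identical(a, b)
})

test_that("LGE toy image matches its construction", {
  im0 <- simulateLGEImage(seed = 2)
  thr0 <- lgeThresholdMask(im0$image, im0$referenceMask)
  expect_equal(thr0$enhancedCount, 0)   # P(Z > 5) ~ 3e-7 per pixel

  lesion <- matrix(FALSE, 64, 64); lesion[30:40, 40:50] <- TRUE
  im <- simulateLGEImage(lesionMask = lesion, lesionDelta = 100,
                         refSd = 10, seed = 2)
  thr <- lgeThresholdMask(im$image, im$referenceMask)
  expect_true(all(thr$mask[lesion]))    # +10 SD clears the +5 SD threshold

  im2 <- simulateLGEImage(lesionMask = lesion, lesionDelta = 100,
                          refSd = 10, seed = 2)
  expect_identical(im$image, im2$image)
  expect_error(simulateLGEImage(lesionDelta = -1), "lesionDelta")
})
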
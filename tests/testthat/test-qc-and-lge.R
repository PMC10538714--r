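test_that("QC fixtures are classified as constructed", {
  clean <- qcReport(makeQCFixtures("clean", seed = 1))
  expect_false(clean$excluded)
  expect_true(all(clean$checks))

  resid <- qcReport(makeQCFixtures("residual_contrast", seed = 1))
  expect_true(resid$excluded)
  expect_false(resid$checks[["residual_contrast"]])
  expect_true(resid$checks[["reversed_order"]])

  rev <- qcReport(makeQCFixtures("reversed_order", seed = 1))
  expect_true(rev$excluded)
  expect_false(rev$checks[["reversed_order"]])

  expect_error(makeQCFixtures("bogus"), "arg")
})

# handcrafted acquisition with controllable baselines and peaks
.handAcq <- function(preLargeBase, smallPeak = 4, largePeak = 40) {
  smallV <- c(rep(0, 8), 0, smallPeak, smallPeak / 2, rep(0, 9))
  largeV <- c(rep(preLargeBase, 8), preLargeBase + largePeak,
              preLargeBase + largePeak / 2, rep(preLargeBase, 21))
  new("DualBolusAcquisition",
      smallAIF = TimeCurve(0:19, smallV),
      largeAIF = TimeCurve(20:50, largeV),
      smallTissue = list(), largeTissue = list(), bolusRatio = 10,
      interBolusDelay = 20, preInjectionWindow = 8,
      smallInjectionTime = 8, largeInjectionTime = 28)
}

test_that("residual-contrast detector applies a strict-inequality rule", {
  atThreshold <- .handAcq(preLargeBase = 0.4)   # metric exactly 0.1
  r <- detectResidualContrast(atThreshold, threshold = 0.1)
  expect_true(r$pass)
  expect_equal(r$metric, 0.1)
  above <- .handAcq(preLargeBase = 0.44)
  expect_false(detectResidualContrast(above, threshold = 0.1)$pass)
})

test_that("reversed-bolus detector compares pass peaks with tie rule", {
  ok <- .handAcq(0)
  expect_true(detectReversedBolus(ok)$pass)
  eq <- .handAcq(0, smallPeak = 40, largePeak = 40)
  expect_warning(r <- detectReversedBolus(eq), "ambiguous")
  expect_true(r$pass)
  single <- .handAcq(0, largePeak = 0)
  expect_error(detectReversedBolus(single), "two bolus passes")
})

test_that("QC decisions are invariant to global intensity scaling", {
  scaleAcq <- function(acq, f) {
    acq@smallAIF <- TimeCurve(curveTimes(acq@smallAIF),
                              f * curveValues(acq@smallAIF))
    acq@largeAIF <- TimeCurve(curveTimes(acq@largeAIF),
                              f * curveValues(acq@largeAIF))
    acq
  }
  for (kind in c("clean", "residual_contrast", "reversed_order")) {
    acq <- makeQCFixtures(kind, seed = 4)
    a <- qcReport(acq)
    b <- qcReport(scaleAcq(acq, 7.3))
    expect_identical(a$checks, b$checks)
    expect_equal(a$metrics, b$metrics, tolerance = 1e-12)
  }
})

test_that("clean noisy fixtures are rarely excluded", {
  excl <- vapply(1:100, function(s)
    qcReport(makeQCFixtures("clean", seed = s))$excluded, logical(1))
  expect_lte(mean(excl), 0.01)
})

test_that("LGE threshold flags exactly the pixels above mean + n SD", {
  img <- matrix(100, 8, 8)
  ref <- matrix(FALSE, 8, 8); ref[, 1:2] <- TRUE
  img[ref] <- rep(c(90, 110), 8)            # known reference distribution
  img[5, 7] <- 200                          # lesion pixel
  res <- lgeThresholdMask(img, ref, nSd = 5)
  thrManual <- mean(img[ref]) + 5 * stats::sd(img[ref])
  expect_equal(res$threshold, thrManual)
  expect_identical(res$mask, img > thrManual)
  expect_equal(res$enhancedCount, sum(img > thrManual))
  expect_true(res$mask[5, 7])

  # nSd = 0 thresholds at the reference mean
  res0 <- lgeThresholdMask(img, ref, nSd = 0)
  expect_equal(res0$threshold, mean(img[ref]))

  # uniform image: zero-variance reference, empty mask with warning
  uni <- matrix(50, 8, 8)
  expect_warning(resU <- lgeThresholdMask(uni, ref), "zero-variance")
  expect_equal(resU$enhancedCount, 0)

  # enhanced fraction is monotone non-increasing in nSd
  set.seed(9)
  noisy <- matrix(rnorm(64 * 64, 100, 10), 64, 64)
  refBig <- matrix(FALSE, 64, 64); refBig[, 1:16] <- TRUE
  fr <- vapply(c(0, 1, 2, 3, 5), function(k)
    lgeThresholdMask(noisy, refBig, nSd = k)$enhancedFraction, numeric(1))
  expect_true(all(diff(fr) <= 0))

  expect_error(lgeThresholdMask(matrix(1, 2, 2),
                                matrix(c(TRUE, FALSE, FALSE, FALSE), 2)),
               "at least 2 pixels")
})
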
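test_that("frame schedules expand, summarize and round-trip", {
  sched <- makeFrameSchedule(list(c(12, 10), c(2, 30), c(1, 60), c(1, 360)))
  expect_length(frameDurations(sched), 16L)
  expect_equal(totalDuration(sched), 600)
  expect_equal(compressFrameSchedule(sched),
               list(c(12, 10), c(2, 30), c(1, 60), c(1, 360)))
  expect_identical(sched, nh3FrameSchedule())

  expect_equal(frameDurations(makeFrameSchedule(list(c(1, 10)))), 10)
  expect_equal(frameDurations(makeFrameSchedule(list(c(3, 5), c(2, 10)))),
               c(5, 5, 5, 10, 10))
  expect_equal(frameMids(makeFrameSchedule(list(c(2, 10)))), c(5, 15))

  expect_error(makeFrameSchedule(list(c(0, 10))), "positive integers")
  expect_error(makeFrameSchedule(list(c(2, -1))), "positive")
  expect_error(makeFrameSchedule(list()), "at least one")
})

test_that("list-mode binning yields frame rates and conserves events", {
  one <- binListMode(c(1, 2, 3), makeFrameSchedule(list(c(1, 10))))
  expect_equal(curveValues(one), 0.3)
  expect_equal(curveTimes(one), 5)

  empty <- binListMode(numeric(0), nh3FrameSchedule())
  expect_true(all(curveValues(empty) == 0))
  expect_length(empty, 16L)

  sched <- nh3FrameSchedule()
  set.seed(11)
  ev <- runif(500, 0, 700)           # some beyond the 600 s schedule
  tc <- binListMode(ev, sched)
  expect_equal(sum(curveValues(tc) * frameDurations(tc)), sum(ev < 600))

  # boundary events belong to the later frame; beyond-schedule dropped
  b <- binListMode(c(0, 10, 600), makeFrameSchedule(list(c(2, 10), c(1, 580))))
  expect_equal(curveValues(b) * frameDurations(b), c(1, 1, 0))

  start <- binListMode(c(1, 2), makeFrameSchedule(list(c(2, 10))),
                       timestamp = "start")
  expect_equal(curveTimes(start), c(0, 10))
})

test_that("binned Poisson stream matches the integrated rate within 3 SE", {
  sim <- simulatePET(totalEvents = 1e5, seed = 42)
  truth <- simulatePET(noiseFree = TRUE)
  # expected counts per frame under the (rescaled) intensity
  scale <- sum(curveValues(truth$tissue) * frameDurations(truth$tissue)) /
    1e5
  expCounts <- curveValues(truth$tissue) * frameDurations(truth$tissue) /
    scale
  obsCounts <- curveValues(sim$tissue) * frameDurations(sim$tissue) /
    (sum(curveValues(sim$tissue) * frameDurations(sim$tissue)) /
       sim$nEventsTissue)
  z <- (obsCounts - expCounts) / sqrt(pmax(expCounts, 1))
  expect_true(all(abs(z) < 3 + 1e-9))
})

test_that("territory aggregation is a validated unweighted mean", {
  model <- defaultSegmentModel()
  const <- stats::setNames(rep(1, 16), as.character(1:16))
  for (tr in c("LAD", "LCX", "BOTH", "GLOBAL"))
    expect_equal(aggregateSegments(const, model, tr), 1)

  ladSegs <- names(territories(model))[territories(model) == "LAD"]
  v <- stats::setNames(rep(0, 16), as.character(1:16))
  v[ladSegs] <- 2
  expect_equal(aggregateSegments(v, model, "LAD"), 2)

  set.seed(3)
  r <- stats::setNames(runif(16), as.character(1:16))
  # brute-force enumeration oracle
  for (tr in c("LAD", "LCX", "BOTH")) {
    segs <- names(territories(model))[territories(model) == tr]
    acc <- 0; cnt <- 0
    for (s in segs) { acc <- acc + r[[s]]; cnt <- cnt + 1 }
    expect_equal(aggregateSegments(r, model, tr), acc / cnt)
  }
  # order invariance and linearity
  shuf <- r[sample(names(r))]
  expect_equal(aggregateSegments(shuf, model, "LCX"),
               aggregateSegments(r, model, "LCX"))
  expect_equal(aggregateSegments(3 * r + 1, model, "LAD"),
               3 * aggregateSegments(r, model, "LAD") + 1)

  expect_error(aggregateSegments(r, model, "RCA"), "unknown territory")
  expect_error(aggregateSegments(r[-1], model,
                                 territories(model)[[1]]), "missing")
})

test_that("segment model validity enforces the 16-segment contract", {
  model <- defaultSegmentModel()
  expect_length(territories(model), 16L)
  expect_setequal(unique(territories(model)), c("LAD", "LCX", "BOTH"))

  expect_error(SegmentModel(stats::setNames(rep("LAD", 15),
                                            as.character(1:15))),
               "16 segments")
  bad <- stats::setNames(rep("LAD", 16), as.character(1:16))
  expect_error(SegmentModel(bad), "every territory")
  bad2 <- bad; bad2[1:8] <- "LCX"; bad2[9] <- "XXX"
  expect_error(SegmentModel(bad2), "LAD, LCX, BOTH")
})

test_that("time curves validate their invariants", {
  expect_error(TimeCurve(c(1, 1), c(0, 0)), "strictly increasing")
  expect_error(TimeCurve(c(1, 2), c(0, Inf)), "finite")
  expect_error(TimeCurve(c(1, 2), c(0, 0), durations = c(1, -1)),
               "positive")
  expect_error(TimeCurve(c(0, 1), c(0, 0), durations = c(5, 5)),
               "overlap")
  tc <- TimeCurve(c(5, 15), c(1, 2), durations = c(10, 10))
  expect_equal(length(tc), 2L)
})

test_that("time curves round-trip through CSV", {
  tc <- TimeCurve(c(5, 15, 25), c(0, 1.5, 0.5), durations = c(10, 10, 10))
  path <- tempfile(fileext = ".csv")
  writeTimeCurve(tc, path)
  back <- readTimeCurve(path)
  expect_equal(curveTimes(back), curveTimes(tc))
  expect_equal(curveValues(back), curveValues(tc))
  expect_equal(frameDurations(back), frameDurations(tc))
})
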
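test_that("exact Mann-Whitney matches full enumeration for small n", {
  set.seed(21)
  for (rep in 1:6) {
    n <- sample(3:6, 1); m <- sample(3:6, 1)
    x <- round(runif(n, 0, 100), 3)       # continuous: no ties
    y <- round(runif(m, 0, 100), 3)
    coh <- makeTinyCohort(list(baseline = y, "1mo" = x))
    got <- mannWhitneyVsBaseline(coh, "LAD", "NH3", "1mo")
    expect_true(got$exact)
    expect_equal(got$p, enumerateMannWhitneyP(x, y), tolerance = 1e-12)
  }

  # n = 5 vs 5 fully separated: exact two-sided p = 2 / C(10, 5)
  coh <- makeTinyCohort(list(baseline = 1:5, "1mo" = 11:15))
  got <- mannWhitneyVsBaseline(coh, "LAD", "NH3", "1mo")
  expect_equal(got$p, 2 / choose(10, 5), tolerance = 1e-12)

  # identical groups: p = 1
  same <- makeTinyCohort(list(baseline = c(1, 2, 3), "1mo" = c(1, 2, 3)))
  expect_equal(mannWhitneyVsBaseline(same, "LAD", "NH3", "1mo")$p, 1)

  # empty group flagged
  ec <- makeTinyCohort(list(baseline = 1:3, "1mo" = numeric(0)))
  expect_true(is.na(mannWhitneyVsBaseline(ec, "LAD", "NH3", "1mo")$p))
})

test_that("Kruskal-Wallis omnibus has the expected relationships", {
  set.seed(31)
  x <- rnorm(6) + 10; y <- rnorm(7) + 10.5
  coh <- makeTinyCohort(list(baseline = x, "1mo" = y))
  kw <- kruskalWallisTimepoints(coh, "LAD", "NH3")
  # two groups: KW chi-squared p equals the asymptotic (uncorrected)
  # two-sided Mann-Whitney p
  mw <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(kw$p, mw$p.value, tolerance = 1e-10)

  # strongly separated groups
  sep <- makeTinyCohort(list(baseline = rnorm(5) + 10,
                             "1wk" = rnorm(5) + 30,
                             "1mo" = rnorm(5) + 50,
                             "3mo" = rnorm(5) + 100,
                             "6mo" = rnorm(5) + 150))
  expect_lt(kruskalWallisTimepoints(sep, "LAD", "NH3")$p, 0.001)

  # insufficient groups flagged, not fatal
  tiny <- makeTinyCohort(list(baseline = 1, "1mo" = 2))
  out <- kruskalWallisTimepoints(tiny, "LAD", "NH3")
  expect_true(is.na(out$p))
  expect_match(out$reason, "fewer than 2")
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(41)
  vals <- list(baseline = runif(5), "1mo" = runif(5) + 0.3,
               "3mo" = runif(5))
  coh <- makeTinyCohort(vals)
  cohT <- coh; cohT$mbf <- exp(3 * cohT$mbf)
  expect_equal(kruskalWallisTimepoints(coh, "LAD", "NH3")$H,
               kruskalWallisTimepoints(cohT, "LAD", "NH3")$H)
  a <- mannWhitneyVsBaseline(coh, "LAD", "NH3", "1mo")
  b <- mannWhitneyVsBaseline(cohT, "LAD", "NH3", "1mo")
  expect_equal(a$U, b$U)
  expect_equal(a$p, b$p)
})

test_that("Pearson and paired tests handle exact and degenerate input", {
  lin <- makeTinyCohort(list(baseline = 1:5, "1mo" = 6:10))
  lin$suv <- 2 * lin$mbf + 1
  pc <- pearsonByTerritory(lin, "LAD")
  expect_equal(pc$r, 1)

  flat <- lin; flat$suv <- 5
  expect_match(pearsonByTerritory(flat, "LAD")$reason, "zero variance")

  # paired: identical columns give t = 0, p = 1
  coh <- makeTinyCohort(list(baseline = 1:5))
  dce <- coh; dce$modality <- "DCE"
  both <- rbind(coh, dce)
  pt <- pairedModalityTest(both, "LAD")
  expect_equal(pt$t, 0)
  expect_equal(pt$p, 1)

  # constant nonzero difference: flagged degenerate
  dce2 <- dce; dce2$mbf <- dce2$mbf + 0.5
  pt2 <- pairedModalityTest(rbind(coh, dce2), "LAD")
  expect_true(is.na(pt2$p))
  expect_match(pt2$reason, "constant nonzero")

  # fewer than 3 complete pairs
  pt3 <- pairedModalityTest(rbind(coh[1:2, ], dce[1:2, ]), "LAD")
  expect_match(pt3$reason, "fewer than 3")
})

test_that("unbiased modalities reject at roughly the nominal rate", {
  ps <- vapply(1:200, function(s) {
    coh <- simulateCohort(cohortSimConfig(seed = 400 + s))
    pairedModalityTest(coh, "LAD")$p
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("the report covers every cell and applies QC exclusions", {
  coh <- simulateCohort(cohortSimConfig(seed = 10))
  rep1 <- buildStatReport(coh)
  # 4 territory levels (3 coronary + whole myocardium) x 2 modalities
  expect_equal(nrow(rep1$omnibus), 8L)
  # 5 follow-up contrasts per territory x modality
  expect_equal(nrow(rep1$contrasts), 8L * 5L)
  expect_true(all(rep1$contrasts$p >= 0 & rep1$contrasts$p <= 1,
                  na.rm = TRUE))
  expect_equal(nrow(rep1$pearson), 4L)
  expect_true(all(abs(rep1$pearson$r) <= 1, na.rm = TRUE))

  # excluding every DCE acquisition empties DCE cells, leaves NH3 intact
  allKeys <- unique(coh[, c("animal_id", "timepoint")])
  rep2 <- buildStatReport(coh, qcExclusions = allKeys)
  dceRows <- rep2$omnibus$modality == "DCE"
  expect_true(all(is.na(rep2$omnibus$p[dceRows])))
  expect_equal(rep2$omnibus[!dceRows, ],
               rep1$omnibus[rep1$omnibus$modality == "NH3", ])

  # determinism
  expect_identical(rep1, buildStatReport(coh))
})

test_that("constant-mean rate-pressure product shows no time trend", {
  ps <- vapply(1:40, function(s)
    buildStatReport(simulateCohort(cohortSimConfig(seed = 100 + s)))$rpp$p,
    numeric(1))
  # null p-values: median near 0.5, not piled at significance
  expect_gt(stats::median(ps), 0.2)
  expect_lt(mean(ps < 0.05), 0.2)
})
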
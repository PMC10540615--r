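# Scoring the flagging system against a reference standard.

test_that("classifyOutcome implements the four-way definition", {
  expect_identical(classifyOutcome(TRUE, 0.3, 0.825), "TP")
  expect_identical(classifyOutcome(FALSE, 0.95, 0.825), "TN")
  expect_identical(classifyOutcome(TRUE, 0.95, 0.825), "FP")
  expect_identical(classifyOutcome(FALSE, 0.3, 0.825), "FN")
  # exact equality counts as performed well
  expect_identical(classifyOutcome(TRUE, 0.825, 0.825), "FP")
  expect_identical(classifyOutcome(FALSE, 0.825, 0.825), "TN")
  # vectorized
  expect_identical(classifyOutcome(c(TRUE, FALSE), c(0.1, 0.9), 0.8),
                   c("TP", "TN"))
  expect_error(classifyOutcome(TRUE, 1.5, 0.8), "\\[0, 1\\]")
  expect_error(classifyOutcome(c(TRUE, FALSE), 0.5, 0.8), "equal length")
})

test_that("confusionCounts tallies outcomes and conserves the total", {
  cc <- confusionCounts(c("TP", "TN", "TN"))
  expect_identical(counts(cc), c(tp = 1L, fp = 0L, fn = 0L, tn = 2L))
  expect_identical(cc@n, 3L)

  allTn <- confusionCounts(rep("TN", 7))
  expect_identical(counts(allTn), c(tp = 0L, fp = 0L, fn = 0L, tn = 7L))

  mixed <- c("TP", "FP", "FN", "TN", "TP", "FN")
  cc2 <- confusionCounts(mixed)
  expect_identical(counts(cc2), c(tp = 2L, fp = 1L, fn = 2L, tn = 1L))
  expect_identical(sum(counts(cc2)), cc2@n)

  expect_error(confusionCounts(character(0)), "non-empty")
  expect_error(confusionCounts(c("TP", "XX")), "TP, FP, FN or TN")
})

test_that("confusion conservation holds on random cohorts", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:50, 1)
    out <- classifyOutcome(runif(n) < 0.4, runif(n), runif(1))
    cc <- confusionCounts(out)
    expect_identical(sum(counts(cc)), n)
  }
})

test_that("cohortStats computes subset means and sample SDs", {
  cs <- cohortStats(c(0.9, 0.8, 0.2), c(FALSE, FALSE, TRUE))
  expect_equal(cs@nonflaggedMean, 0.85)
  expect_equal(cs@flaggedMean, 0.2)
  expect_equal(cs@overallMean, mean(c(0.9, 0.8, 0.2)))
  expect_equal(cs@nonflaggedSd, sd(c(0.9, 0.8)))  # sample convention (n-1)
  expect_identical(cs@nFlagged, 1L)

  # all flagged: the complement's statistics are absent, not zero
  allFl <- cohortStats(c(0.1, 0.2), c(TRUE, TRUE))
  expect_true(is.na(allFl@nonflaggedMean))
  expect_true(is.na(allFl@nonflaggedSd))

  # no flags: overall and non-flagged summaries coincide
  noFl <- cohortStats(c(0.7, 0.9, 0.95), rep(FALSE, 3))
  expect_equal(noFl@nonflaggedMean, noFl@overallMean)
  expect_equal(noFl@nonflaggedSd, noFl@overallSd)

  expect_error(cohortStats(c(0.5), logical(0)), "equal length")
})

test_that("subset means recombine into the overall mean", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(4:40, 1)
    d <- runif(n)
    f <- runif(n) < 0.5
    cs <- cohortStats(d, f)
    expect_identical(cs@nFlagged + (cs@nTotal - cs@nFlagged), n)
    if (cs@nFlagged > 0 && cs@nFlagged < n) {
      recombined <- (cs@nFlagged * cs@flaggedMean +
                       (n - cs@nFlagged) * cs@nonflaggedMean) / n
      expect_equal(recombined, cs@overallMean)
    }
  }
})

test_that("stratifyFlagsByFeature localizes flags along the feature axis", {
  # flags concentrated at small feature values
  feature <- c(1, 2, 3, 10, 11, 12, 20, 21, 22)
  flags <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  st <- stratifyFlagsByFeature(flags, feature, nBins = 3)
  expect_identical(nrow(st), 3L)
  expect_gt(st$fraction[1], st$fraction[3])
  expect_equal(sum(st$n), length(feature))
  expect_equal(sum(st$nFlagged), sum(flags))

  # no flags anywhere -> all fractions zero
  none <- stratifyFlagsByFeature(rep(FALSE, 9), feature, nBins = 3)
  expect_true(all(none$fraction == 0))

  # single bin -> overall flag rate
  one <- stratifyFlagsByFeature(flags, feature, nBins = 1)
  expect_equal(one$fraction, mean(flags))

  expect_error(stratifyFlagsByFeature(flags, feature[-1], 3), "equal length")
  expect_error(stratifyFlagsByFeature(flags, feature, 0), ">= 1")
})
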
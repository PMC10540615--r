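# Dice similarity, label volume measurement and inter-fold disagreement.

test_that("diceScore matches hand-computable cases and conventions", {
  a <- lv(c(1, 1, 1, 1, 0, 0, 0, 0), c(2, 2, 2), labels = 0:1)
  expect_identical(diceScore(a, a, 1L), 1)

  # disjoint foreground
  b <- lv(c(0, 0, 0, 0, 1, 1, 1, 1), c(2, 2, 2), labels = 0:1)
  expect_identical(diceScore(a, b, 1L), 0)

  # |A| = |B| = 4, overlap 2 -> 2*2/(4+4) = 0.5
  c2 <- lv(c(1, 1, 0, 0, 1, 1, 0, 0), c(2, 2, 2), labels = 0:1)
  expect_equal(diceScore(a, c2, 1L), 0.5)
  expect_equal(diceScore(c2, a, 1L), diceScore(a, c2, 1L))

  # empty conventions: both empty agrees (1 by default, 0 by override);
  # exactly one empty is 0
  e <- lv(rep(0, 8), c(2, 2, 2), labels = 0:1)
  expect_identical(diceScore(e, e, 1L), 1)
  expect_identical(diceScore(e, e, 1L, bothEmpty = 0), 0)
  expect_identical(diceScore(a, e, 1L), 0)
})

test_that("diceScore rejects incompatible grids and unknown labels", {
  a <- lv(rep(1, 8), c(2, 2, 2), labels = 0:1)
  b <- lv(rep(1, 12), c(2, 2, 3), labels = 0:1)
  expect_error(diceScore(a, b, 1L), "grid incompatibility")
  c2 <- lv(rep(1, 8), c(2, 2, 2), spacing = c(1, 1, 2), labels = 0:1)
  expect_error(diceScore(a, c2, 1L), "spacing")
  expect_error(diceScore(a, a, 7L), "label")
})

test_that("diceScore agrees with the brute-force voxel enumeration oracle", {
  for (seed in 1:12) {
    d <- c(sample(3:10, 1), sample(3:10, 1), sample(3:10, 1))
    a <- randomLv(d, seed)
    b <- randomLv(d, seed + 100)
    for (target in 0:2)
      expect_equal(diceScore(a, b, target), bruteForceDice(a, b, target),
                   info = sprintf("seed %d target %d", seed, target))
  }
})

test_that("Dice is spacing-invariant; label volume scales with spacing", {
  a <- randomLv(c(6, 6, 6), 1)
  b <- randomLv(c(6, 6, 6), 2)
  a2 <- lv(voxels(a), spacing = c(0.5, 2, 3), labels = 0:2)
  b2 <- lv(voxels(b), spacing = c(0.5, 2, 3), labels = 0:2)
  expect_equal(diceScore(a2, b2, 1L), diceScore(a, b, 1L))
  # 1000 voxels at 1x1x1 mm -> 1 ml; 100 voxels at 1x1x5 mm -> 0.5 ml
  v <- lv(rep(1, 1000), c(10, 10, 10), labels = 0:1)
  expect_equal(labelVolumeMl(v, 1L), 1)
  w <- lv(c(rep(1, 100), rep(0, 900)), c(10, 10, 10),
          spacing = c(1, 1, 5), labels = 0:1)
  expect_equal(labelVolumeMl(w, 1L), 0.5)
  expect_equal(labelVolumeMl(w, 0L), 4.5)
  none <- lv(rep(0, 8), c(2, 2, 2), labels = 0:1)
  expect_equal(labelVolumeMl(none, 1L), 0)
  expect_error(labelVolumeMl(none, 9L), "label")
})

test_that("interfoldDices returns each unordered pair once, in order", {
  set.seed(11)
  for (k in 2:8) {
    folds <- lapply(seq_len(k), function(i) randomLv(c(5, 5, 4), 200 + i))
    ir <- interfoldDices(FoldSet(folds), 1L)
    expect_length(pairwiseDices(ir), k * (k - 1) / 2)
    expected <- character(0)
    for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k))
      expected <- c(expected, paste0(i, "-", j))
    expect_identical(names(pairwiseDices(ir)), expected)
    s <- diceSummaries(ir)
    expect_lte(s[["min"]], s[["median"]])
    expect_lte(s[["median"]], s[["max"]])
    expect_lte(s[["min"]], s[["mean"]])
    expect_lte(s[["mean"]], s[["max"]])
  }
})

test_that("interfoldDices handles the identity and K = 2 cases", {
  a <- smallPhantom()
  identical5 <- FoldSet(rep(list(a), 5))
  ir <- interfoldDices(identical5, 2L)
  expect_length(pairwiseDices(ir), 10L)  # K = 5 -> 10 interfold Dices
  expect_true(all(pairwiseDices(ir) == 1))
  expect_true(all(diceSummaries(ir) == 1))

  two <- FoldSet(list(a, randomLv(dim(voxels(a)), 3)))
  ir2 <- interfoldDices(two, 2L)
  expect_length(pairwiseDices(ir2), 1L)
  expect_true(all(diceSummaries(ir2) == pairwiseDices(ir2)[[1]]))

  expect_error(FoldSet(list(a)), "at least 2")
})

test_that("summarizeDices computes the four first-order statistics", {
  expect_equal(summarizeDices(c(0.8, 0.9), "median"), 0.85)
  expect_equal(summarizeDices(c(0.2, 0.4, 0.9, 1.0), "min"), 0.2)
  expect_equal(summarizeDices(rep(0.7, 10), "mean"), 0.7)
  expect_equal(summarizeDices(c(0.1, 0.5, 0.9, 1.0), "median"), 0.7)
  expect_equal(summarizeDices(c(0.3, 0.2, 0.9), "max"), 0.9)
  expect_error(summarizeDices(numeric(0), "mean"), "empty")
  expect_error(summarizeDices(c(0.5, 1.2), "mean"), "\\[0, 1\\]")
})

test_that("LabelVolume enforces its invariants", {
  expect_error(LabelVolume(array(0L, c(2, 2)), c(1, 1, 1)), "3D")
  expect_error(LabelVolume(array(0L, c(2, 2, 2)), c(1, -1, 1)), "positive|spacing")
  expect_error(lv(rep(3, 8), c(2, 2, 2), labels = 0:2), "vocabulary")
  expect_error(LabelVolume(array(0.5, c(2, 2, 2))), "whole numbers")
})
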
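# Phantom construction and fold-perturbation simulation.

test_that("makePhantom is deterministic and labels override correctly", {
  cfg <- phantomConfig(gridShape = c(40L, 40L, 32L), spacingMm = c(1, 1, 1),
                       organRadiiMm = c(14, 10, 8), tumorRadiusMm = 5,
                       tumorOffsetMm = c(4, 2, 1))
  p1 <- makePhantom(cfg)
  p2 <- makePhantom(cfg)
  expect_identical(voxels(p1), voxels(p2))
  expect_setequal(unique(as.vector(voxels(p1))), c(0L, 1L, 2L))

  # tumor fully inside the organ: union voxel count equals the organ-alone
  # count of a no-tumor phantom with the same geometry
  inside <- phantomConfig(gridShape = c(40L, 40L, 32L),
                          organRadiiMm = c(14, 10, 8), tumorRadiusMm = 3,
                          tumorOffsetMm = c(2, 1, 0))
  pt <- makePhantom(inside)
  tiny <- phantomConfig(gridShape = c(40L, 40L, 32L),
                        organRadiiMm = c(14, 10, 8), tumorRadiusMm = 1e-6,
                        tumorOffsetMm = c(2, 1, 0))
  p0 <- makePhantom(tiny)
  expect_identical(sum(voxels(pt) != 0L), sum(voxels(p0) == 1L) + 1L)
  # (+1: the degenerate tumor still occupies its centre voxel)
})

test_that("a sub-voxel tumor occupies exactly one voxel", {
  cfg <- phantomConfig(gridShape = c(21L, 21L, 21L),
                       organRadiiMm = c(8, 8, 8), tumorRadiusMm = 1e-9,
                       tumorOffsetMm = c(0, 0, 0))
  p <- makePhantom(cfg)
  expect_identical(sum(voxels(p) == 2L), 1L)
})

test_that("a tumor outside the grid is rejected", {
  expect_error(phantomConfig(gridShape = c(20L, 20L, 20L),
                             organRadiiMm = c(5, 5, 5), tumorRadiusMm = 8,
                             tumorOffsetMm = c(6, 0, 0)),
               "does not fit")
})

test_that("null perturbation reproduces the truth in every fold", {
  truth <- smallPhantom()
  fs <- simulateFoldPredictions(truth, 5, perturbationConfig(seed = 3))
  for (f in foldPredictions(fs))
    expect_identical(voxels(f), voxels(truth))
  ir <- interfoldDices(fs, 2L)
  expect_true(all(pairwiseDices(ir) == 1))
})

test_that("certain misses give pairwise 1 under the both-empty convention", {
  truth <- smallPhantom()
  fs <- simulateFoldPredictions(truth, 5,
                                perturbationConfig(missProb = 1, seed = 4))
  for (f in foldPredictions(fs))
    expect_identical(sum(voxels(f) == 2L), 0L)
  # the consistent confident failure: agreement is perfect, so the case is
  # not flaggable -- by design
  expect_true(all(pairwiseDices(interfoldDices(fs, 2L)) == 1))
  expect_true(all(pairwiseDices(interfoldDices(fs, 2L, bothEmpty = 0)) == 0))
})

test_that("intermittent misses produce empty-vs-nonempty zero pairs", {
  truth <- smallPhantom()
  fs <- simulateFoldPredictions(truth, 5,
                                perturbationConfig(missProb = 0.5, seed = 1))
  nEmpty <- sum(vapply(foldPredictions(fs),
                       function(f) sum(voxels(f) == 2L) == 0L, logical(1)))
  expect_gt(nEmpty, 0L)
  expect_lt(nEmpty, 5L)
  pw <- pairwiseDices(interfoldDices(fs, 2L))
  expect_true(any(pw == 0))
  expect_lt(diceSummaries(interfoldDices(fs, 2L))[["median"]], 0.81)
})

test_that("fold simulation is reproducible and k-stable", {
  truth <- smallPhantom()
  pert <- perturbationConfig(boundaryRadiusVoxels = 2, shiftVoxels = 2,
                             missProb = 0.2, seed = 11)
  a <- simulateFoldPredictions(truth, 4, pert)
  b <- simulateFoldPredictions(truth, 4, pert)
  for (i in 1:4)
    expect_identical(voxels(foldPredictions(a)[[i]]),
                     voxels(foldPredictions(b)[[i]]))
  # per-fold substreams are derived by counter: fold i does not depend on k
  c6 <- simulateFoldPredictions(truth, 6, pert)
  for (i in 1:4)
    expect_identical(voxels(foldPredictions(c6)[[i]]),
                     voxels(foldPredictions(a)[[i]]))
  expect_error(simulateFoldPredictions(truth, 1, pert), ">= 2")
})

test_that("soft fields are normalized and argmax-consistent with hard folds", {
  truth <- smallPhantom()
  pert <- perturbationConfig(boundaryRadiusVoxels = 1, softSigmaMm = 2,
                             seed = 5)
  fs <- simulateFoldPredictions(truth, 2, pert, withProbabilities = TRUE)
  p <- foldProbabilities(fs)[[1]]
  expect_true(validObject(p))
  # smoothing is label-preserving away from boundaries: the argmax of the
  # soft field agrees with the hard fold on a large majority of voxels
  amax <- apply(p@probs, 1:3, which.max) - 1L
  agree <- mean(amax == voxels(foldPredictions(fs)[[1]]))
  expect_gt(agree, 0.95)
  # sigma 0 gives the exact one-hot encoding
  fs0 <- simulateFoldPredictions(truth, 2, perturbationConfig(seed = 5),
                                 withProbabilities = TRUE)
  expect_setequal(unique(as.vector(foldProbabilities(fs0)[[1]]@probs)),
                  c(0, 1))
})

test_that("higher miss probability lowers median interfold agreement", {
  truth <- smallPhantom()
  medians <- function(missProb) {
    vapply(1:20, function(s) {
      fs <- simulateFoldPredictions(truth, 5,
                                    perturbationConfig(missProb = missProb,
                                                       boundaryRadiusVoxels = 1,
                                                       seed = s))
      diceSummaries(interfoldDices(fs, 2L))[["median"]]
    }, numeric(1))
  }
  expect_lt(mean(medians(0.5)), mean(medians(0)))
})

test_that("simulateCohort records recoverable arm labels, reproducibly", {
  spec <- cohortSpec(nIn = 2L, nOut = 2L, kFolds = 3L, masterSeed = 9L,
                     phantom = list(gridShape = c(48L, 48L, 40L),
                                    organRadiiMm = c(16, 12, 10),
                                    tumorRadiusRangeInMm = c(8, 12),
                                    tumorRadiusRangeOutMm = c(2, 4),
                                    tumorOffsetMm = c(4, 2, 2),
                                    offsetJitterMm = 1))
  co <- simulateCohort(spec)
  expect_length(co$cases, 4L)
  expect_identical(vapply(co$cases, `[[`, character(1), "arm"),
                   rep(c("in_distribution", "out_of_distribution"), each = 2))
  # OOD tumors are smaller by construction
  vols <- vapply(co$cases, `[[`, numeric(1), "tumorVolumeMl")
  expect_lt(max(vols[3:4]), min(vols[1:2]))
  # bit-identical rerun
  co2 <- simulateCohort(spec)
  for (i in 1:4)
    expect_identical(voxels(foldPredictions(co$cases[[i]]$foldSet)[[1]]),
                     voxels(foldPredictions(co2$cases[[i]]$foldSet)[[1]]))
  expect_error(cohortSpec(nIn = 0L, nOut = 0L), "not both zero")
})
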
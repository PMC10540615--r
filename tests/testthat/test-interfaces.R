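# NIfTI round-tripping, manifests, run configs and the end-to-end workflows.

# a tiny written cohort shared by the tests in this file
tinyCohortDir <- local({
  dir <- file.path(tempdir(), "tiny_cohort")
  if (!dir.exists(dir)) {
    spec <- cohortSpec(nIn = 2L, nOut = 2L, kFolds = 3L, masterSeed = 5L,
                       phantom = list(gridShape = c(40L, 40L, 32L),
                                      organRadiiMm = c(14, 10, 8),
                                      tumorRadiusRangeInMm = c(7, 10),
                                      tumorRadiusRangeOutMm = c(2, 4),
                                      tumorOffsetMm = c(4, 2, 1),
                                      offsetJitterMm = 1))
    writeCohort(simulateCohort(spec), dir)
  }
  dir
})

test_that("label and probability volumes round-trip through NIfTI", {
  v <- randomLv(c(7, 6, 5), 21, spacing = c(0.9, 1.1, 3))
  f <- tempfile(fileext = ".nii.gz")
  writeLabelVolume(v, f)
  back <- readLabelVolume(f, caseId = "t")
  expect_identical(voxels(back), voxels(v))
  expect_equal(voxelSpacing(back), voxelSpacing(v), tolerance = 1e-6)

  # independent reader agrees on voxel data and spacing
  ind <- oro.nifti::readNIfTI(f)
  expect_equal(array(as.integer(ind@.Data), dim(voxels(v))), voxels(v))
  expect_equal(oro.nifti::pixdim(ind)[2:4], voxelSpacing(v), tolerance = 1e-6)

  p <- oneHotProbabilities(v, classLabels = 0:2)
  fp <- tempfile(fileext = ".nii.gz")
  writeProbabilityVolume(p, fp)
  pback <- readProbabilityVolume(fp, classLabels = 0:2)
  expect_equal(pback@probs, p@probs)
})

test_that("a simulated cohort round-trips through the manifest loader", {
  m <- loadManifest(file.path(tinyCohortDir, "manifest.csv"))
  expect_s3_class(m, "qcManifest")
  expect_identical(nrow(m), 4L)
  expect_identical(lengths(m$foldPaths), rep(3L, 4))
  expect_true(all(file.exists(unlist(m$foldPaths))))
  expect_true(all(file.exists(m$referencePath)))
  expect_true(all(c("arm", "tumor_volume_ml") %in% names(m)))
})

test_that("malformed manifests are rejected with the offending case named", {
  dir <- tempdir()
  vol <- file.path(dir, "v.nii.gz")
  writeLabelVolume(randomLv(c(4, 4, 3), 1), vol)
  write.csv(data.frame(case_id = "solo", folds = vol),
            file.path(dir, "bad1.csv"), row.names = FALSE)
  expect_error(loadManifest(file.path(dir, "bad1.csv")),
               "solo.*fewer than 2")
  write.csv(data.frame(case_id = "ghost",
                       folds = paste(vol, file.path(dir, "missing.nii.gz"),
                                     sep = ";")),
            file.path(dir, "bad2.csv"), row.names = FALSE)
  expect_error(loadManifest(file.path(dir, "bad2.csv")), "ghost.*missing")
  write.csv(data.frame(case_id = c("dup", "dup"),
                       folds = paste(vol, vol, sep = ";")),
            file.path(dir, "bad3.csv"), row.names = FALSE)
  expect_error(loadManifest(file.path(dir, "bad3.csv")), "duplicate.*dup")
  expect_error(loadManifest(file.path(dir, "nope.csv")), "no such manifest")
})

test_that("runFlag flags without references and isolates bad cases", {
  m <- loadManifest(file.path(tinyCohortDir, "manifest.csv"))
  cfg <- runConfig(targetLabel = 2L, statistic = "median", threshold = 0.9)
  out <- file.path(tempdir(), "flagrun")
  res <- runFlag(m, cfg, outDir = out)
  expect_identical(nrow(res$report), 4L)
  expect_true(all(res$report$status == "ok"))
  expect_true(file.exists(file.path(out, "report.csv")))
  expect_true(file.exists(file.path(out, "summary.json")))
  expect_true(all(file.exists(file.path(out, "ensembles",
                                        paste0(res$report$case_id, ".nii.gz")))))

  # a case with a mismatched fold grid fails alone; the others are untouched
  dir <- file.path(tempdir(), "mixed")
  dir.create(dir, showWarnings = FALSE)
  ok1 <- file.path(dir, "a1.nii.gz"); writeLabelVolume(randomLv(c(4, 4, 3), 1), ok1)
  ok2 <- file.path(dir, "a2.nii.gz"); writeLabelVolume(randomLv(c(4, 4, 3), 2), ok2)
  bad <- file.path(dir, "b2.nii.gz"); writeLabelVolume(randomLv(c(5, 4, 3), 3), bad)
  write.csv(data.frame(case_id = c("good", "mismatch"),
                       folds = c(paste(ok1, ok2, sep = ";"),
                                 paste(ok1, bad, sep = ";"))),
            file.path(dir, "manifest.csv"), row.names = FALSE)
  res2 <- runFlag(file.path(dir, "manifest.csv"), cfg)
  expect_identical(res2$report$status, c("ok", "failed"))
  expect_match(res2$report$message[2], "grid|shape")
  expect_false(is.na(res2$report$flagged[1]))
})

test_that("identical predictions are never flagged at any threshold <= 1", {
  dir <- file.path(tempdir(), "ident")
  dir.create(dir, showWarnings = FALSE)
  v <- smallPhantom()
  paths <- vapply(1:5, function(i) {
    f <- file.path(dir, sprintf("f%d.nii.gz", i)); writeLabelVolume(v, f); f
  }, character(1))
  write.csv(data.frame(case_id = "same",
                       folds = paste(paths, collapse = ";")),
            file.path(dir, "manifest.csv"), row.names = FALSE)
  for (th in c(0.5, 0.9, 1)) {
    res <- runFlag(file.path(dir, "manifest.csv"),
                   runConfig(threshold = th))
    expect_false(res$decisions[["same"]]@flagged)
  }
})

test_that("runEvaluate scores the cohort and conserves confusion totals", {
  m <- loadManifest(file.path(tinyCohortDir, "manifest.csv"))
  cfg <- runConfig(targetLabel = 2L, threshold = 0.9, plots = TRUE)
  out <- file.path(tempdir(), "evalrun")
  res <- runEvaluate(m, cfg, outDir = out)
  expect_identical(sum(counts(res$confusion)), 4L)
  expect_true(all(!is.na(res$report$ensemble_dice)))
  expect_true(all(res$report$outcome %in% c("TP", "FP", "FN", "TN")))
  expect_s4_class(res$cohort, "CohortSummary")
  expect_true(file.exists(file.path(out, "scatter.png")))
  expect_true(file.exists(file.path(out, "confusion.png")))
  # reruns are byte-identical: stable ordering and fixed float formatting
  r1 <- readLines(file.path(out, "report.csv"))
  s1 <- readLines(file.path(out, "summary.json"))
  runEvaluate(m, cfg, outDir = out)
  expect_identical(readLines(file.path(out, "report.csv")), r1)
  expect_identical(readLines(file.path(out, "summary.json")), s1)
})

test_that("perfect predictions yield an all-TN confusion matrix", {
  dir <- file.path(tempdir(), "perfect")
  dir.create(dir, showWarnings = FALSE)
  v <- smallPhantom()
  ref <- file.path(dir, "ref.nii.gz"); writeLabelVolume(v, ref)
  paths <- vapply(1:3, function(i) {
    f <- file.path(dir, sprintf("f%d.nii.gz", i)); writeLabelVolume(v, f); f
  }, character(1))
  write.csv(data.frame(case_id = c("p1", "p2"),
                       folds = rep(paste(paths, collapse = ";"), 2),
                       reference = rep(ref, 2)),
            file.path(dir, "manifest.csv"), row.names = FALSE)
  res <- runEvaluate(file.path(dir, "manifest.csv"),
                     runConfig(threshold = 0.9))
  expect_identical(counts(res$confusion),
                   c(tp = 0L, fp = 0L, fn = 0L, tn = 2L))
})

test_that("runSensitivity writes a monotone scan over the cohort", {
  m <- loadManifest(file.path(tinyCohortDir, "manifest.csv"))
  cfg <- runConfig(threshold = 0.9)
  out <- file.path(tempdir(), "sens")
  scan <- runSensitivity(m, cfg, c(0.81, 0.86, 0.90), outDir = out)
  expect_true(all(diff(scan$nFlagged) >= 0))
  expect_true(all(c("tp", "fp", "fn", "tn") %in% names(scan)))
  expect_true(file.exists(file.path(out, "sensitivity.csv")))
})

test_that("run configuration round-trips through YAML", {
  y <- file.path(tempdir(), "cfg.yaml")
  writeLines(c("target_label: 2",
               "statistic: median",
               "task_name: kidney tumor MR",
               "threshold:",
               "  source_values: [0.87, 0.78]"), y)
  cfg <- readRunConfig(y)
  expect_equal(thresholdValue(cfg$threshold), 0.825)
  expect_identical(cfg$statistic, "median")
  expect_equal(cfg$performanceThreshold, 0.825)
  # explicit value wins over derivation, and performance threshold separates
  writeLines(c("threshold:", "  value: 0.9", "performance_threshold: 0.8"), y)
  cfg2 <- readRunConfig(y)
  expect_equal(thresholdValue(cfg2$threshold), 0.9)
  expect_equal(cfg2$performanceThreshold, 0.8)
  expect_error(runConfig(), "threshold value or interobserver")
})

test_that("the packaged default cohort config parses into the default spec", {
  y <- system.file("extdata", "default_cohort.yaml", package = "interfoldQC")
  spec <- interfoldQC:::.cohortSpecFromYaml(y)
  ref <- defaultCohortSpec()
  expect_equal(spec[c("nIn", "nOut", "kFolds", "masterSeed")],
               ref[c("nIn", "nOut", "kFolds", "masterSeed")])
  expect_equal(unclass(spec$inPert), unclass(ref$inPert))
  expect_equal(unclass(spec$outPert), unclass(ref$outPert))
  expect_equal(spec$phantom, ref$phantom)
})
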
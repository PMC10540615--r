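## End-to-end workflows: flag (reference-free), evaluate (with references),
## sensitivity scan, simulate. Per-case failures are data, not crashes: a QC
## tool must not die on one bad case.

.log <- function(...) message(sprintf(...))

# fixed 6-decimal float formatting; keeps reports byte-stable across reruns
.fmt <- function(x) {
  ifelse(is.na(x), "", formatC(x, format = "f", digits = 6))
}

.pairColumns <- function(kMax) {
  nm <- character(0L)
  for (i in seq_len(kMax - 1L))
    for (j in seq.int(i + 1L, kMax)) nm <- c(nm, sprintf("dice_%d_%d", i, j))
  nm
}

# one report row per case (numeric columns; formatting happens on write)
.caseRow <- function(caseId, k, result, decision, kMax, status = "ok",
                     message = "") {
  row <- list(case_id = caseId, k = k, status = status)
  pcols <- .pairColumns(kMax)
  vals <- stats::setNames(rep(NA_real_, length(pcols)), pcols)
  if (!is.null(result)) {
    pw <- result@pairwise
    names(pw) <- sub("-", "_", paste0("dice_", names(pw)))
    vals[names(pw)] <- pw
    row <- c(row, as.list(vals),
             list(mean = result@summaries[["mean"]],
                  median = result@summaries[["median"]],
                  min = result@summaries[["min"]],
                  max = result@summaries[["max"]]))
  } else {
    row <- c(row, as.list(vals),
             list(mean = NA_real_, median = NA_real_, min = NA_real_,
                  max = NA_real_))
  }
  if (!is.null(decision)) {
    row <- c(row, list(statistic = decision@statistic,
                       summary_value = decision@summaryValue,
                       threshold = decision@threshold,
                       flagged = decision@flagged))
  } else {
    row <- c(row, list(statistic = NA_character_, summary_value = NA_real_,
                       threshold = NA_real_, flagged = NA))
  }
  row$message <- message
  as.data.frame(row, stringsAsFactors = FALSE)
}

.writeReport <- function(report, path) {
  out <- report
  for (cn in names(out))
    if (is.numeric(out[[cn]]) && !cn %in% c("k"))
      out[[cn]] <- .fmt(out[[cn]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

.provenance <- function(config) {
  th <- config$threshold
  list(package = "interfoldQC",
       version = as.character(utils::packageVersion("interfoldQC")),
       task_name = config$taskName,
       target_label = config$targetLabel,
       statistic = config$statistic,
       threshold = list(value = th@value,
                        source_values = th@sourceValues,
                        rounding_decimals = th@roundingDecimals,
                        derivation = th@derivation),
       performance_threshold = config$performanceThreshold,
       both_empty_dice = config$bothEmptyDice)
}

#' Run the reference-free flagging workflow
#'
#' For every case in the manifest: load the K fold predictions, compute the
#' pairwise interfold Dices and their summaries, apply the flagging rule, and
#' reconstruct the ensemble prediction (probability averaging when soft
#' fields are listed, label vote otherwise), written as NIfTI under
#' \code{outDir/ensembles}. No reference standard is needed. A case whose
#' grids mismatch (or that fails for any other reason) is recorded as failed
#' and the run continues.
#'
#' @param manifest a [loadManifest()] result or a manifest CSV path.
#' @param config a [runConfig()].
#' @param outDir output directory for \code{report.csv},
#'   \code{summary.json} and the ensemble NIfTIs; \code{NULL} skips writing.
#' @param verbose log per-case progress to standard error.
#' @return invisibly, a list with \code{report} (one row per case, manifest
#'   order), \code{results} (InterfoldResult per ok case), \code{decisions},
#'   \code{ensembles} (paths or in-memory predictions) and \code{summary}.
#' @export
runFlag <- function(manifest, config, outDir = NULL, verbose = FALSE) {
  if (is.character(manifest)) manifest <- loadManifest(manifest)
  stopifnot(inherits(manifest, "qcManifest"), inherits(config, "runConfig"))
  if (!is.null(outDir)) {
    dir.create(file.path(outDir, "ensembles"), recursive = TRUE,
               showWarnings = FALSE)
  }
  kMax <- max(vapply(manifest$foldPaths, length, integer(1L)))
  rows <- list(); results <- list(); decisions <- list(); ensembles <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, , drop = FALSE]
    cid <- row$case_id
    res <- tryCatch({
      fs <- .loadFoldSet(row, config$targetLabel, withReference = FALSE)
      ir <- interfoldDices(fs, config$targetLabel,
                           bothEmpty = config$bothEmptyDice)
      dec <- flagCase(ir, config$threshold, config$statistic)
      ens <- if (length(fs@probabilities))
        ensembleFromProbabilities(fs@probabilities)
      else ensembleFromLabels(fs@folds)
      if (!is.null(outDir)) {
        ep <- file.path(outDir, "ensembles", paste0(cid, ".nii.gz"))
        writeLabelVolume(ens@labelVolume, ep)
      }
      if (verbose) .log("[%s] %s=%.4f -> %s", cid, config$statistic,
                        dec@summaryValue,
                        if (dec@flagged) "FLAGGED" else "ok")
      list(ir = ir, dec = dec, ens = ens)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (verbose) .log("[%s] FAILED: %s", cid, conditionMessage(res))
      rows[[i]] <- .caseRow(cid, length(row$foldPaths[[1L]]), NULL, NULL,
                            kMax, status = "failed",
                            message = conditionMessage(res))
    } else {
      rows[[i]] <- .caseRow(cid, res$ir@k, res$ir, res$dec, kMax)
      results[[cid]] <- res$ir
      decisions[[cid]] <- res$dec
      ensembles[[cid]] <- res$ens
    }
  }
  report <- do.call(rbind, rows)
  flags <- report$flagged[report$status == "ok"]
  summary <- list(provenance = .provenance(config),
                  n_cases = nrow(report),
                  n_ok = sum(report$status == "ok"),
                  n_failed = sum(report$status == "failed"),
                  n_flagged = sum(flags, na.rm = TRUE))
  if (!is.null(outDir)) {
    .writeReport(report, file.path(outDir, "report.csv"))
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = 6, pretty = TRUE,
                         null = "null")
  }
  invisible(list(report = report, results = results, decisions = decisions,
                 ensembles = ensembles, summary = summary))
}

#' Run the evaluation workflow against reference standards
#'
#' Everything [runFlag()] does, plus: the ensemble prediction of each case is
#' scored against its reference (Dice on the target label), each flagging
#' decision is classified TP/FP/FN/TN against the performance threshold, and
#' the run summary gains the confusion matrix, flagged/non-flagged cohort
#' statistics and (when a numeric feature column such as
#' \code{tumor_volume_ml} is present) a flag-rate stratification. Cases
#' without a reference are still flagged but excluded from evaluation with a
#' warning.
#'
#' @inheritParams runFlag
#' @param plots write scatter (summary vs ensemble Dice) and confusion-matrix
#'   PNGs under \code{outDir}; defaults to the config's \code{plots} switch.
#' @return invisibly, the [runFlag()] list extended with \code{confusion}
#'   (a \linkS4class{ConfusionCounts}), \code{cohort} (a
#'   \linkS4class{CohortSummary}) and an extended per-case report
#'   (\code{ensemble_dice}, \code{outcome}).
#' @export
runEvaluate <- function(manifest, config, outDir = NULL,
                        plots = NULL, verbose = FALSE) {
  if (is.character(manifest)) manifest <- loadManifest(manifest)
  stopifnot(inherits(manifest, "qcManifest"), inherits(config, "runConfig"))
  if (is.null(plots)) plots <- config$plots
  run <- runFlag(manifest, config, outDir = outDir, verbose = verbose)
  report <- run$report
  report$ensemble_dice <- NA_real_
  report$outcome <- NA_character_
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, , drop = FALSE]
    cid <- row$case_id
    if (report$status[i] != "ok") next
    if (is.na(row$referencePath)) {
      warning("case '", cid, "' has no reference; excluded from evaluation",
              call. = FALSE)
      next
    }
    ref <- readLabelVolume(row$referencePath, caseId = cid)
    ens <- run$ensembles[[cid]]@labelVolume
    vocab <- sort(unique(c(ref@labels, ens@labels, config$targetLabel)))
    ref@labels <- vocab; ens@labels <- vocab
    ed <- diceScore(ens, ref, config$targetLabel,
                    bothEmpty = config$bothEmptyDice)
    report$ensemble_dice[i] <- ed
    report$outcome[i] <- classifyOutcome(report$flagged[i], ed,
                                         config$performanceThreshold)
  }
  ev <- !is.na(report$outcome)
  confusion <- if (any(ev)) confusionCounts(report$outcome[ev]) else NULL
  cohort <- if (any(ev)) cohortStats(report$ensemble_dice[ev],
                                     report$flagged[ev]) else NULL
  strat <- NULL
  featureCol <- intersect(c("tumor_volume_ml"),
                          names(manifest)[vapply(manifest, is.numeric,
                                                 logical(1L))])
  if (any(ev) && length(featureCol))
    strat <- stratifyFlagsByFeature(report$flagged[ev],
                                    manifest[[featureCol[1L]]][ev])
  summary <- run$summary
  if (!is.null(confusion))
    summary$confusion <- as.list(counts(confusion))
  if (!is.null(cohort))
    summary$cohort <- list(
      n_flagged = cohort@nFlagged, n_total = cohort@nTotal,
      flagged_mean = cohort@flaggedMean, flagged_sd = cohort@flaggedSd,
      nonflagged_mean = cohort@nonflaggedMean,
      nonflagged_sd = cohort@nonflaggedSd,
      overall_mean = cohort@overallMean, overall_sd = cohort@overallSd)
  if (!is.null(outDir)) {
    .writeReport(report, file.path(outDir, "report.csv"))
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = 6, pretty = TRUE,
                         null = "null")
    if (plots && any(ev)) {
      grDevices::png(file.path(outDir, "scatter.png"), 800, 600)
      plotFlagScatter(report$summary_value[ev], report$ensemble_dice[ev],
                      config$threshold@value, config$performanceThreshold,
                      config$statistic)
      grDevices::dev.off()
      grDevices::png(file.path(outDir, "confusion.png"), 500, 500)
      plotConfusionMatrix(confusion)
      grDevices::dev.off()
    }
  }
  invisible(c(run[c("results", "decisions", "ensembles")],
              list(report = report, confusion = confusion, cohort = cohort,
                   stratification = strat, summary = summary)))
}

#' Run a threshold sensitivity scan over a manifest
#'
#' Computes the interfold results once and applies [sensitivityScan()] at the
#' given thresholds; when references are present, ensemble Dices are scored
#' and per-threshold confusion matrices added (performance threshold from
#' the config, held fixed across scanned thresholds).
#'
#' @inheritParams runFlag
#' @param thresholds numeric vector of flagging thresholds to scan.
#' @return invisibly, the scan data.frame (also written as
#'   \code{sensitivity.csv} when \code{outDir} is given).
#' @export
runSensitivity <- function(manifest, config, thresholds, outDir = NULL,
                           verbose = FALSE) {
  if (is.character(manifest)) manifest <- loadManifest(manifest)
  hasRefs <- any(!is.na(manifest$referencePath))
  run <- if (hasRefs) runEvaluate(manifest, config, outDir = NULL,
                                  plots = FALSE, verbose = verbose)
  else runFlag(manifest, config, outDir = NULL, verbose = verbose)
  ok <- run$report$status == "ok"
  results <- run$results[run$report$case_id[ok]]
  dices <- if (hasRefs) run$report$ensemble_dice[ok] else NULL
  scan <- sensitivityScan(results, thresholds, statistic = config$statistic,
                          ensembleDices = dices,
                          performanceThreshold = config$performanceThreshold)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    out <- scan
    out$flaggedCases <- vapply(scan$flaggedCases, paste, character(1L),
                               collapse = ";")
    out$threshold <- .fmt(out$threshold)
    utils::write.csv(out, file.path(outDir, "sensitivity.csv"),
                     row.names = FALSE)
  }
  invisible(scan)
}

#' Simulate a cohort and write it to disk
#'
#' Convenience wrapper: [simulateCohort()] then [writeCohort()]. The written
#' manifest round-trips through [runFlag()] / [runEvaluate()] without edits.
#'
#' @param spec a [cohortSpec()], or a path to a cohort YAML (as written by
#'   [writeCohort()]).
#' @param outDir dataset directory to create.
#' @param withProbabilities also write per-fold soft probability fields.
#' @return invisibly, the manifest path.
#' @export
runSimulate <- function(spec, outDir, withProbabilities = FALSE) {
  if (is.character(spec)) spec <- .cohortSpecFromYaml(spec)
  cohort <- simulateCohort(spec, withProbabilities = withProbabilities)
  writeCohort(cohort, outDir)
}

.cohortSpecFromYaml <- function(path) {
  y <- yaml::read_yaml(path)
  pc <- function(b) perturbationConfig(
    boundaryRadiusVoxels = b$boundaryRadiusVoxels %||% 0L,
    shiftVoxels = b$shiftVoxels %||% 0L,
    missProb = b$missProb %||% 0,
    softSigmaMm = b$softSigmaMm %||% 0,
    seed = b$seed %||% 1L)
  cohortSpec(nIn = y$n_in_distribution %||% 30L,
             nOut = y$n_out_of_distribution %||% 30L,
             inPert = pc(y$in_dist), outPert = pc(y$out_dist),
             kFolds = y$k_folds %||% 5L,
             masterSeed = y$master_seed %||% 42L,
             phantom = y$phantom %||% list())
}
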
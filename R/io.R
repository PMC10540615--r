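## NIfTI round-tripping, manifest handling and run configuration.

# strip image classes/attributes down to a plain numeric array
.plainArray <- function(img) {
  a <- as.array(img)
  array(as.vector(a), dim(a))
}

#' Read a label volume from a NIfTI file
#'
#' Reads an integer-valued NIfTI-1 volume; voxel spacing is taken from the
#' header (pixdim). Orientation metadata is not interpreted beyond spacing:
#' fold predictions of one model on one image share a grid by construction.
#'
#' @param path path to a .nii or .nii.gz file.
#' @param labels optional label vocabulary; defaults to the values present.
#' @param caseId,foldId identifiers to attach.
#' @return a \linkS4class{LabelVolume}.
#' @export
readLabelVolume <- function(path, labels = NULL, caseId = NULL,
                            foldId = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  vox <- .plainArray(img)
  if (length(dim(vox)) == 4L && dim(vox)[4L] == 1L)
    vox <- array(vox, dim(vox)[1:3])
  if (length(dim(vox)) != 3L)
    stop("expected a 3D label volume in ", path)
  if (is.null(caseId))
    caseId <- sub("\\.nii(\\.gz)?$", "", basename(path))
  LabelVolume(round(vox), spacing = RNifti::pixdim(img)[1:3],
              labels = labels, caseId = caseId, foldId = foldId)
}

#' Write a label volume to a NIfTI file
#'
#' @param v a \linkS4class{LabelVolume}.
#' @param path output path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
writeLabelVolume <- function(v, path) {
  img <- RNifti::asNifti(v@voxels)
  RNifti::pixdim(img) <- v@spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a probability volume from NIfTI
#'
#' Soft predictions come in two dialects that map to the same object: one 4D
#' file with the class axis last, or one scalar 3D file per class.
#'
#' @param paths a single 4D NIfTI path, or a vector of per-class 3D paths
#'   ordered to match \code{classLabels}.
#' @param classLabels integer class labels for the class axis.
#' @param caseId,foldId identifiers to attach.
#' @return a \linkS4class{ProbabilityVolume}.
#' @export
readProbabilityVolume <- function(paths, classLabels, caseId = "case",
                                  foldId = NA_character_) {
  for (p in paths) if (!file.exists(p)) stop("no such file: ", p)
  if (length(paths) == 1L) {
    img <- RNifti::readNifti(paths)
    arr <- .plainArray(img)
    if (length(dim(arr)) != 4L)
      stop("expected a 4D probability volume in ", paths)
    sp <- RNifti::pixdim(img)[1:3]
  } else {
    if (length(paths) != length(classLabels))
      stop("need one per-class file per class label")
    imgs <- lapply(paths, RNifti::readNifti)
    sp <- RNifti::pixdim(imgs[[1L]])[1:3]
    d <- dim(.plainArray(imgs[[1L]]))
    arr <- array(0, c(d, length(paths)))
    for (i in seq_along(imgs)) arr[, , , i] <- .plainArray(imgs[[i]])
  }
  ProbabilityVolume(arr, classLabels, sp, caseId = caseId, foldId = foldId)
}

#' Write a probability volume as one 4D NIfTI file
#'
#' @param p a \linkS4class{ProbabilityVolume}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeProbabilityVolume <- function(p, path) {
  img <- RNifti::asNifti(p@probs)
  RNifti::pixdim(img) <- c(p@spacing, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

## ---- manifest -------------------------------------------------------------

.splitPaths <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0L) else strsplit(x, ";", fixed = TRUE)[[1L]]
}

#' Load and validate a case manifest
#'
#' The manifest is a CSV with one row per case: \code{case_id}, \code{folds}
#' (semicolon-delimited paths to the K per-fold label NIfTIs), optional
#' \code{probs} (semicolon-delimited per-fold probability NIfTIs), optional
#' \code{reference} (reference-standard NIfTI), and any further columns kept
#' as per-case features (e.g. \code{tumor_volume_ml}, \code{arm}). Explicit
#' listing beats directory-convention discovery for clinical pipelines.
#' Malformed rows (fewer than two folds, missing files, duplicate case ids)
#' are reported together, naming each offending case.
#'
#' @param path path to the manifest CSV. Relative volume paths are resolved
#'   against the manifest's directory.
#' @return a data.frame of class \code{"qcManifest"} with list-columns
#'   \code{foldPaths} and \code{probPaths}.
#' @export
loadManifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("case_id", "folds") %in% names(df)))
    stop("manifest must have columns case_id and folds")
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (!length(p)) return(character(0L))
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  problems <- character(0L)
  dup <- df$case_id[duplicated(df$case_id)]
  if (length(dup))
    problems <- c(problems, paste0("duplicate case_id: ",
                                   paste(unique(dup), collapse = ", ")))
  foldPaths <- vector("list", nrow(df))
  probPaths <- vector("list", nrow(df))
  refPath <- rep(NA_character_, nrow(df))
  for (i in seq_len(nrow(df))) {
    fp <- resolve(.splitPaths(df$folds[i]))
    if (length(fp) < 2L)
      problems <- c(problems, sprintf(
        "case '%s' (row %d): fewer than 2 fold predictions", df$case_id[i], i))
    missing <- fp[!file.exists(fp)]
    if (length(missing))
      problems <- c(problems, sprintf("case '%s' (row %d): missing file(s) %s",
                                      df$case_id[i], i,
                                      paste(missing, collapse = ", ")))
    foldPaths[[i]] <- fp
    if ("probs" %in% names(df)) {
      pp <- resolve(.splitPaths(df$probs[i]))
      missing <- pp[!file.exists(pp)]
      if (length(missing))
        problems <- c(problems, sprintf(
          "case '%s' (row %d): missing probability file(s) %s",
          df$case_id[i], i, paste(missing, collapse = ", ")))
      probPaths[[i]] <- pp
    } else probPaths[[i]] <- character(0L)
    if ("reference" %in% names(df) && !is.na(df$reference[i]) &&
        nzchar(df$reference[i])) {
      rp <- resolve(df$reference[i])
      if (!file.exists(rp))
        problems <- c(problems, sprintf(
          "case '%s' (row %d): missing reference %s", df$case_id[i], i, rp))
      refPath[i] <- rp
    }
  }
  if (length(problems))
    stop("invalid manifest:\n  ", paste(problems, collapse = "\n  "))
  out <- df[, setdiff(names(df), c("folds", "probs", "reference")),
            drop = FALSE]
  out$foldPaths <- I(foldPaths)
  out$probPaths <- I(probPaths)
  out$referencePath <- refPath
  class(out) <- c("qcManifest", "data.frame")
  out
}

# materialize one manifest row as a FoldSet
.loadFoldSet <- function(row, targetLabel, withReference = TRUE) {
  labels <- NULL  # vocabulary inferred per volume, then unioned
  folds <- lapply(seq_along(row$foldPaths[[1L]]), function(i)
    readLabelVolume(row$foldPaths[[1L]][i], caseId = row$case_id,
                    foldId = as.character(i)))
  vocab <- sort(unique(c(unlist(lapply(folds, slot, "labels")),
                         as.integer(targetLabel))))
  folds <- lapply(folds, function(f) { f@labels <- vocab; f })
  ref <- NULL
  if (withReference && !is.na(row$referencePath)) {
    ref <- readLabelVolume(row$referencePath, caseId = row$case_id)
    ref@labels <- sort(unique(c(ref@labels, vocab)))
  }
  probs <- list()
  pp <- row$probPaths[[1L]]
  if (length(pp)) {
    k <- length(folds)
    if (length(pp) == k) {
      probs <- lapply(seq_len(k), function(i)
        readProbabilityVolume(pp[i], classLabels = vocab,
                              caseId = row$case_id, foldId = as.character(i)))
    } else if (length(pp) == k * length(vocab)) {
      # one scalar file per class, grouped per fold in class order
      probs <- lapply(seq_len(k), function(i) {
        sel <- pp[seq.int((i - 1L) * length(vocab) + 1L, i * length(vocab))]
        readProbabilityVolume(sel, classLabels = vocab, caseId = row$case_id,
                              foldId = as.character(i))
      })
    } else stop("case '", row$case_id,
                "': probability paths must be one 4D file per fold, ",
                "or one 3D file per fold and class")
  }
  FoldSet(folds, probabilities = probs, reference = ref,
          caseId = row$case_id)
}

## ---- run configuration ----------------------------------------------------

#' Assemble a run configuration
#'
#' Collects the user-facing choices of a QC run: which label to monitor,
#' which summary statistic, and the flagging threshold (an explicit value or
#' interobserver source values to derive it from), plus the performance
#' threshold used in evaluation mode (defaulting to the flagging threshold,
#' as in the standard scatter/confusion displays).
#'
#' @param targetLabel integer label whose disagreement is monitored.
#' @param statistic summary statistic (default \code{"median"}).
#' @param threshold explicit threshold value in [0, 1], or \code{NULL} to
#'   derive from \code{sourceValues}.
#' @param sourceValues interobserver source values/ranges (see
#'   [deriveThreshold()]); ignored when \code{threshold} is given.
#' @param roundingDecimals optional half-up rounding for the derived value.
#' @param performanceThreshold good/poor ensemble cutoff for evaluation;
#'   defaults to the flagging threshold.
#' @param taskName task label for provenance.
#' @param plots whether evaluation writes scatter/confusion PNGs.
#' @param bothEmptyDice Dice convention for fold pairs empty at the target
#'   label on both sides (1, the default, or 0).
#' @return a list of class \code{"runConfig"} carrying a
#'   \linkS4class{ThresholdSpec}.
#' @export
runConfig <- function(targetLabel = 2L,
                      statistic = c("median", "mean", "min", "max"),
                      threshold = NULL, sourceValues = NULL,
                      roundingDecimals = NULL, performanceThreshold = NULL,
                      taskName = "", plots = FALSE, bothEmptyDice = 1) {
  statistic <- match.arg(statistic)
  spec <- if (!is.null(threshold)) .asThresholdSpec(threshold, taskName)
  else if (!is.null(sourceValues))
    deriveThreshold(sourceValues, taskName, roundingDecimals)
  else stop("provide either a threshold value or interobserver sourceValues")
  if (is.null(performanceThreshold)) performanceThreshold <- spec@value
  stopifnot(performanceThreshold >= 0, performanceThreshold <= 1,
            bothEmptyDice %in% c(0, 1))
  structure(list(targetLabel = as.integer(targetLabel), statistic = statistic,
                 threshold = spec,
                 performanceThreshold = as.numeric(performanceThreshold),
                 taskName = taskName, plots = isTRUE(plots),
                 bothEmptyDice = bothEmptyDice),
            class = "runConfig")
}

#' Read a run configuration from YAML
#'
#' Expected keys: \code{target_label}, \code{statistic}, and a
#' \code{threshold} block with either \code{value} or \code{source_values}
#' (+ optional \code{rounding_decimals}), plus optional
#' \code{performance_threshold}, \code{task_name}, \code{plots},
#' \code{both_empty_dice}.
#'
#' @param path path to a YAML file.
#' @return a [runConfig()].
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  th <- y$threshold
  runConfig(targetLabel = y$target_label %||% 2L,
            statistic = y$statistic %||% "median",
            threshold = th$value,
            sourceValues = th$source_values,
            roundingDecimals = th$rounding_decimals,
            performanceThreshold = y$performance_threshold,
            taskName = y$task_name %||% "",
            plots = isTRUE(y$plots),
            bothEmptyDice = y$both_empty_dice %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a simulated cohort as a self-contained dataset directory
#'
#' Writes NIfTI truths and per-fold label (and, when present, probability)
#' volumes, a manifest CSV consumable by [runFlag()] / [runEvaluate()]
#' without edits, and the generating configuration as YAML for provenance.
#'
#' @param cohort a \code{"qcCohort"} from [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "qcCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$cases, function(cs) {
    fs <- cs$foldSet
    cdir <- file.path(dir, cs$caseId)
    dir.create(cdir, showWarnings = FALSE)
    refFile <- file.path(cdir, "truth.nii.gz")
    writeLabelVolume(fs@reference, refFile)
    foldFiles <- vapply(seq_along(fs@folds), function(i) {
      f <- file.path(cdir, sprintf("fold_%d.nii.gz", i))
      writeLabelVolume(fs@folds[[i]], f)
      f
    }, character(1L))
    probFiles <- character(0L)
    if (length(fs@probabilities))
      probFiles <- vapply(seq_along(fs@probabilities), function(i) {
        f <- file.path(cdir, sprintf("probs_%d.nii.gz", i))
        writeProbabilityVolume(fs@probabilities[[i]], f)
        f
      }, character(1L))
    data.frame(case_id = cs$caseId,
               folds = paste(.relPath(foldFiles, dir), collapse = ";"),
               probs = paste(.relPath(probFiles, dir), collapse = ";"),
               reference = .relPath(refFile, dir),
               arm = cs$arm,
               tumor_volume_ml = cs$tumorVolumeMl,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  manifestPath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifestPath, row.names = FALSE)
  sp <- cohort$spec
  yaml::write_yaml(list(
    n_in_distribution = sp$nIn, n_out_of_distribution = sp$nOut,
    k_folds = sp$kFolds, master_seed = sp$masterSeed,
    in_dist = unclass(sp$inPert), out_dist = unclass(sp$outPert),
    phantom = sp$phantom), file.path(dir, "cohort_config.yaml"))
  invisible(manifestPath)
}

.relPath <- function(paths, base) {
  if (!length(paths)) return(character(0L))
  base <- paste0(normalizePath(base), "/")
  vapply(paths, function(p) sub(base, "", normalizePath(p), fixed = TRUE),
         character(1L), USE.NAMES = FALSE)
}
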
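#' Construct a LabelVolume
#'
#' @param voxels a 3D array of non-negative integer label values (numeric
#'   arrays are coerced to integer storage; values must already be whole
#'   numbers).
#' @param spacing numeric(3): voxel edge lengths in mm, all positive.
#' @param labels permitted label values; defaults to the values present in
#'   \code{voxels}.
#' @param caseId,foldId identifiers; \code{foldId} is \code{NA} for volumes
#'   that are not fold predictions (references, truths, ensembles).
#' @return a \linkS4class{LabelVolume}.
#' @examples
#' v <- LabelVolume(array(0L, c(4, 4, 2)), spacing = c(1, 1, 5))
#' labelVolumeMl(v, 0L)
#' @export
LabelVolume <- function(voxels, spacing = c(1, 1, 1), labels = NULL,
                        caseId = "case", foldId = NA_character_) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array")
  if (!is.integer(voxels)) {
    if (any(abs(voxels - round(voxels)) > 1e-8))
      stop("voxel values must be whole numbers")
    storage.mode(voxels) <- "integer"
  }
  if (is.null(labels)) labels <- sort(unique(as.vector(voxels)))
  new("LabelVolume", voxels = voxels, spacing = as.numeric(spacing),
      labels = as.integer(labels), caseId = as.character(caseId),
      foldId = as.character(foldId))
}

#' Construct a ProbabilityVolume
#'
#' @param probs 4D numeric array, spatial dimensions first, class axis last.
#' @param classLabels integer label values matching the class axis.
#' @param spacing numeric(3): voxel spacing in mm.
#' @param caseId,foldId identifiers.
#' @return a \linkS4class{ProbabilityVolume}.
#' @export
ProbabilityVolume <- function(probs, classLabels, spacing = c(1, 1, 1),
                              caseId = "case", foldId = NA_character_) {
  new("ProbabilityVolume", probs = probs, classLabels = as.integer(classLabels),
      spacing = as.numeric(spacing), caseId = as.character(caseId),
      foldId = as.character(foldId))
}

#' Construct a FoldSet
#'
#' @param folds list of K \linkS4class{LabelVolume} fold predictions (K >= 2)
#'   on a shared grid.
#' @param probabilities optional list of K matching
#'   \linkS4class{ProbabilityVolume} objects.
#' @param reference optional reference-standard \linkS4class{LabelVolume}.
#' @param caseId case identifier; defaults to the first fold's.
#' @return a \linkS4class{FoldSet}.
#' @export
FoldSet <- function(folds, probabilities = list(), reference = NULL,
                    caseId = NULL) {
  if (is.null(caseId)) {
    caseId <- if (length(folds)) folds[[1L]]@caseId else "case"
  }
  new("FoldSet", caseId = as.character(caseId), folds = folds,
      probabilities = probabilities, reference = reference)
}

## ---- accessors ------------------------------------------------------------

#' @rdname LabelVolume-class
#' @export
setMethod("voxels", "LabelVolume", function(x) x@voxels)

#' @rdname LabelVolume-class
#' @export
setMethod("voxelSpacing", "LabelVolume", function(x) x@spacing)

#' @rdname ProbabilityVolume-class
#' @export
setMethod("voxelSpacing", "ProbabilityVolume", function(x) x@spacing)

#' @rdname LabelVolume-class
#' @export
setMethod("labelValues", "LabelVolume", function(x) x@labels)

#' @rdname ProbabilityVolume-class
#' @export
setMethod("labelValues", "ProbabilityVolume", function(x) x@classLabels)

#' @rdname LabelVolume-class
#' @export
setMethod("caseId", "LabelVolume", function(x) x@caseId)

#' @rdname ProbabilityVolume-class
#' @export
setMethod("caseId", "ProbabilityVolume", function(x) x@caseId)

#' @rdname FoldSet-class
#' @export
setMethod("caseId", "FoldSet", function(x) x@caseId)

#' @rdname InterfoldResult-class
#' @export
setMethod("caseId", "InterfoldResult", function(x) x@caseId)

#' @rdname FlagDecision-class
#' @export
setMethod("caseId", "FlagDecision", function(x) x@caseId)

#' @rdname LabelVolume-class
#' @export
setMethod("foldId", "LabelVolume", function(x) x@foldId)

#' @rdname FoldSet-class
#' @export
setMethod("nFolds", "FoldSet", function(x) length(x@folds))

#' @rdname FoldSet-class
#' @export
setMethod("foldPredictions", "FoldSet", function(x) x@folds)

#' @rdname FoldSet-class
#' @export
setMethod("foldProbabilities", "FoldSet", function(x) x@probabilities)

#' @rdname FoldSet-class
#' @export
setMethod("referenceVolume", "FoldSet", function(x) x@reference)

#' @rdname InterfoldResult-class
#' @export
setMethod("pairwiseDices", "InterfoldResult", function(x) x@pairwise)

#' @rdname InterfoldResult-class
#' @export
setMethod("diceSummaries", "InterfoldResult", function(x) x@summaries)

#' @rdname ThresholdSpec-class
#' @export
setMethod("thresholdValue", "ThresholdSpec", function(x) x@value)

#' @rdname FlagDecision-class
#' @export
setMethod("isFlagged", "FlagDecision", function(x) x@flagged)

#' @rdname ConfusionCounts-class
#' @export
setMethod("counts", "ConfusionCounts", function(x)
  c(tp = x@tp, fp = x@fp, fn = x@fn, tn = x@tn))

## ---- show methods ---------------------------------------------------------

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("LabelVolume '%s'%s: %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
              object@caseId,
              if (is.na(object@foldId)) "" else sprintf(" (fold %s)", object@foldId),
              d[1L], d[2L], d[3L],
              object@spacing[1L], object@spacing[2L], object@spacing[3L]))
  cat("  labels:", paste(object@labels, collapse = ", "), "\n")
})

setMethod("show", "ProbabilityVolume", function(object) {
  d <- dim(object@probs)
  cat(sprintf("ProbabilityVolume '%s': %d x %d x %d voxels, %d classes (%s)\n",
              object@caseId, d[1L], d[2L], d[3L], d[4L],
              paste(object@classLabels, collapse = ", ")))
})

setMethod("show", "FoldSet", function(object) {
  cat(sprintf("FoldSet '%s': %d folds%s%s\n", object@caseId,
              length(object@folds),
              if (length(object@probabilities)) " + soft fields" else "",
              if (is.null(object@reference)) "" else " + reference"))
})

setMethod("show", "InterfoldResult", function(object) {
  s <- object@summaries
  cat(sprintf("InterfoldResult '%s' (label %d, k = %d): %d pairwise Dices\n",
              object@caseId, object@targetLabel, object@k,
              length(object@pairwise)))
  cat(sprintf("  mean %.3f | median %.3f | min %.3f | max %.3f\n",
              s[["mean"]], s[["median"]], s[["min"]], s[["max"]]))
})

setMethod("show", "ThresholdSpec", function(object) {
  cat(sprintf("ThresholdSpec '%s': %.6g\n", object@taskName, object@value))
  if (length(object@sourceValues))
    cat("  derived from:",
        paste(vapply(object@sourceValues, function(v)
          paste(format(v), collapse = "-"), character(1L)), collapse = ", "),
        "\n")
  if (nzchar(object@derivation)) cat(" ", object@derivation, "\n")
})

setMethod("show", "FlagDecision", function(object) {
  cat(sprintf("FlagDecision '%s': %s interfold Dice %.4f %s threshold %.4f -> %s\n",
              object@caseId, object@statistic, object@summaryValue,
              if (object@flagged) "<" else ">=", object@threshold,
              if (object@flagged) "FLAGGED for review" else "not flagged"))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts (n = %d)\n", object@n))
  m <- matrix(c(object@tp, object@fp, object@fn, object@tn), 2L, byrow = TRUE,
              dimnames = list(c("flagged", "not flagged"),
                              c("poor", "good")))
  print(m)
})

setMethod("show", "CohortSummary", function(object) {
  fmt <- function(m, s) {
    if (is.na(m)) "absent" else sprintf("%.3f +/- %.3f", m, s)
  }
  cat(sprintf("CohortSummary: %d / %d flagged\n", object@nFlagged,
              object@nTotal))
  cat("  overall    :", fmt(object@overallMean, object@overallSd), "\n")
  cat("  flagged    :", fmt(object@flaggedMean, object@flaggedSd), "\n")
  cat("  non-flagged:", fmt(object@nonflaggedMean, object@nonflaggedSd), "\n")
})
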
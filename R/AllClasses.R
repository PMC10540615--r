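#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' LabelVolume: a dense 3D integer segmentation
#'
#' The unit of segmentation: a 3D grid of non-negative integer labels
#' (0 = background) with physical voxel spacing in millimetres and a declared
#' label vocabulary. Per-fold sub-model predictions, reference standards and
#' phantom ground truths are all \code{LabelVolume} objects.
#'
#' @slot voxels 3D integer array of label values.
#' @slot spacing numeric(3), voxel edge lengths in mm (all > 0).
#' @slot labels integer vector of permitted label values (must include every
#'   value present in \code{voxels}).
#' @slot caseId character scalar identifying the case.
#' @slot foldId character scalar identifying the cross-validation fold
#'   (\code{NA} for references, truths and ensembles).
#'
#' @seealso [LabelVolume()], [diceScore()], [labelVolumeMl()]
#' @name LabelVolume-class
#' @rdname LabelVolume-class
#' @exportClass LabelVolume
setClass("LabelVolume",
  representation(
    voxels  = "array",
    spacing = "numeric",
    labels  = "integer",
    caseId  = "character",
    foldId  = "character"
  )
)

setValidity("LabelVolume", function(object) {
  msg <- character()
  d <- dim(object@voxels)
  if (length(d) != 3L || any(d < 1L))
    msg <- c(msg, "voxels must be a 3D array with each dimension >= 1")
  if (!is.integer(object@voxels))
    msg <- c(msg, "voxels must have integer storage")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive finite values (mm)")
  if (any(object@labels < 0L))
    msg <- c(msg, "labels must be non-negative")
  if (is.integer(object@voxels) &&
      !all(unique(as.vector(object@voxels)) %in% object@labels))
    msg <- c(msg, "every voxel value must be a member of the label vocabulary")
  if (length(msg)) msg else TRUE
})

#' ProbabilityVolume: per-class soft predictions on a grid
#'
#' A 4D field of class probabilities (three spatial dimensions plus a class
#' axis) as produced by the softmax layer of a segmentation network; the input
#' to probability-averaging ensembling. Probabilities are in [0, 1] and sum to
#' 1 over classes at every voxel (to a tolerance of 1e-5).
#'
#' @slot probs 4D numeric array, spatial dims first, class axis last.
#' @slot classLabels integer vector matching the class axis (must contain the
#'   background label 0).
#' @slot spacing numeric(3), voxel spacing in mm.
#' @slot caseId,foldId character identifiers.
#'
#' @seealso [ProbabilityVolume()], [ensembleFromProbabilities()]
#' @name ProbabilityVolume-class
#' @rdname ProbabilityVolume-class
#' @exportClass ProbabilityVolume
setClass("ProbabilityVolume",
  representation(
    probs       = "array",
    classLabels = "integer",
    spacing     = "numeric",
    caseId      = "character",
    foldId      = "character"
  )
)

setValidity("ProbabilityVolume", function(object) {
  msg <- character()
  d <- dim(object@probs)
  if (length(d) != 4L)
    msg <- c(msg, "probs must be a 4D array (x, y, z, class)")
  else {
    if (d[4L] != length(object@classLabels))
      msg <- c(msg, "length of classLabels must match the class axis")
    rng <- range(object@probs)
    if (rng[1L] < -1e-8 || rng[2L] > 1 + 1e-8)
      msg <- c(msg, "probabilities must lie in [0, 1]")
    sums <- rowSums(matrix(object@probs, ncol = d[4L]))
    if (max(abs(sums - 1)) > 1e-5)
      msg <- c(msg, "per-voxel class probabilities must sum to 1 (tol 1e-5)")
  }
  if (!0L %in% object@classLabels)
    msg <- c(msg, "classLabels must contain the background label 0")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive values (mm)")
  if (length(msg)) msg else TRUE
})

setClassUnion("LabelVolumeOrNULL", c("LabelVolume", "NULL"))
setClassUnion("ProbabilityVolumeOrNULL", c("ProbabilityVolume", "NULL"))

#' FoldSet: one case's K per-fold predictions
#'
#' Bundles the K co-registered sub-model predictions of one case (hard labels,
#' optionally the matching soft probability fields) together with an optional
#' reference-standard segmentation. All member grids must share shape and
#' spacing; no resampling is attempted -- fold predictions of one model on one
#' image share a grid by construction, so a mismatch is an error.
#'
#' @slot caseId character scalar.
#' @slot folds list of K \linkS4class{LabelVolume} objects, K >= 2.
#' @slot probabilities list of K \linkS4class{ProbabilityVolume} objects, or
#'   an empty list when soft outputs are unavailable.
#' @slot reference optional \linkS4class{LabelVolume} (may be \code{NULL}).
#'
#' @seealso [FoldSet()], [interfoldDices()]
#' @name FoldSet-class
#' @rdname FoldSet-class
#' @exportClass FoldSet
setClass("FoldSet",
  representation(
    caseId        = "character",
    folds         = "list",
    probabilities = "list",
    reference     = "LabelVolumeOrNULL"
  )
)

setValidity("FoldSet", function(object) {
  msg <- character()
  k <- length(object@folds)
  if (k < 2L)
    msg <- c(msg, "a FoldSet needs at least 2 fold predictions")
  if (!all(vapply(object@folds, is, logical(1L), class2 = "LabelVolume")))
    msg <- c(msg, "folds must all be LabelVolume objects")
  else {
    dims <- lapply(object@folds, function(v) dim(v@voxels))
    sps  <- lapply(object@folds, function(v) v@spacing)
    ref  <- object@reference
    if (!is.null(ref)) {
      dims <- c(dims, list(dim(ref@voxels)))
      sps  <- c(sps, list(ref@spacing))
    }
    if (length(object@probabilities)) {
      if (length(object@probabilities) != k)
        msg <- c(msg, "probabilities, when present, must have one entry per fold")
      dims <- c(dims, lapply(object@probabilities,
                             function(p) dim(p@probs)[1:3]))
      sps  <- c(sps, lapply(object@probabilities, function(p) p@spacing))
    }
    if (!all(vapply(dims, identical, logical(1L), y = dims[[1L]])))
      msg <- c(msg, "all member grids must share an identical shape")
    if (!all(vapply(sps, function(s) isTRUE(all.equal(s, sps[[1L]])),
                    logical(1L))))
      msg <- c(msg, "all member grids must share identical spacing")
  }
  if (length(msg)) msg else TRUE
})

#' InterfoldResult: pairwise inter-fold Dice disagreement
#'
#' The C(K, 2) pairwise Dice values between the K sub-model predictions of one
#' case on a target label (the "interfold Dices"), together with their four
#' first-order summaries (mean, median, min, max). The summarized value is the
#' reference-free quality surrogate that is compared against an interobserver
#' threshold.
#'
#' @slot caseId character scalar.
#' @slot targetLabel integer, the label the disagreement was computed on.
#' @slot pairwise named numeric of length K(K-1)/2, each value in [0, 1];
#'   names are "i-j" for fold pair (i, j), i < j, in lexicographic order.
#' @slot summaries named numeric with elements mean, median, min, max.
#' @slot k integer, the number of folds.
#'
#' @seealso [interfoldDices()], [flagCase()]
#' @name InterfoldResult-class
#' @rdname InterfoldResult-class
#' @exportClass InterfoldResult
setClass("InterfoldResult",
  representation(
    caseId      = "character",
    targetLabel = "integer",
    pairwise    = "numeric",
    summaries   = "numeric",
    k           = "integer"
  )
)

setValidity("InterfoldResult", function(object) {
  msg <- character()
  k <- object@k
  if (length(object@pairwise) != k * (k - 1L) / 2L)
    msg <- c(msg, "pairwise must have length k(k-1)/2")
  if (any(object@pairwise < 0 | object@pairwise > 1))
    msg <- c(msg, "pairwise Dice values must lie in [0, 1]")
  s <- object@summaries
  if (!all(c("mean", "median", "min", "max") %in% names(s)))
    msg <- c(msg, "summaries must contain mean, median, min and max")
  else {
    if (s[["min"]] > s[["median"]] + 1e-12 || s[["median"]] > s[["max"]] + 1e-12)
      msg <- c(msg, "summaries must satisfy min <= median <= max")
    if (s[["min"]] > s[["mean"]] + 1e-12 || s[["mean"]] > s[["max"]] + 1e-12)
      msg <- c(msg, "summaries must satisfy min <= mean <= max")
  }
  if (length(msg)) msg else TRUE
})

#' EnsemblePrediction: the final ensembled segmentation
#'
#' The final prediction reconstructed from K sub-model outputs, either by
#' voxel-wise averaging of softmax probabilities (the standard route) or by a
#' plurality vote over hard labels (fallback when soft outputs were not
#' exported; equivalent to averaging one-hot fields).
#'
#' @slot labelVolume the hard-label \linkS4class{LabelVolume}.
#' @slot meanProbs the averaged \linkS4class{ProbabilityVolume}, or \code{NULL}
#'   for the label-vote route.
#' @slot source either \code{"probability_average"} or \code{"label_vote"}.
#'
#' @seealso [ensembleFromProbabilities()], [ensembleFromLabels()]
#' @name EnsemblePrediction-class
#' @rdname EnsemblePrediction-class
#' @exportClass EnsemblePrediction
setClass("EnsemblePrediction",
  representation(
    labelVolume = "LabelVolume",
    meanProbs   = "ProbabilityVolumeOrNULL",
    source      = "character"
  )
)

setValidity("EnsemblePrediction", function(object) {
  msg <- character()
  if (!object@source %in% c("probability_average", "label_vote"))
    msg <- c(msg, "source must be probability_average or label_vote")
  if (!is.null(object@meanProbs)) {
    if (!identical(dim(object@labelVolume@voxels),
                   dim(object@meanProbs@probs)[1:3]))
      msg <- c(msg, "labelVolume grid must match meanProbs grid")
  }
  if (length(msg)) msg else TRUE
})

#' ThresholdSpec: a flagging threshold with provenance
#'
#' A flagging threshold in [0, 1], optionally derived as the arithmetic mean of
#' published human interobserver Dice values (a low-high range contributes its
#' midpoint), with the derivation recorded so it can be reproduced exactly.
#'
#' @slot value numeric scalar in [0, 1].
#' @slot sourceValues list of numeric scalars or length-2 ranges in [0, 1];
#'   empty when the value was supplied directly.
#' @slot roundingDecimals integer or NULL; half-up rounding applied to the
#'   mean of the sources.
#' @slot derivation free-text provenance.
#' @slot taskName character, the segmentation task the threshold is for.
#'
#' @seealso [deriveThreshold()], [flagCase()]
#' @name ThresholdSpec-class
#' @rdname ThresholdSpec-class
#' @exportClass ThresholdSpec
setClass("ThresholdSpec",
  representation(
    value            = "numeric",
    sourceValues     = "list",
    roundingDecimals = "numericOrNULL",
    derivation       = "character",
    taskName         = "character"
  )
)

setValidity("ThresholdSpec", function(object) {
  msg <- character()
  if (length(object@value) != 1L || object@value < 0 || object@value > 1)
    msg <- c(msg, "value must be a scalar in [0, 1]")
  bad <- vapply(object@sourceValues, function(v) {
    !is.numeric(v) || !length(v) %in% 1:2 || any(v < 0 | v > 1)
  }, logical(1L))
  if (any(bad))
    msg <- c(msg, "sourceValues must be scalars or length-2 ranges in [0, 1]")
  if (length(object@sourceValues)) {
    expected <- .thresholdFromSources(object@sourceValues,
                                      object@roundingDecimals)
    if (abs(object@value - expected) > 1e-12)
      msg <- c(msg, "value must equal the (rounded) mean of sourceValues")
  }
  if (length(msg)) msg else TRUE
})

#' FlagDecision: the flagging outcome for one case
#'
#' Records which summary statistic was compared against which threshold and
#' whether the case was flagged for human review. The comparison is strict:
#' a case is flagged if and only if its summarized interfold Dice is strictly
#' below the threshold.
#'
#' @slot caseId character scalar.
#' @slot statistic one of mean, median, min, max.
#' @slot summaryValue the summarized interfold Dice, in [0, 1].
#' @slot threshold the threshold value used, in [0, 1].
#' @slot flagged logical.
#'
#' @seealso [flagCase()]
#' @name FlagDecision-class
#' @rdname FlagDecision-class
#' @exportClass FlagDecision
setClass("FlagDecision",
  representation(
    caseId       = "character",
    statistic    = "character",
    summaryValue = "numeric",
    threshold    = "numeric",
    flagged      = "logical"
  )
)

setValidity("FlagDecision", function(object) {
  msg <- character()
  if (!object@statistic %in% c("mean", "median", "min", "max"))
    msg <- c(msg, "statistic must be one of mean, median, min, max")
  if (!identical(object@flagged, object@summaryValue < object@threshold))
    msg <- c(msg, "flagged must equal (summaryValue < threshold)")
  if (length(msg)) msg else TRUE
})

#' ConfusionCounts: flagging-system confusion matrix
#'
#' Counts of the four per-case outcomes when flagging decisions are scored
#' against reference-standard ensemble performance: TP = flagged and performed
#' poorly, FP = flagged but performed well, FN = not flagged but performed
#' poorly (the worst failure mode), TN = not flagged and performed well.
#'
#' @slot tp,fp,fn,tn non-negative integer counts.
#' @slot n total number of cases (always tp + fp + fn + tn).
#'
#' @seealso [confusionCounts()], [classifyOutcome()]
#' @name ConfusionCounts-class
#' @rdname ConfusionCounts-class
#' @exportClass ConfusionCounts
setClass("ConfusionCounts",
  representation(tp = "integer", fp = "integer", fn = "integer",
                 tn = "integer", n = "integer")
)

setValidity("ConfusionCounts", function(object) {
  msg <- character()
  cnt <- c(object@tp, object@fp, object@fn, object@tn)
  if (any(cnt < 0L))
    msg <- c(msg, "counts must be non-negative")
  if (sum(cnt) != object@n)
    msg <- c(msg, "tp + fp + fn + tn must equal n")
  if (length(msg)) msg else TRUE
})

#' CohortSummary: flagged vs non-flagged cohort statistics
#'
#' Mean and sample standard deviation (n - 1 denominator) of ensemble Dice
#' versus the reference standard for the full cohort, the flagged subset and
#' the non-flagged complement. Statistics of an empty subset are \code{NA}
#' (absent, not zero).
#'
#' @slot nFlagged,nTotal integer counts.
#' @slot flaggedMean,flaggedSd,nonflaggedMean,nonflaggedSd,overallMean,overallSd
#'   numeric scalars (possibly \code{NA}).
#'
#' @seealso [cohortStats()]
#' @name CohortSummary-class
#' @rdname CohortSummary-class
#' @exportClass CohortSummary
setClass("CohortSummary",
  representation(
    nFlagged       = "integer",
    nTotal         = "integer",
    flaggedMean    = "numeric",
    flaggedSd      = "numeric",
    nonflaggedMean = "numeric",
    nonflaggedSd   = "numeric",
    overallMean    = "numeric",
    overallSd      = "numeric"
  )
)

setValidity("CohortSummary", function(object) {
  msg <- character()
  if (object@nFlagged > object@nTotal)
    msg <- c(msg, "nFlagged cannot exceed nTotal")
  means <- c(object@flaggedMean, object@nonflaggedMean, object@overallMean)
  if (any(!is.na(means) & (means < 0 | means > 1)))
    msg <- c(msg, "means must lie in [0, 1]")
  sds <- c(object@flaggedSd, object@nonflaggedSd, object@overallSd)
  if (any(!is.na(sds) & sds < 0))
    msg <- c(msg, "standard deviations must be non-negative")
  if (length(msg)) msg else TRUE
})
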
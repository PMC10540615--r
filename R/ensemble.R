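## Ensemble reconstruction: voxel-wise averaging of per-fold softmax
## probability fields (the standard route), with a hard-label plurality vote
## fallback for pipelines that did not export soft outputs.

# argmax over a nvox x nclass matrix with ties to the lowest class label;
# classLabels must be supplied in increasing order so that max.col's "first"
# tie rule lands on the lowest label (background-favoring for label 0).
.argmaxLabels <- function(m, classLabels) {
  ord <- order(classLabels)
  idx <- max.col(m[, ord, drop = FALSE], ties.method = "first")
  classLabels[ord][idx]
}

#' Ensemble K soft predictions by probability averaging
#'
#' Averages the voxel-wise class (softmax) probabilities of the K sub-models
#' arithmetically in linear probability space and assigns every voxel the
#' class with maximal averaged probability. For a two-class problem this is
#' exactly rounding the averaged foreground probability to the nearest
#' prediction value at the 0.5 boundary; exact ties go to the lowest class
#' label (deterministic and background-favoring).
#'
#' @param foldProbs non-empty list of \linkS4class{ProbabilityVolume} objects
#'   on an identical grid with identical class labels in identical order.
#' @return an \linkS4class{EnsemblePrediction} with
#'   \code{source = "probability_average"} and the averaged field in
#'   \code{meanProbs}.
#' @export
ensembleFromProbabilities <- function(foldProbs) {
  if (length(foldProbs) < 1L) stop("need at least one probability volume")
  p1 <- foldProbs[[1L]]
  for (p in foldProbs[-1L]) {
    if (!identical(dim(p@probs), dim(p1@probs)))
      stop("grid incompatibility: probability volume shapes differ")
    if (!isTRUE(all.equal(p@spacing, p1@spacing)))
      stop("grid incompatibility: voxel spacings differ")
    if (!identical(p@classLabels, p1@classLabels))
      stop("class label vocabularies/order differ between folds")
  }
  mean_probs <- Reduce(`+`, lapply(foldProbs, slot, "probs")) / length(foldProbs)
  d <- dim(mean_probs)
  lab <- .argmaxLabels(matrix(mean_probs, ncol = d[4L]), p1@classLabels)
  vol <- LabelVolume(array(as.integer(lab), d[1:3]), spacing = p1@spacing,
                     labels = p1@classLabels, caseId = p1@caseId)
  mp <- ProbabilityVolume(mean_probs, p1@classLabels, p1@spacing,
                          caseId = p1@caseId)
  new("EnsemblePrediction", labelVolume = vol, meanProbs = mp,
      source = "probability_average")
}

#' Ensemble K hard-label predictions by plurality vote
#'
#' Per-voxel plurality vote over the fold labels, ties toward the lowest
#' label value. Voxel-for-voxel equivalent to
#' \code{ensembleFromProbabilities} applied to the one-hot encodings of the
#' folds.
#'
#' @param foldLabels non-empty list of \linkS4class{LabelVolume} objects on an
#'   identical grid.
#' @param classLabels vote vocabulary; defaults to the union of the folds'
#'   label vocabularies.
#' @return an \linkS4class{EnsemblePrediction} with
#'   \code{source = "label_vote"} (no averaged field).
#' @export
ensembleFromLabels <- function(foldLabels, classLabels = NULL) {
  if (length(foldLabels) < 1L) stop("need at least one label volume")
  v1 <- foldLabels[[1L]]
  for (v in foldLabels[-1L]) .checkGrids(v1, v)
  if (is.null(classLabels))
    classLabels <- sort(unique(unlist(lapply(foldLabels, slot, "labels"))))
  classLabels <- as.integer(classLabels)
  d <- dim(v1@voxels)
  votes <- matrix(0L, prod(d), length(classLabels))
  for (v in foldLabels)
    for (ci in seq_along(classLabels))
      votes[, ci] <- votes[, ci] + (as.vector(v@voxels) == classLabels[ci])
  lab <- .argmaxLabels(votes, classLabels)
  vol <- LabelVolume(array(as.integer(lab), d), spacing = v1@spacing,
                     labels = classLabels, caseId = v1@caseId)
  new("EnsemblePrediction", labelVolume = vol, meanProbs = NULL,
      source = "label_vote")
}

#' One-hot probability encoding of a hard segmentation
#'
#' Encodes a \linkS4class{LabelVolume} as a degenerate
#' \linkS4class{ProbabilityVolume} with probability 1 on the observed class at
#' every voxel.
#'
#' @param v a \linkS4class{LabelVolume}.
#' @param classLabels class axis; defaults to the volume's label vocabulary.
#' @return a \linkS4class{ProbabilityVolume}.
#' @export
oneHotProbabilities <- function(v, classLabels = NULL) {
  if (is.null(classLabels)) classLabels <- v@labels
  classLabels <- as.integer(classLabels)
  d <- dim(v@voxels)
  probs <- array(0, c(d, length(classLabels)))
  for (ci in seq_along(classLabels))
    probs[, , , ci] <- as.numeric(v@voxels == classLabels[ci])
  ProbabilityVolume(probs, classLabels, v@spacing, caseId = v@caseId,
                    foldId = v@foldId)
}
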
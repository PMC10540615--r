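## Core volumetric operations: Dice similarity, label volume measurement and
## pairwise inter-fold disagreement with first-order summaries.

.checkGrids <- function(a, b) {
  if (!identical(dim(a@voxels), dim(b@voxels)))
    stop("grid incompatibility: volume shapes differ (",
         paste(dim(a@voxels), collapse = "x"), " vs ",
         paste(dim(b@voxels), collapse = "x"), ")")
  if (!isTRUE(all.equal(a@spacing, b@spacing)))
    stop("grid incompatibility: voxel spacings differ")
  invisible(TRUE)
}

.checkLabel <- function(v, targetLabel) {
  if (length(targetLabel) != 1L || !targetLabel %in% v@labels)
    stop("target label ", targetLabel,
         " is not in the label vocabulary of volume '", v@caseId, "'")
  invisible(TRUE)
}

#' Dice similarity coefficient between two label volumes
#'
#' Computes 2|A n B| / (|A| + |B|) where A and B are the voxel sets carrying
#' \code{targetLabel} in each volume: 1 indicates complete overlap, 0 no
#' overlap. The measure is symmetric and independent of voxel spacing. When
#' both volumes are empty at the target label the two segmentations agree
#' (vacuously) and the value of \code{bothEmpty} is returned -- 1 by default,
#' so that consistent misses across folds count as agreement; when exactly one
#' is empty the score is 0.
#'
#' @param a,b \linkS4class{LabelVolume} objects on an identical grid.
#' @param targetLabel the label defining the foreground sets; must be in both
#'   label vocabularies.
#' @param bothEmpty value returned when neither volume contains the target
#'   label (1 or 0).
#' @return a numeric scalar in [0, 1].
#' @examples
#' a <- LabelVolume(array(c(1L, 1L, 0L, 0L), c(2, 2, 1)), labels = 0:1)
#' b <- LabelVolume(array(c(1L, 0L, 1L, 0L), c(2, 2, 1)), labels = 0:1)
#' diceScore(a, b, 1L)  # |A| = |B| = 2, overlap 1 -> 0.5
#' @export
diceScore <- function(a, b, targetLabel, bothEmpty = 1) {
  .checkGrids(a, b)
  .checkLabel(a, targetLabel)
  .checkLabel(b, targetLabel)
  stopifnot(bothEmpty %in% c(0, 1))
  inA <- a@voxels == targetLabel
  inB <- b@voxels == targetLabel
  nA <- sum(inA)
  nB <- sum(inB)
  if (nA == 0L && nB == 0L) return(as.numeric(bothEmpty))
  2 * sum(inA & inB) / (nA + nB)
}

#' Physical volume of a label, in millilitres
#'
#' Voxel count at the target label times the voxel volume (product of the
#' three spacing components, mm^3), divided by 1000.
#'
#' @param v a \linkS4class{LabelVolume}.
#' @param targetLabel the label to measure.
#' @return volume in ml (>= 0).
#' @export
labelVolumeMl <- function(v, targetLabel) {
  .checkLabel(v, targetLabel)
  sum(v@voxels == targetLabel) * prod(v@spacing) / 1000
}

#' Summarize a set of Dice values with a first-order statistic
#'
#' @param values non-empty numeric vector of Dice values in [0, 1].
#' @param statistic one of \code{"mean"}, \code{"median"}, \code{"min"},
#'   \code{"max"}. The median of an even-length vector is the midpoint of the
#'   two central order statistics.
#' @return a numeric scalar in [0, 1].
#' @export
summarizeDices <- function(values,
                           statistic = c("mean", "median", "min", "max")) {
  statistic <- match.arg(statistic)
  if (length(values) == 0L) stop("cannot summarize an empty set of Dice values")
  if (any(values < 0 | values > 1)) stop("Dice values must lie in [0, 1]")
  switch(statistic,
         mean = mean(values),
         median = stats::median(values),
         min = min(values),
         max = max(values))
}

#' Pairwise inter-fold Dice disagreement for one case
#'
#' Computes the Dice score between every unordered pair of the K fold
#' predictions in a \linkS4class{FoldSet} on the target label -- fold 1 vs
#' fold 2, fold 1 vs fold 3, and so on -- yielding K(K-1)/2 interfold Dices
#' (10 for the usual K = 5), plus their mean, median, minimum and maximum.
#' High values mean the sub-models agree; low values signal epistemic
#' uncertainty, typically from under-represented (out-of-distribution) inputs.
#'
#' @param folds a \linkS4class{FoldSet} with K >= 2 fold predictions.
#' @param targetLabel the label on which disagreement is measured (one
#'   structure at a time; loop over labels for multi-structure reports).
#' @param bothEmpty Dice convention when a fold pair is empty at the target
#'   label on both sides (see [diceScore()]).
#' @return an \linkS4class{InterfoldResult}; pairwise values are named
#'   \code{"i-j"} in lexicographic fold order.
#' @export
interfoldDices <- function(folds, targetLabel, bothEmpty = 1) {
  k <- length(folds@folds)
  if (k < 2L) stop("at least 2 folds are needed to compare")
  # precompute the per-fold foreground masks once; pairs then reduce to
  # logical sums
  masks <- lapply(folds@folds, function(f) {
    .checkLabel(f, targetLabel)
    f@voxels == targetLabel
  })
  for (i in seq_len(k - 1L)) .checkGrids(folds@folds[[1L]], folds@folds[[i + 1L]])
  sizes <- vapply(masks, sum, numeric(1L))
  pair <- numeric(0L)
  nm <- character(0L)
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      d <- if (sizes[i] == 0 && sizes[j] == 0) as.numeric(bothEmpty)
      else 2 * sum(masks[[i]] & masks[[j]]) / (sizes[i] + sizes[j])
      pair <- c(pair, d)
      nm <- c(nm, paste0(i, "-", j))
    }
  }
  names(pair) <- nm
  summaries <- c(mean = mean(pair), median = stats::median(pair),
                 min = min(pair), max = max(pair))
  new("InterfoldResult", caseId = folds@caseId,
      targetLabel = as.integer(targetLabel), pairwise = pair,
      summaries = summaries, k = as.integer(k))
}
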
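## Evaluation against a reference standard: per-case outcome classification,
## confusion matrices, flagged/non-flagged cohort statistics and
## flagged-vs-feature stratification.

#' Classify flagging outcomes against reference performance
#'
#' Scores the flagging system when a reference standard exists: a case
#' "performed poorly" when its ensemble Dice versus the reference is strictly
#' below the performance threshold, and "performed well" otherwise (exact
#' equality counts as well, symmetric with the strict flagging rule). TP =
#' flagged and poor; FP = flagged but good; FN = not flagged but poor (the
#' worst failure mode -- an unreviewed poor segmentation); TN = not flagged
#' and good.
#'
#' @param flagged logical vector (or scalar).
#' @param ensembleDice numeric vector in [0, 1], same length.
#' @param performanceThreshold scalar in [0, 1]; typically the same
#'   interobserver threshold used for flagging.
#' @return character vector of \code{"TP"}, \code{"FP"}, \code{"FN"},
#'   \code{"TN"}.
#' @export
classifyOutcome <- function(flagged, ensembleDice, performanceThreshold) {
  if (length(flagged) != length(ensembleDice))
    stop("flagged and ensembleDice must have equal length")
  if (any(ensembleDice < 0 | ensembleDice > 1) ||
      performanceThreshold < 0 || performanceThreshold > 1)
    stop("Dice values and the performance threshold must lie in [0, 1]")
  poor <- ensembleDice < performanceThreshold
  ifelse(flagged & poor, "TP",
         ifelse(flagged & !poor, "FP",
                ifelse(!flagged & poor, "FN", "TN")))
}

#' Tally outcomes into a confusion matrix
#'
#' @param outcomes non-empty character vector of \code{"TP"}, \code{"FP"},
#'   \code{"FN"}, \code{"TN"} (as returned by [classifyOutcome()]).
#' @return a \linkS4class{ConfusionCounts}; the four counts always sum to the
#'   cohort size.
#' @export
confusionCounts <- function(outcomes) {
  if (length(outcomes) == 0L) stop("outcomes must be non-empty")
  if (!all(outcomes %in% c("TP", "FP", "FN", "TN")))
    stop("outcomes must be TP, FP, FN or TN")
  new("ConfusionCounts",
      tp = sum(outcomes == "TP"), fp = sum(outcomes == "FP"),
      fn = sum(outcomes == "FN"), tn = sum(outcomes == "TN"),
      n = length(outcomes))
}

#' Flagged versus non-flagged cohort statistics
#'
#' Mean and sample standard deviation (n - 1) of ensemble Dice versus the
#' reference for the full cohort, the flagged subset and the non-flagged
#' complement -- the "how much does the test-set Dice improve if flagged
#' cases are excluded" view. Statistics of an empty subset are \code{NA}.
#'
#' @param dices numeric vector of ensemble Dice scores in [0, 1].
#' @param flags logical vector of the same length.
#' @return a \linkS4class{CohortSummary}.
#' @export
cohortStats <- function(dices, flags) {
  if (length(dices) != length(flags))
    stop("dices and flags must have equal length")
  if (length(dices) == 0L) stop("cohort must be non-empty")
  sub <- function(x) {
    if (length(x) == 0L) c(NA_real_, NA_real_)
    else c(mean(x), if (length(x) > 1L) stats::sd(x) else NA_real_)
  }
  fl <- sub(dices[flags])
  nf <- sub(dices[!flags])
  ov <- sub(dices)
  new("CohortSummary", nFlagged = sum(flags), nTotal = length(flags),
      flaggedMean = fl[1L], flaggedSd = fl[2L],
      nonflaggedMean = nf[1L], nonflaggedSd = nf[2L],
      overallMean = ov[1L], overallSd = ov[2L])
}

#' Stratify flag rates by a per-case feature
#'
#' Bins a per-case feature (e.g. tumor volume in ml) into equal-width bins
#' over its range and reports the flagged fraction per bin -- the view that
#' shows, for instance, that flagged cases concentrate at small tumor
#' volumes when small tumors are under-represented in training.
#'
#' @param flags logical vector.
#' @param feature numeric vector, same length.
#' @param nBins number of equal-width bins (>= 1).
#' @return a data.frame with columns \code{bin}, \code{lower}, \code{upper},
#'   \code{n}, \code{nFlagged}, \code{fraction} (NA for empty bins).
#' @export
stratifyFlagsByFeature <- function(flags, feature, nBins = 5L) {
  if (length(flags) != length(feature))
    stop("flags and feature must have equal length")
  if (length(flags) == 0L) stop("cohort must be non-empty")
  nBins <- as.integer(nBins)
  if (nBins < 1L) stop("nBins must be >= 1")
  rng <- range(feature)
  if (diff(rng) == 0) {
    # degenerate constant feature: everything in the first bin
    idx <- rep(1L, length(feature))
    breaks <- c(rng[1L], rep(rng[2L], nBins))
  } else {
    breaks <- seq(rng[1L], rng[2L], length.out = nBins + 1L)
    idx <- findInterval(feature, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
  }
  n <- tabulate(idx, nbins = nBins)
  nf <- vapply(seq_len(nBins), function(b) sum(flags[idx == b]), integer(1L))
  data.frame(bin = seq_len(nBins),
             lower = breaks[seq_len(nBins)],
             upper = breaks[seq_len(nBins) + 1L],
             n = n, nFlagged = nf,
             fraction = ifelse(n > 0L, nf / pmax(n, 1L), NA_real_))
}
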
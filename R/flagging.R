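## Flagging: interobserver-derived thresholds, the per-case flagging rule and
## threshold sensitivity scans.

# half-up decimal rounding (base round() is round-half-even)
.roundHalfUp <- function(x, digits) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# mean of scalar sources, ranges contributing their midpoint
.thresholdFromSources <- function(sourceValues, roundingDecimals = NULL) {
  mids <- vapply(sourceValues, function(v) mean(range(v)), numeric(1L))
  val <- mean(mids)
  if (!is.null(roundingDecimals)) val <- .roundHalfUp(val, roundingDecimals)
  val
}

#' Derive a flagging threshold from published interobserver Dice values
#'
#' Inter-fold disagreement is only meaningful relative to how much two human
#' experts would disagree on the same task. This takes published human
#' interobserver Dice values (each a scalar, or a low-high range which
#' contributes its midpoint), averages them arithmetically, and optionally
#' applies half-up rounding; the full provenance is recorded so the threshold
#' is exactly re-derivable. For kidney-tumor MR, sources 0.87 and 0.78 give
#' the 0.825 threshold; for kidney-tumor CT, the range 0.91-0.93 together
#' with 0.87 gives 0.895 (0.90 after rounding to two decimals).
#'
#' @param sourceValues non-empty list of values or length-2 ranges, all in
#'   [0, 1]. A plain numeric vector is treated as a list of scalars.
#' @param taskName the segmentation task the threshold applies to.
#' @param roundingDecimals optional integer; half-up rounding applied to the
#'   mean. \code{NULL} (default) stores full precision.
#' @param derivation optional free-text provenance note.
#' @return a \linkS4class{ThresholdSpec}.
#' @examples
#' deriveThreshold(c(0.87, 0.78), "kidney tumor MR")      # 0.825
#' deriveThreshold(list(c(0.91, 0.93), 0.87), "kidney tumor CT")  # 0.895
#' @export
deriveThreshold <- function(sourceValues, taskName = "",
                            roundingDecimals = NULL, derivation = "") {
  if (is.numeric(sourceValues)) sourceValues <- as.list(sourceValues)
  if (length(sourceValues) == 0L)
    stop("at least one interobserver source value is required")
  ok <- vapply(sourceValues, function(v)
    is.numeric(v) && length(v) %in% 1:2 && all(v >= 0 & v <= 1), logical(1L))
  if (!all(ok))
    stop("source values must be scalars or length-2 ranges in [0, 1]")
  if (!is.null(roundingDecimals)) roundingDecimals <- as.numeric(roundingDecimals)
  val <- .thresholdFromSources(sourceValues, roundingDecimals)
  if (!nzchar(derivation))
    derivation <- sprintf(
      "arithmetic mean of %d published interobserver value(s)%s",
      length(sourceValues),
      if (is.null(roundingDecimals)) "" else
        sprintf(", rounded half-up to %d decimals", as.integer(roundingDecimals)))
  new("ThresholdSpec", value = val, sourceValues = sourceValues,
      roundingDecimals = roundingDecimals, derivation = derivation,
      taskName = as.character(taskName))
}

# accept a bare number anywhere a ThresholdSpec is expected
.asThresholdSpec <- function(threshold, taskName = "") {
  if (is(threshold, "ThresholdSpec")) return(threshold)
  if (is.numeric(threshold) && length(threshold) == 1L)
    return(new("ThresholdSpec", value = as.numeric(threshold),
               sourceValues = list(), roundingDecimals = NULL,
               derivation = "explicit value", taskName = taskName))
  stop("threshold must be a ThresholdSpec or a numeric scalar")
}

#' Flag one case from its summarized inter-fold disagreement
#'
#' A case is flagged for human review if and only if its summarized interfold
#' Dice is strictly below the threshold; equality is not flagged.
#'
#' @param result an \linkS4class{InterfoldResult}.
#' @param threshold a \linkS4class{ThresholdSpec} or numeric scalar.
#' @param statistic which first-order summary to compare; the median is the
#'   default (it drives the headline confusion matrices).
#' @return a \linkS4class{FlagDecision}.
#' @export
flagCase <- function(result, threshold,
                     statistic = c("median", "mean", "min", "max")) {
  statistic <- match.arg(statistic)
  threshold <- .asThresholdSpec(threshold)
  sv <- result@summaries[[statistic]]
  new("FlagDecision", caseId = result@caseId, statistic = statistic,
      summaryValue = sv, threshold = threshold@value,
      flagged = sv < threshold@value)
}

#' Threshold sensitivity scan
#'
#' Applies the flagging rule at each of several thresholds to a fixed cohort
#' of interfold results. Because flagging is a strict-below comparison on a
#' fixed summary, the flagged set at a lower threshold is always a subset of
#' the flagged set at a higher one, so flag counts are non-decreasing in the
#' threshold. When ensemble Dice scores versus a reference are supplied, a
#' per-threshold confusion matrix is added.
#'
#' @param results non-empty list of \linkS4class{InterfoldResult} objects.
#' @param thresholds non-empty numeric vector of thresholds in [0, 1].
#' @param statistic summary statistic to compare (default median).
#' @param ensembleDices optional numeric vector of ensemble Dice scores vs
#'   reference, one per result (in the same order).
#' @param performanceThreshold threshold separating poor from good ensemble
#'   performance; defaults to each scanned flagging threshold.
#' @return a data.frame with one row per threshold: \code{threshold},
#'   \code{nFlagged}, a list-column \code{flaggedCases} of case ids, and
#'   (when \code{ensembleDices} is given) \code{tp}, \code{fp}, \code{fn},
#'   \code{tn}.
#' @export
sensitivityScan <- function(results, thresholds,
                            statistic = c("median", "mean", "min", "max"),
                            ensembleDices = NULL,
                            performanceThreshold = NULL) {
  statistic <- match.arg(statistic)
  if (length(results) == 0L) stop("results must be non-empty")
  if (length(thresholds) == 0L) stop("thresholds must be non-empty")
  if (any(thresholds < 0 | thresholds > 1))
    stop("thresholds must lie in [0, 1]")
  if (!is.null(ensembleDices) && length(ensembleDices) != length(results))
    stop("ensembleDices must have one value per result")
  thresholds <- sort(thresholds)
  ids <- vapply(results, caseId, character(1L))
  sv <- vapply(results, function(r) r@summaries[[statistic]], numeric(1L))
  rows <- lapply(thresholds, function(t) {
    fl <- sv < t
    row <- data.frame(threshold = t, nFlagged = sum(fl))
    row$flaggedCases <- I(list(ids[fl]))
    if (!is.null(ensembleDices)) {
      pt <- if (is.null(performanceThreshold)) t else performanceThreshold
      out <- classifyOutcome(fl, ensembleDices, pt)
      cc <- confusionCounts(out)
      row$tp <- cc@tp; row$fp <- cc@fp; row$fn <- cc@fn; row$tn <- cc@tn
    }
    row
  })
  do.call(rbind, rows)
}
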
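## Diagnostic displays: summary-vs-ensemble scatter with the two threshold
## lines, and the 2x2 flagging confusion matrix.

#' Scatter of summarized interfold Dice against ensemble performance
#'
#' One point per case; the horizontal line is the flagging cutoff (points
#' below are flagged), the vertical line the ensemble performance cutoff
#' (points to its left performed poorly). The four quadrants are the
#' TP/FP/FN/TN of [classifyOutcome()].
#'
#' @param summaryValues summarized interfold Dice per case.
#' @param ensembleDices ensemble Dice vs reference per case.
#' @param threshold flagging threshold (horizontal line).
#' @param performanceThreshold performance threshold (vertical line).
#' @param statistic summary statistic name, used for the axis label.
#' @return invisibly, \code{NULL}; draws on the current device.
#' @export
plotFlagScatter <- function(summaryValues, ensembleDices, threshold,
                            performanceThreshold = threshold,
                            statistic = "median") {
  flagged <- summaryValues < threshold
  graphics::plot(ensembleDices, summaryValues, xlim = c(0, 1), ylim = c(0, 1),
                 pch = ifelse(flagged, 17, 19),
                 col = ifelse(flagged, "firebrick", "steelblue"),
                 xlab = "ensemble Dice vs reference",
                 ylab = sprintf("%s interfold Dice", statistic),
                 main = "Inter-fold disagreement vs ensemble performance")
  graphics::abline(h = threshold, lty = 2, col = "blue")
  graphics::abline(v = performanceThreshold, lty = 2, col = "red")
  graphics::legend("bottomright", pch = c(17, 19),
                   col = c("firebrick", "steelblue"),
                   legend = c("flagged", "not flagged"), bty = "n")
  invisible(NULL)
}

#' Draw a 2x2 flagging confusion matrix
#'
#' @param confusion a \linkS4class{ConfusionCounts}.
#' @return invisibly, \code{NULL}; draws on the current device.
#' @export
plotConfusionMatrix <- function(confusion) {
  stopifnot(is(confusion, "ConfusionCounts"))
  m <- matrix(c(confusion@tp, confusion@fp, confusion@fn, confusion@tn),
              2L, byrow = TRUE)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 2), ylim = c(0, 2), asp = 1)
  cols <- c("#b3cde3", "#fbb4ae", "#fbb4ae", "#ccebc5")
  k <- 1L
  for (r in 1:2) for (cc in 1:2) {
    graphics::rect(cc - 1, 2 - r, cc, 3 - r, col = cols[k], border = "grey30")
    graphics::text(cc - 0.5, 2.5 - r, m[r, cc], cex = 2)
    k <- k + 1L
  }
  graphics::mtext("performed poorly   performed well", side = 1, line = 0.5)
  graphics::mtext("not flagged    flagged", side = 2, line = 0.5)
  graphics::title(sprintf("Flagging confusion matrix (n = %d)", confusion@n))
  invisible(NULL)
}
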
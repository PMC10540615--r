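# Fixture builders and independent oracles shared across the suite.
# All fixtures are built in code; nothing is read from disk.

# a LabelVolume from a vector/array of labels
lv <- function(values, dim3 = NULL, spacing = c(1, 1, 1), labels = NULL,
               caseId = "t", foldId = NA_character_) {
  if (is.null(dim3)) dim3 <- dim(values)
  LabelVolume(array(as.integer(values), dim3), spacing = spacing,
              labels = labels, caseId = caseId, foldId = foldId)
}

# random small label volume over labels {0, 1, 2}
randomLv <- function(dim3, seed, spacing = c(1, 1, 1)) {
  set.seed(seed)
  lv(sample(0:2, prod(dim3), replace = TRUE), dim3, spacing = spacing,
     labels = 0:2)
}

# independent brute-force Dice oracle: enumerates every voxel explicitly
# and counts set memberships. Deliberately naive; never calls diceScore.
bruteForceDice <- function(a, b, target, bothEmpty = 1) {
  va <- voxels(a); vb <- voxels(b)
  d <- dim(va)
  nA <- 0L; nB <- 0L; nAB <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    inA <- va[i, j, k] == target
    inB <- vb[i, j, k] == target
    if (inA) nA <- nA + 1L
    if (inB) nB <- nB + 1L
    if (inA && inB) nAB <- nAB + 1L
  }
  if (nA + nB == 0L) return(bothEmpty)
  2 * nAB / (nA + nB)
}

# an InterfoldResult carrying the given pairwise values (k inferred)
makeResult <- function(values, caseId = "t", targetLabel = 2L) {
  k <- (1 + sqrt(1 + 8 * length(values))) / 2
  stopifnot(k == round(k))
  nm <- character(0)
  for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k))
    nm <- c(nm, paste0(i, "-", j))
  new("InterfoldResult", caseId = caseId, targetLabel = targetLabel,
      pairwise = stats::setNames(values, nm),
      summaries = c(mean = mean(values), median = stats::median(values),
                    min = min(values), max = max(values)),
      k = as.integer(k))
}

# small, fast phantom used where absolute geometry does not matter
smallPhantom <- function(tumorRadiusMm = 8) {
  makePhantom(phantomConfig(gridShape = c(48L, 48L, 40L),
                            spacingMm = c(1, 1, 1),
                            organRadiiMm = c(16, 12, 10),
                            tumorRadiusMm = tumorRadiusMm,
                            tumorOffsetMm = c(4, 2, 2)))
}
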
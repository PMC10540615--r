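## Synthetic phantom cohort: organ+tumor label phantoms, K simulated fold
## predictions with controllable inter-fold agreement, and mixed
## in-distribution / out-of-distribution cohorts. This makes the whole
## flag-and-evaluate pipeline testable with no trained network and no
## patient data: the method consumes label geometry, not images.

.BACKGROUND <- 0L
.ORGAN <- 1L
.TUMOR <- 2L

# deterministic substream derivation: adding cases or folds never perturbs
# the draws of existing ones. The base is multiplied by an LCG constant
# before the counter is added so that nested derivations (case -> fold) do
# not collapse onto each other's streams. Kept below 2^31 - 1 (doubles stay
# well under 2^53, so the arithmetic is exact).
.deriveSeed <- function(base, counter) {
  as.integer((as.numeric(base) %% 2147483647 * 48271 +
                counter * 1000003) %% 2147483647)
}

#' Phantom geometry configuration
#'
#' Describes an organ-plus-tumor label phantom: an organ ellipsoid (label 1)
#' centred in the grid and a spherical tumor (label 2, overriding the organ
#' where they intersect) at a configurable offset. A stand-in for
#' kidney-plus-tumor anatomy; intensity is not simulated because the QC
#' method consumes predictions, not images.
#'
#' @param gridShape integer(3) grid dimensions.
#' @param spacingMm numeric(3) voxel spacing in mm.
#' @param organRadiiMm numeric(3) organ ellipsoid semi-axes in mm.
#' @param tumorRadiusMm tumor radius in mm (> 0; a radius smaller than a
#'   voxel still occupies the voxel nearest its centre).
#' @param tumorOffsetMm numeric(3) tumor centre offset from the organ centre,
#'   mm. The tumor must fit inside the grid.
#' @param labels label vocabulary; fixed at background 0, organ 1, tumor 2.
#' @return a validated list of class \code{"phantomConfig"}.
#' @export
phantomConfig <- function(gridShape = c(64L, 64L, 48L),
                          spacingMm = c(1, 1, 1),
                          organRadiiMm = c(22, 15, 13),
                          tumorRadiusMm = 8,
                          tumorOffsetMm = c(6, 4, 3),
                          labels = c(0L, 1L, 2L)) {
  gridShape <- as.integer(gridShape)
  stopifnot(length(gridShape) == 3L, all(gridShape >= 1L),
            length(spacingMm) == 3L, all(spacingMm > 0),
            length(organRadiiMm) == 3L, all(organRadiiMm > 0),
            length(tumorRadiusMm) == 1L, tumorRadiusMm > 0,
            length(tumorOffsetMm) == 3L,
            identical(as.integer(labels), c(0L, 1L, 2L)))
  halfExtent <- (gridShape - 1) / 2 * spacingMm
  if (any(abs(tumorOffsetMm) + tumorRadiusMm > halfExtent))
    stop("tumor does not fit inside the grid")
  structure(list(gridShape = gridShape, spacingMm = as.numeric(spacingMm),
                 organRadiiMm = as.numeric(organRadiiMm),
                 tumorRadiusMm = as.numeric(tumorRadiusMm),
                 tumorOffsetMm = as.numeric(tumorOffsetMm),
                 labels = c(0L, 1L, 2L)),
            class = "phantomConfig")
}

#' Fold-perturbation configuration
#'
#' The knobs that turn one ground truth into K discordant fold predictions.
#' Each fold independently draws (i) a signed boundary operation of radius
#' uniform in \{-boundaryRadiusVoxels, ..., +boundaryRadiusVoxels\} applied to
#' the target label (negative = erode, positive = dilate, spherical
#' structuring element), (ii) a rigid per-axis integer shift uniform in
#' \{-shiftVoxels, ..., +shiftVoxels\}, and (iii) with probability
#' \code{missProb} a complete miss of the target label. Zero perturbation
#' reproduces the truth exactly; each knob monotonically reduces expected
#' inter-fold Dice.
#'
#' @param boundaryRadiusVoxels non-negative integer, max erosion/dilation
#'   radius in voxels.
#' @param shiftVoxels non-negative integer, max per-axis rigid jitter.
#' @param missProb per-fold probability of emitting the target label empty,
#'   in [0, 1].
#' @param softSigmaMm non-negative smoothing width (mm) used to turn the hard
#'   folds into soft probability fields; 0 gives exact one-hot fields.
#' @param seed integer seed; per-fold substreams are derived from it by
#'   counter, so fold i's draws never depend on k.
#' @return a validated list of class \code{"perturbationConfig"}.
#' @export
perturbationConfig <- function(boundaryRadiusVoxels = 0L, shiftVoxels = 0L,
                               missProb = 0, softSigmaMm = 0, seed = 1L) {
  stopifnot(boundaryRadiusVoxels >= 0L, shiftVoxels >= 0L,
            missProb >= 0, missProb <= 1, softSigmaMm >= 0)
  structure(list(boundaryRadiusVoxels = as.integer(boundaryRadiusVoxels),
                 shiftVoxels = as.integer(shiftVoxels),
                 missProb = as.numeric(missProb),
                 softSigmaMm = as.numeric(softSigmaMm),
                 seed = as.integer(seed)),
            class = "perturbationConfig")
}

#' Build an organ+tumor label phantom
#'
#' Deterministic given its configuration: organ ellipsoid labelled 1, tumor
#' sphere labelled 2 overriding the organ where they intersect, background 0.
#' The \code{seed} argument is accepted for interface stability (stochastic
#' phantom variants would consume it) but current phantoms draw nothing.
#'
#' @param config a [phantomConfig()].
#' @param seed integer (reserved; phantoms are deterministic in config).
#' @return a \linkS4class{LabelVolume} with the grid and spacing of the
#'   config.
#' @export
makePhantom <- function(config, seed = 0L) {
  stopifnot(inherits(config, "phantomConfig"))
  d <- config$gridShape
  sp <- config$spacingMm
  centreMm <- (d + 1) / 2 * sp  # physical centre of the grid
  ax <- lapply(1:3, function(a) (seq_len(d[a]) * sp[a] - centreMm[a]))
  insideEllipsoid <- function(centre, radii) {
    q1 <- ((ax[[1L]] - centre[1L]) / radii[1L])^2
    q2 <- ((ax[[2L]] - centre[2L]) / radii[2L])^2
    q3 <- ((ax[[3L]] - centre[3L]) / radii[3L])^2
    outer(outer(q1, q2, `+`), q3, `+`) <= 1
  }
  organ <- insideEllipsoid(c(0, 0, 0), config$organRadiiMm)
  tumor <- insideEllipsoid(config$tumorOffsetMm, rep(config$tumorRadiusMm, 3L))
  if (!any(tumor)) {
    # sub-voxel tumor: it still occupies the voxel nearest its centre
    nearest <- pmin(pmax(round((config$tumorOffsetMm + centreMm) / sp), 1), d)
    tumor[nearest[1L], nearest[2L], nearest[3L]] <- TRUE
  }
  vox <- array(.BACKGROUND, d)
  vox[organ] <- .ORGAN
  vox[tumor] <- .TUMOR
  LabelVolume(vox, spacing = sp, labels = config$labels, caseId = "phantom")
}

# apply one fold's draw (boundary op, shift, miss) to the truth
.perturbOnce <- function(truth, targetLabel, opRadius, shift, miss) {
  vox <- truth@voxels
  tmask <- vox == targetLabel
  organUnion <- vox != .BACKGROUND
  if (miss) {
    tmask <- array(FALSE, dim(vox))
  } else if (opRadius > 0L) {
    tmask <- .binaryDilate(tmask, opRadius)
  } else if (opRadius < 0L) {
    tmask <- .binaryErode(tmask, -opRadius)
  }
  out <- array(.BACKGROUND, dim(vox))
  out[organUnion] <- .ORGAN   # a missed tumor is predicted as organ
  out[tmask] <- targetLabel
  if (any(shift != 0L)) out <- .shiftArray(out, shift, fill = .BACKGROUND)
  storage.mode(out) <- "integer"
  out
}

#' Simulate K fold predictions for one ground truth
#'
#' Emulates the inter-fold disagreement of a K-fold cross-validation
#' ensemble: each fold applies an independent random boundary operation,
#' rigid jitter and possible miss to the truth (see [perturbationConfig()]).
#' With all knobs at zero every fold equals the truth and all pairwise Dices
#' are 1; with \code{missProb = 1} all folds miss consistently, which under
#' the both-empty Dice convention also yields pairwise 1 -- the confident
#' consistent failure that inter-fold disagreement cannot flag.
#'
#' @param truth a \linkS4class{LabelVolume} ground truth.
#' @param k number of folds (>= 2).
#' @param pert a [perturbationConfig()].
#' @param targetLabel the perturbed label (default 2, the tumor).
#' @param withProbabilities also build soft fields: the Gaussian-smoothed
#'   (width \code{softSigmaMm}), per-voxel-renormalized one-hot encoding of
#'   each perturbed fold.
#' @return a \linkS4class{FoldSet} with \code{reference = truth}.
#' @export
simulateFoldPredictions <- function(truth, k, pert, targetLabel = .TUMOR,
                                    withProbabilities = FALSE) {
  stopifnot(inherits(pert, "perturbationConfig"))
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  folds <- vector("list", k)
  probs <- if (withProbabilities) vector("list", k) else list()
  classLabels <- truth@labels
  for (i in seq_len(k)) {
    set.seed(.deriveSeed(pert$seed, i))
    r <- pert$boundaryRadiusVoxels
    opRadius <- if (r > 0L) sample(seq.int(-r, r), 1L) else 0L
    s <- pert$shiftVoxels
    shift <- if (s > 0L) sample(seq.int(-s, s), 3L, replace = TRUE)
    else integer(3L)
    miss <- stats::runif(1L) < pert$missProb
    vox <- .perturbOnce(truth, targetLabel, opRadius, shift, miss)
    folds[[i]] <- LabelVolume(vox, spacing = truth@spacing,
                              labels = classLabels, caseId = truth@caseId,
                              foldId = as.character(i))
    if (withProbabilities) {
      oh <- oneHotProbabilities(folds[[i]], classLabels)
      if (pert$softSigmaMm > 0) {
        p <- oh@probs
        for (ci in seq_along(classLabels))
          p[, , , ci] <- .gaussianSmooth(p[, , , ci], pert$softSigmaMm,
                                         truth@spacing)
        norm <- rowSums(matrix(p, ncol = length(classLabels)))
        p <- p / array(norm, dim(p))
        oh <- ProbabilityVolume(p, classLabels, truth@spacing,
                                caseId = truth@caseId, foldId = as.character(i))
      }
      probs[[i]] <- oh
    }
  }
  FoldSet(folds, probabilities = probs, reference = truth,
          caseId = truth@caseId)
}

#' Cohort simulation specification
#'
#' A mixed cohort of in-distribution cases (mild perturbations, large tumors
#' as in a radical-nephrectomy training distribution) and out-of-distribution
#' cases (strong perturbations, distinctly smaller tumors -- the domain-shift
#' motif in which a model trained on large tumors meets a small-tumor task
#' set). Per-case arm labels are recorded so recovery can be tested.
#'
#' @param nIn,nOut arm sizes (non-negative, not both zero).
#' @param inPert,outPert [perturbationConfig()] for each arm (the seed fields
#'   are ignored; per-case seeds are derived from \code{masterSeed}).
#' @param kFolds folds per case (>= 2).
#' @param masterSeed integer master seed; every draw in the cohort is a
#'   deterministic function of it.
#' @param phantom list of phantom sampling parameters: \code{gridShape},
#'   \code{spacingMm}, \code{organRadiiMm}, per-arm tumor radius ranges
#'   \code{tumorRadiusRangeInMm} / \code{tumorRadiusRangeOutMm},
#'   \code{tumorOffsetMm} and per-axis jitter \code{offsetJitterMm}.
#' @return a validated list of class \code{"cohortSpec"}.
#' @export
cohortSpec <- function(nIn = 30L, nOut = 30L,
                       inPert = perturbationConfig(boundaryRadiusVoxels = 1L,
                                                   shiftVoxels = 1L,
                                                   missProb = 0),
                       outPert = perturbationConfig(boundaryRadiusVoxels = 3L,
                                                    shiftVoxels = 4L,
                                                    missProb = 0.35),
                       kFolds = 5L, masterSeed = 42L,
                       phantom = list()) {
  nIn <- as.integer(nIn); nOut <- as.integer(nOut)
  if (nIn < 0L || nOut < 0L || nIn + nOut == 0L)
    stop("arm sizes must be non-negative and not both zero")
  stopifnot(inherits(inPert, "perturbationConfig"),
            inherits(outPert, "perturbationConfig"), kFolds >= 2L)
  ph <- utils::modifyList(.defaultPhantomSampler(), phantom)
  structure(list(nIn = nIn, nOut = nOut, inPert = inPert, outPert = outPert,
                 kFolds = as.integer(kFolds),
                 masterSeed = as.integer(masterSeed), phantom = ph),
            class = "cohortSpec")
}

# The phantom sampling defaults are the fixture study conditions; rationale
# (voxel size, tumor-size arms relative to reported kidney-tumor volume
# distributions) is laid out in the methods vignette.
.defaultPhantomSampler <- function() {
  list(gridShape = c(114L, 106L, 104L),
       spacingMm = c(1, 1, 1),
       organRadiiMm = c(45, 30, 26),
       tumorRadiusRangeInMm = c(30, 42),
       tumorRadiusRangeOutMm = c(8, 20),
       tumorOffsetMm = c(10, 6, 5),
       offsetJitterMm = 2)
}

#' The default mixed synthetic cohort
#'
#' The versioned fixture configuration: 30 in-distribution + 30
#' out-of-distribution cases, 5 folds, master seed 42, default phantom
#' sampler and the default per-arm perturbations (in-dist: boundary 1 voxel,
#' shift 1, no misses; OOD: boundary 3, shift 4, miss probability 0.35,
#' smaller tumors). The same configuration ships as
#' \code{inst/extdata/default_cohort.yaml}.
#'
#' @param nIn,nOut,masterSeed overrides for the arm sizes and seed.
#' @return a [cohortSpec()].
#' @export
defaultCohortSpec <- function(nIn = 30L, nOut = 30L, masterSeed = 42L) {
  cohortSpec(nIn = nIn, nOut = nOut, masterSeed = masterSeed)
}

#' Simulate a mixed in-distribution / out-of-distribution cohort
#'
#' Samples one phantom per case (the OOD arm drawing from the smaller tumor
#' radius range), perturbs it per the arm's configuration, and records the
#' true arm label for recovery testing. Fully reproducible from the master
#' seed; per-case substreams are derived by counter, so changing arm sizes
#' does not perturb the draws of existing cases.
#'
#' @param spec a [cohortSpec()].
#' @param withProbabilities also build soft probability fields per fold.
#' @return a list of class \code{"qcCohort"} with elements \code{cases} (a
#'   list of records: \code{foldSet}, \code{arm}, \code{caseId},
#'   \code{tumorVolumeMl}) and \code{spec}.
#' @export
simulateCohort <- function(spec, withProbabilities = FALSE) {
  stopifnot(inherits(spec, "cohortSpec"))
  ph <- spec$phantom
  nTotal <- spec$nIn + spec$nOut
  cases <- vector("list", nTotal)
  for (i in seq_len(nTotal)) {
    inDist <- i <= spec$nIn
    caseSeed <- .deriveSeed(spec$masterSeed, i)
    set.seed(caseSeed)
    rng <- if (inDist) ph$tumorRadiusRangeInMm else ph$tumorRadiusRangeOutMm
    radius <- stats::runif(1L, rng[1L], rng[2L])
    offset <- ph$tumorOffsetMm +
      stats::runif(3L, -ph$offsetJitterMm, ph$offsetJitterMm)
    cfg <- phantomConfig(gridShape = ph$gridShape, spacingMm = ph$spacingMm,
                         organRadiiMm = ph$organRadiiMm,
                         tumorRadiusMm = radius, tumorOffsetMm = offset)
    truth <- makePhantom(cfg)
    truth@caseId <- sprintf("case_%03d", i)
    pert <- if (inDist) spec$inPert else spec$outPert
    pert$seed <- .deriveSeed(caseSeed, 1L)
    fs <- simulateFoldPredictions(truth, spec$kFolds, pert,
                                  withProbabilities = withProbabilities)
    cases[[i]] <- list(foldSet = fs,
                       arm = if (inDist) "in_distribution" else "out_of_distribution",
                       caseId = truth@caseId,
                       tumorVolumeMl = labelVolumeMl(truth, .TUMOR))
  }
  structure(list(cases = cases, spec = spec), class = "qcCohort")
}
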
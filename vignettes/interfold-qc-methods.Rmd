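---
title: "Reference-free QC of ensemble segmentations by inter-fold disagreement"
author: "interfoldQC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free QC of ensemble segmentations by inter-fold disagreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interfoldQC)
```

## The problem

A segmentation network in a clinical workflow will produce a prediction for
any properly formatted input, with no built-in signal of how trustworthy that
prediction is. When the input is poorly represented in the training data --
out-of-distribution contrast phases, unusually small tumors, corrupted scans
-- the prediction can be badly wrong, and no reference standard exists at
inference time to catch it. `interfoldQC` implements a reference-free quality
monitor for the common K-fold cross-validation ensemble setting: the K
sub-models (one per train/validation split) are queried individually, their
mutual agreement is measured, and cases where the sub-models disagree more
than two human experts plausibly would are flagged for review.

The intuition is epistemic: if the test case is well represented in training,
all K sub-models have seen enough similar examples to converge to similar
predictions despite their different splits. If it is not, the folds diverge --
inter-fold variance is a cheap, always-available surrogate for model
uncertainty, obtained without training any auxiliary model.

## The statistic

For one case and one target label (one anatomical structure at a time), the
Dice similarity

$$\mathrm{DSC}(A, B) = \frac{2\,|A \cap B|}{|A| + |B|}$$

is computed between every unordered pair of the K fold predictions, giving
$\binom{K}{2}$ pairwise values (10 for the usual K = 5). These "interfold
Dices" are collapsed by a first-order summary -- mean, median, minimum or
maximum -- and the case is flagged when the summary is **strictly below** a
threshold. The median is the default summary: it is robust to a single
discordant fold while still collapsing when the majority disagree.

The threshold is not learned from data. It is derived from published human
interobserver Dice values for the same (or the closest available) task: the
arithmetic mean of the published values, a published low--high range
contributing its midpoint. The package ships this derivation as
`deriveThreshold()`, with provenance stored so the value is exactly
re-derivable:

```{r thresholds}
deriveThreshold(c(0.87, 0.78), "kidney tumor MR")
deriveThreshold(list(c(0.91, 0.93), 0.87), "kidney tumor CT")
```

For the CT task the two sources average to 0.895; the conventional working
value 0.90 is obtained with `roundingDecimals = 2`. The package stores full
precision by default and treats rounding as presentation: the two differ by
half a percent of Dice, well inside interobserver noise, but the unrounded
value is the reproducible one.

## Ensembling

The final prediction scored in evaluation mode is the standard
cross-validation ensemble: the voxel-wise arithmetic mean of the K softmax
probability fields, each voxel assigned the class of maximal averaged
probability (`ensembleFromProbabilities()`). For two classes this is exactly
rounding the averaged foreground probability at 0.5. Averaging is done in
linear probability space, matching how such ensembles are actually computed.
Exact ties go to the lowest class label -- deterministic and
background-favoring; ties are measure-zero for real softmax outputs, so the
rule only matters for degenerate (e.g. one-hot) inputs. When soft outputs
were not exported, `ensembleFromLabels()` takes a per-voxel plurality vote,
which is provably the same as averaging one-hot encodings (a tested
invariant).

## Conventions at the edges

Three edge conventions are deliberate and configurable or documented:

* **Both folds empty at the target label**: Dice is taken as 1 (two empty
  segmentations agree perfectly). This means a case where *all* folds
  consistently miss the structure shows perfect agreement and is not
  flagged -- the method's honest blind spot: it detects *disagreement*, not
  *confident error*. An override to 0 is provided (`bothEmpty = 0`) for
  pipelines that prefer to flag empty consensus.
* **Exactly one fold empty**: Dice 0 (maximal disagreement).
* **Equality at a threshold**: flagging uses a strict `<`, so a summary
  exactly at threshold passes; symmetrically, an ensemble Dice exactly at the
  performance threshold counts as "performed well" in evaluation.

Grids must match exactly across folds and reference; no resampling or
registration is attempted, because fold predictions of one model on one image
share a grid by construction. A mismatch is treated as a data error, reported
per case without aborting the run.

Standard deviations in cohort summaries use the sample convention (n - 1).
Statistics of an empty subset (e.g. the non-flagged arm when everything was
flagged) are reported as absent (`NA`), never as zero.

## Evaluation mode

With a reference standard available, each case's flagging decision is scored
against the ensemble's actual Dice: flagged-and-poor is a true positive,
not-flagged-but-poor a false negative (the costly failure: an unreviewed bad
segmentation), and so on; the performance cutoff defaults to the same
interobserver threshold used for flagging. `runEvaluate()` produces the
per-case report, the confusion matrix, flagged/non-flagged cohort statistics,
and a flag-rate stratification over a per-case feature such as tumor volume.
`sensitivityScan()` re-applies the rule over a grid of thresholds; because
flagging is a strict comparison on a fixed per-case summary, flagged sets are
nested and counts non-decreasing in the threshold (a tested invariant).

## The synthetic cohort

No patient data or trained network ships with the package, so every stage is
exercised on simulated label geometry. The simulator is first-class, tested
code, not a fixture dump.

**Phantom.** `makePhantom()` builds an organ ellipsoid (label 1) with a
spherical tumor (label 2) at an offset -- kidney-plus-tumor geometry reduced
to what the method actually consumes, label masks on a grid. Intensities,
texture and anatomy beyond two nested structures are deliberately not
simulated: the QC statistic never sees the image.

**Fold perturbation.** `simulateFoldPredictions()` turns one truth into K
discordant folds. Each fold independently draws

* a signed boundary operation: erosion/dilation of the target label by a
  radius drawn uniformly from $\{-r, \dots, +r\}$ voxels, with a spherical
  (digital ball) structuring element -- models boundary-placement
  disagreement;
* a rigid per-axis integer shift uniform in $\{-s, \dots, +s\}$ -- models
  localization disagreement;
* with probability `missProb`, a complete miss of the target label, the
  missed region reverting to the surrounding organ label -- models a fold
  that finds no tumor at all.

These mechanics were chosen so that zero perturbation reproduces the truth
exactly (all pairwise Dice 1) and each knob monotonically reduces expected
inter-fold Dice -- both are tested properties, the monotone-degradation one
over boundary radii $\{0, 1, 3, 5\}$ across 20 seeds. Soft fields, when
requested, are the Gaussian-smoothed (width `softSigmaMm`),
per-voxel-renormalized one-hot encodings of the perturbed folds.

**Randomness contract.** One master seed; per-case and per-fold substreams
are derived deterministically by a counter hashed through an LCG-style
multiplier, so adding cases or folds never perturbs existing draws, and
identical specs give bit-identical volumes.

**The default mixed cohort** (`defaultCohortSpec()`, also shipped as
`inst/extdata/default_cohort.yaml`) emulates the domain-shift experiment
design: a model trained on large tumors meeting a small-tumor task set.

* Grid 114 x 106 x 104 at 1 mm isotropic spacing; organ semi-axes
  (45, 30, 26) mm. The 1 mm spacing is typical of in-plane CT resolution and
  keeps one-voxel boundary noise small relative to structure size.
* In-distribution arm (30 cases): tumor radius uniform in 30--42 mm
  (volumes roughly 113--310 ml, consistent with reported radical-nephrectomy
  tumor distributions whose median is around 200 ml); mild perturbation
  (boundary radius 1 voxel, shift 1 voxel, no misses).
* Out-of-distribution arm (30 cases): tumor radius uniform in 8--20 mm
  (roughly 2--34 ml, distinctly smaller, matching the motif that flagged
  cases concentrate at small tumor volumes); strong perturbation (boundary
  radius 3, shift 4, miss probability 0.35).

With these conditions, flagging at threshold 0.9 on the median recovers the
OOD arm with sensitivity above 0.9 at a zero-to-low in-distribution
false-flag rate, and excluding flagged cases raises the retained cohort's
mean ensemble Dice substantially -- the qualitative pattern the method is
designed to produce. About 5% of OOD cases draw four or five simultaneous
misses; their folds agree perfectly on an empty tumor and are unflaggable by
construction (the blind spot above), which is why recovery is not expected to
reach 1.0.

**What the simulator does not show.** Passing on phantoms demonstrates the
statistic's mechanics -- pair computation, thresholding, evaluation wiring,
monotone response to injected disagreement -- not clinical performance. Real
fold disagreement is spatially structured, correlated across folds, and
coupled to image content in ways independent morphological noise is not; real
interobserver thresholds are task-specific. Deploying the method on a new
task should follow the practice the evaluation machinery supports: derive a
task-specific interobserver threshold and run a sensitivity scan.

## Numerical and design choices

* Morphology is implemented as shift-OR/AND accumulation over the digital
  ball's offsets, cropped to the target's bounding box plus the radius, so
  cost scales with structure size rather than grid size. No installed R
  package provides 3D binary morphology on plain arrays, so it is
  implemented here and oracle-tested.
* Dice is computed on logical masks with integer accumulation; it is exactly
  spacing-invariant, and `labelVolumeMl()` is exactly linear in each spacing
  component (tested).
* The median of the (even-length, for K = 5) pairwise vector is the midpoint
  of the two central order statistics, i.e. `stats::median()`.
* Threshold rounding, when requested, is half-up (not banker's), because
  that is how printed clinical thresholds are conventionally obtained.
* Reports format floats at 6 decimals and preserve manifest order, making
  reruns byte-identical; per-case failures (e.g. a mismatched grid) become
  `status = "failed"` rows rather than aborting the run.
* Problem sizes in the test suite: oracle checks run on grids up to
  10 x 10 x 10 voxels against a brute-force voxel-enumeration Dice;
  pipeline tests use 40--48 voxel grids; the recovery check runs the full
  default 60-case cohort.

## Limitations

* Confident consistent errors -- all folds wrong in the same way, including
  unanimous misses -- produce high agreement and cannot be flagged by any
  disagreement statistic. This is inherent to the approach, not an
  implementation limit.
* The interobserver thresholds shipped in examples come from tasks related
  to, but not identical with, any new deployment task; they are defaults to
  be replaced by task-specific studies.
* Only overlap (Dice) is implemented; surface-distance metrics are out of
  scope.
* No automatic threshold learning: the design position is that the threshold
  should come from human interobserver evidence, with `sensitivityScan()`
  for exploring the trade-off.
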
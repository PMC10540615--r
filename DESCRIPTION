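Package: interfoldQC
Title: Reference-Free Quality Control of Ensemble Image Segmentations via
    Inter-Fold Disagreement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Flags automated 3D image segmentations that need human review
    without consulting a reference standard. For a K-fold cross-validation
    ensemble, the Dice similarity between every pair of per-fold (sub-model)
    predictions is computed on a target label, summarized by a first-order
    statistic (mean, median, minimum or maximum), and compared against a
    threshold derived from published human interobserver Dice values; cases
    whose summarized inter-fold Dice falls below the threshold are flagged as
    likely out-of-distribution or otherwise unreliable. Includes ensemble
    reconstruction by voxel-wise softmax-probability averaging, evaluation
    machinery (confusion matrices against a reference standard, flagged versus
    non-flagged cohort statistics, threshold sensitivity scans, feature
    stratification), NIfTI input and output, and a synthetic phantom cohort
    simulator with controllable inter-fold agreement so the full pipeline is
    testable without trained networks or patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    oro.nifti,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
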
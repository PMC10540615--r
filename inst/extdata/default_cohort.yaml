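# Default mixed synthetic cohort: 30 in-distribution cases with mild
# perturbations and large tumors, 30 out-of-distribution cases with strong
# perturbations and distinctly smaller tumors. These are the versioned
# fixture conditions used throughout the test suite.
n_in_distribution: 30
n_out_of_distribution: 30
k_folds: 5
master_seed: 42
in_dist:
  boundaryRadiusVoxels: 1
  shiftVoxels: 1
  missProb: 0.0
  softSigmaMm: 0.0
  seed: 1
out_dist:
  boundaryRadiusVoxels: 3
  shiftVoxels: 4
  missProb: 0.35
  softSigmaMm: 0.0
  seed: 1
phantom:
  gridShape: [114, 106, 104]
  spacingMm: [1.0, 1.0, 1.0]
  organRadiiMm: [45.0, 30.0, 26.0]
  tumorRadiusRangeInMm: [30.0, 42.0]
  tumorRadiusRangeOutMm: [8.0, 20.0]
  tumorOffsetMm: [10.0, 6.0, 5.0]
  offsetJitterMm: 2.0
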
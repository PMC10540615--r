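#' @rdname LabelVolume-class
#' @param object,x an object.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname LabelVolume-class
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname LabelVolume-class
#' @export
setGeneric("labelValues", function(x) standardGeneric("labelValues"))

#' @rdname LabelVolume-class
#' @export
setGeneric("caseId", function(x) standardGeneric("caseId"))

#' @rdname LabelVolume-class
#' @export
setGeneric("foldId", function(x) standardGeneric("foldId"))

#' @rdname FoldSet-class
#' @export
setGeneric("nFolds", function(x) standardGeneric("nFolds"))

#' @rdname FoldSet-class
#' @export
setGeneric("foldPredictions", function(x) standardGeneric("foldPredictions"))

#' @rdname FoldSet-class
#' @export
setGeneric("foldProbabilities", function(x) standardGeneric("foldProbabilities"))

#' @rdname FoldSet-class
#' @export
setGeneric("referenceVolume", function(x) standardGeneric("referenceVolume"))

#' @rdname InterfoldResult-class
#' @export
setGeneric("pairwiseDices", function(x) standardGeneric("pairwiseDices"))

#' @rdname InterfoldResult-class
#' @export
setGeneric("diceSummaries", function(x) standardGeneric("diceSummaries"))

#' @rdname ThresholdSpec-class
#' @export
setGeneric("thresholdValue", function(x) standardGeneric("thresholdValue"))

#' @rdname FlagDecision-class
#' @export
setGeneric("isFlagged", function(x) standardGeneric("isFlagged"))

#' @rdname ConfusionCounts-class
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
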
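#' @export
setGeneric("setId", function(x) standardGeneric("setId"))

#' @export
setGeneric("nIntervals", function(x) standardGeneric("nIntervals"))

#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @export
setGeneric("chromPartition", function(x) standardGeneric("chromPartition"))

#' @export
setGeneric("droppedRecords", function(x) standardGeneric("droppedRecords"))

#' @export
setGeneric("treeHeight", function(x) standardGeneric("treeHeight"))

#' @export
setGeneric("nLeaves", function(x) standardGeneric("nLeaves"))

#' @export
setGeneric("nStored", function(x) standardGeneric("nStored"))

#' @export
setGeneric("treeStats", function(x) standardGeneric("treeStats"))

#' @export
setGeneric("queryPoint", function(x, at) standardGeneric("queryPoint"))

#' @export
setGeneric("queryInterval",
           function(x, qlow, qhigh) standardGeneric("queryInterval"))

#' @export
setGeneric("cutoffDepth", function(x) standardGeneric("cutoffDepth"))

#' @export
setGeneric("presetValue", function(x) standardGeneric("presetValue"))

#' @export
setGeneric("nForestNodes", function(x) standardGeneric("nForestNodes"))

#' @export
setGeneric("bucketCount", function(x) standardGeneric("bucketCount"))

#' @export
setGeneric("forestStats", function(x) standardGeneric("forestStats"))

#' @export
setGeneric("sourceTree", function(x) standardGeneric("sourceTree"))

#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @export
setGeneric("contributorMatrix", function(x) standardGeneric("contributorMatrix"))
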
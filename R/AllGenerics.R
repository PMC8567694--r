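#' @rdname RmsScreenResult-class
#' @param object,x an object.
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))

#' @rdname RmsScreenResult-class
#' @export
setGeneric("rmsSubfamilies", function(x) standardGeneric("rmsSubfamilies"))

#' @rdname RmsScreenResult-class
#' @export
setGeneric("pmeis", function(x) standardGeneric("pmeis"))

#' @rdname SimulatedGenome-class
#' @export
setGeneric("teAnnotation", function(x) standardGeneric("teAnnotation"))

#' @rdname SimulatedGenome-class
#' @export
setGeneric("indelCalls", function(x) standardGeneric("indelCalls"))

#' @rdname SimulatedGenome-class
#' @export
setGeneric("crossGenomeMappings",
           function(x) standardGeneric("crossGenomeMappings"))

#' @rdname SimulatedGenome-class
#' @export
setGeneric("simulationTruth", function(x) standardGeneric("simulationTruth"))

#' @rdname EnrichmentResult-class
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname IndelOverlapGraph-class
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' @rdname IndelOverlapGraph-class
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname IndelOverlapGraph-class
#' @export
setGeneric("nodeDegrees", function(x) standardGeneric("nodeDegrees"))
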
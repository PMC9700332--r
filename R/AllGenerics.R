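#' @include AllClasses.R
NULL

#' @export
setGeneric("graphId", function(x) standardGeneric("graphId"))

#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @export
setGeneric("sourceNodes", function(x) standardGeneric("sourceNodes"))

#' @export
setGeneric("sinkNodes", function(x) standardGeneric("sinkNodes"))

#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @export
setGeneric("isConserving", function(x) standardGeneric("isConserving"))

#' @export
setGeneric("totalFlow", function(x) standardGeneric("totalFlow"))

#' @export
setGeneric("decompPaths", function(x) standardGeneric("decompPaths"))

#' @export
setGeneric("pathWeights", function(x) standardGeneric("pathWeights"))

#' @export
setGeneric("numPaths", function(x) standardGeneric("numPaths"))

#' @export
setGeneric("constraintLegs", function(x) standardGeneric("constraintLegs"))

#' @export
setGeneric("constraintSize", function(x) standardGeneric("constraintSize"))

#' @export
setGeneric("isValid", function(x) standardGeneric("isValid"))

#' @export
setGeneric("ensureSingleSourceSink", function(net) standardGeneric("ensureSingleSourceSink"))
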
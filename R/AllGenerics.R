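#' @include AllClasses.R
NULL

#' @export
setGeneric("traceIDs", function(x) standardGeneric("traceIDs"))

#' @export
setGeneric("nTraces", function(x) standardGeneric("nTraces"))

#' @export
setGeneric("intensities", function(x, i) standardGeneric("intensities"))

#' @export
setGeneric("traceLengths", function(x) standardGeneric("traceLengths"))

#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @export
setGeneric("traceData", function(x) standardGeneric("traceData"))

#' @export
setGeneric("traceData<-", function(x, value) standardGeneric("traceData<-"))

#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @export
setGeneric("modelFamily", function(x) standardGeneric("modelFamily"))

#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' @export
setGeneric("nParameters", function(x, ...) standardGeneric("nParameters"))

#' @export
setGeneric("frozenLayers", function(x) standardGeneric("frozenLayers"))

#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))
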
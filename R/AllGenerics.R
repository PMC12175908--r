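#' @rdname Ensemble-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname Ensemble-accessors
#' @export
setGeneric("nParticles", function(x) standardGeneric("nParticles"))

#' @rdname Ensemble-accessors
#' @export
setGeneric("frameCoords", function(x, frame) standardGeneric("frameCoords"))

#' @rdname Ensemble-accessors
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

#' @rdname Ensemble-accessors
#' @export
setGeneric("priorWeights", function(x) standardGeneric("priorWeights"))

#' @rdname Ensemble-accessors
#' @export
setGeneric("priorWeights<-", function(x, value) standardGeneric("priorWeights<-"))

#' @rdname Ensemble-accessors
#' @export
setGeneric("trueWeights", function(x) standardGeneric("trueWeights"))

#' @rdname Ensemble-accessors
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname Ensemble-accessors
#' @export
setGeneric("residueNumbers", function(x, chain) standardGeneric("residueNumbers"))

#' @rdname refinedWeights
#' @export
setGeneric("refinedWeights", function(x) standardGeneric("refinedWeights"))
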
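#' @import methods
NULL

#' @rdname PulseSignal-class
#' @param object,x an object
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))

#' @rdname PulseSignal-class
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))

#' @rdname PulseSignal-class
#' @export
setGeneric("startTime", function(object) standardGeneric("startTime"))

#' @rdname PulseSignal-class
#' @export
setGeneric("signalUnits", function(object) standardGeneric("signalUnits"))

#' @rdname PulseSignal-class
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname PulseSignal-class
#' @export
setGeneric("duration", function(object) standardGeneric("duration"))

#' @rdname PulseSignal-class
#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))

#' @rdname ArtifactMask-class
#' @param object an object
#' @export
setGeneric("maskIntervals", function(object) standardGeneric("maskIntervals"))

#' @rdname PulseSignal-class
#' @export
setGeneric("beatTruth", function(object) standardGeneric("beatTruth"))

#' @rdname DensityGrid-class
#' @param object an object
#' @export
setGeneric("densityMatrix", function(object) standardGeneric("densityMatrix"))

#' @rdname DensityGrid-class
#' @export
setGeneric("gridExtent", function(object) standardGeneric("gridExtent"))
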
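#' @include AllClasses.R
NULL

#' @rdname Frame
#' @param object,x a \code{Frame}
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname Frame
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))

#' @rdname Frame
#' @export
setGeneric("timeIndex", function(x) standardGeneric("timeIndex"))

#' @rdname Frame
#' @export
setGeneric("phaseLabel", function(x) standardGeneric("phaseLabel"))

#' @rdname TimeLapse
#' @export
setGeneric("nTimePoints", function(x) standardGeneric("nTimePoints"))

#' @rdname TimeLapse
#' @export
setGeneric("phaseLabels", function(x) standardGeneric("phaseLabels"))

#' @rdname TimeLapse
#' @export
setGeneric("getFrame", function(x, time, phase) standardGeneric("getFrame"))

#' @rdname CellDetection
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' @rdname CellDetection
#' @export
setGeneric("pixelSet", function(x) standardGeneric("pixelSet"))

#' @rdname CellDetection
#' @export
setGeneric("detectionId", function(x) standardGeneric("detectionId"))

#' @rdname Track
#' @export
setGeneric("trackId", function(x) standardGeneric("trackId"))

#' @rdname Track
#' @export
setGeneric("stepDistances", function(x) standardGeneric("stepDistances"))

#' @rdname SyntheticScene
#' @export
setGeneric("sceneTruth", function(x) standardGeneric("sceneTruth"))
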
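#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname CellDetection
#' @param x a \code{CellDetection}
#' @export
setMethod("features", "CellDetection", function(x) x@features)

#' @rdname CellDetection
#' @export
setMethod("pixelSet", "CellDetection", function(x) x@pixels)

#' @rdname CellDetection
#' @export
setMethod("detectionId", "CellDetection", function(x) x@detectionId)

#' @rdname CellDetection
#' @export
setMethod("timeIndex", "CellDetection", function(x) x@timeIndex)

setMethod("show", "CellDetection", function(object) {
  f <- object@features
  cat(sprintf(
    "CellDetection %s (t=%d, %s): centroid (%.1f, %.1f), area %d, ecc %.2f\n",
    object@detectionId, object@timeIndex, object@phaseLabel,
    f$centroid[1], f$centroid[2], f$area, f$eccentricity))
})
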
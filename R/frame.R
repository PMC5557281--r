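#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a Frame
#'
#' Validating constructor for a single image plane. Pixel values are coerced
#' to integer storage; fractional input is rejected.
#'
#' @param pixels numeric matrix of non-negative integer intensities with at
#'   least 32 rows and 32 columns.
#' @param bitDepth 8 or 16 (default 16; intensity ceilings of 65535 in
#'   typical calcium-indicator data imply 16-bit sources).
#' @param timeIndex 0-based time point (default 0).
#' @param phaseLabel phase/channel label (default \code{"phase1"}).
#' @return a [Frame-class] object.
#' @examples
#' f <- Frame(matrix(0L, 64, 64))
#' dim(pixels(f))
#' @export
Frame <- function(pixels, bitDepth = 16L, timeIndex = 0L,
                  phaseLabel = "phase1") {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (any(pixels != round(pixels)))
    stop("pixels must contain integer intensities")
  storage.mode(pixels) <- "integer"
  new("Frame", pixels = pixels, bitDepth = as.integer(bitDepth),
      timeIndex = as.integer(timeIndex), phaseLabel = phaseLabel)
}

#' @rdname Frame
#' @export
setMethod("pixels", "Frame", function(x) x@pixels)

#' @rdname Frame
#' @export
setMethod("bitDepth", "Frame", function(x) x@bitDepth)

#' @rdname Frame
#' @export
setMethod("timeIndex", "Frame", function(x) x@timeIndex)

#' @rdname Frame
#' @export
setMethod("phaseLabel", "Frame", function(x) x@phaseLabel)

setMethod("show", "Frame", function(object) {
  cat(sprintf("Frame %dx%d, %d-bit, t=%d, phase=%s\n",
              nrow(object@pixels), ncol(object@pixels), object@bitDepth,
              object@timeIndex, object@phaseLabel))
  cat(sprintf("  intensity range [%d, %d]\n",
              min(object@pixels), max(object@pixels)))
})

#' Construct a TimeLapse
#'
#' @param frames list of [Frame-class] objects; reordered by
#'   \code{(timeIndex, phaseLabel)} before validation.
#' @param pixelResolutionNote optional provenance note (free text, carried
#'   along but never used in computation).
#' @return a [TimeLapse-class] object.
#' @export
TimeLapse <- function(frames, pixelResolutionNote = NA_character_) {
  if (!length(frames)) stop("a TimeLapse must contain at least one frame")
  ti <- vapply(frames, function(f) f@timeIndex, integer(1))
  ph <- vapply(frames, function(f) f@phaseLabel, character(1))
  frames <- frames[order(ti, ph)]
  new("TimeLapse", frames = frames,
      pixelResolutionNote = pixelResolutionNote)
}

#' @rdname TimeLapse
#' @param x a \code{TimeLapse}
#' @export
setMethod("nTimePoints", "TimeLapse", function(x)
  length(unique(vapply(x@frames, function(f) f@timeIndex, integer(1)))))

#' @rdname TimeLapse
#' @export
setMethod("phaseLabels", "TimeLapse", function(x)
  sort(unique(vapply(x@frames, function(f) f@phaseLabel, character(1)))))

#' @rdname TimeLapse
#' @param time 0-based time point
#' @param phase phase label; defaults to the first phase
#' @export
setMethod("getFrame", "TimeLapse", function(x, time, phase) {
  if (missing(phase)) phase <- phaseLabels(x)[1]
  for (f in x@frames)
    if (f@timeIndex == time && f@phaseLabel == phase) return(f)
  stop(sprintf("no frame at time %d, phase %s", time, phase))
})

#' @rdname TimeLapse
#' @export
setMethod("length", "TimeLapse", function(x) length(x@frames))

setMethod("show", "TimeLapse", function(object) {
  f1 <- object@frames[[1]]
  cat(sprintf("TimeLapse: %d time points x %d phase(s), %dx%d, %d-bit\n",
              nTimePoints(object), length(phaseLabels(object)),
              nrow(f1@pixels), ncol(f1@pixels), f1@bitDepth))
  if (!is.na(object@pixelResolutionNote))
    cat("  note:", object@pixelResolutionNote, "\n")
})

#' @rdname TimeLapse
#' @export
frameDim <- function(x) dim(x@frames[[1]]@pixels)
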
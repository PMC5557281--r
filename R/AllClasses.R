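#' @import methods
NULL

#' Frame: a single microscopy image plane
#'
#' A \code{Frame} holds one grayscale image plane of a time-lapse sequence:
#' an integer pixel raster together with its bit depth, its 0-based position
#' in the time series and a phase (channel) label. The coordinate convention
#' throughout the package is 0-based \code{(row, col)} with row 0 at the top
#' of the image and pixel centers at integer coordinates.
#'
#' @slot pixels integer matrix of pixel intensities.
#' @slot bitDepth integer, 8 or 16; pixel values must lie in
#'   \code{[0, 2^bitDepth - 1]}.
#' @slot timeIndex 0-based integer time point.
#' @slot phaseLabel short character label for the imaging phase/channel.
#'
#' @seealso [Frame()] for the validating constructor.
#' @exportClass Frame
setClass("Frame",
  representation(
    pixels = "matrix",
    bitDepth = "integer",
    timeIndex = "integer",
    phaseLabel = "character"
  )
)

setValidity("Frame", function(object) {
  msgs <- character()
  px <- object@pixels
  if (!is.numeric(px)) msgs <- c(msgs, "pixels must be a numeric matrix")
  if (!(object@bitDepth %in% c(8L, 16L)))
    msgs <- c(msgs, "bitDepth must be 8 or 16")
  if (nrow(px) < 32L || ncol(px) < 32L)
    msgs <- c(msgs, "frame must be at least 32x32 pixels (one tile)")
  maxval <- 2^object@bitDepth - 1
  if (is.numeric(px) && length(px) &&
      (min(px) < 0 || max(px) > maxval))
    msgs <- c(msgs, sprintf("pixel values must lie in [0, %d]", maxval))
  if (length(object@timeIndex) != 1L || is.na(object@timeIndex) ||
      object@timeIndex < 0L)
    msgs <- c(msgs, "timeIndex must be a single non-negative integer")
  if (length(object@phaseLabel) != 1L || !nzchar(object@phaseLabel))
    msgs <- c(msgs, "phaseLabel must be a non-empty string")
  if (length(msgs)) msgs else TRUE
})

#' TimeLapse: an ordered multi-phase image sequence
#'
#' Container for the frames of one acquisition, grouped by time point and
#' phase. All frames share dimensions and bit depth; time indices are
#' consecutive from 0 and every time point carries the same set of phases.
#'
#' @slot frames list of [Frame-class] objects ordered by
#'   \code{(timeIndex, phaseLabel)}.
#' @slot pixelResolutionNote optional free-text provenance string carried
#'   through from acquisition metadata; never used in computation.
#'
#' @exportClass TimeLapse
setClass("TimeLapse",
  representation(
    frames = "list",
    pixelResolutionNote = "character"
  ),
  prototype(pixelResolutionNote = NA_character_)
)

setValidity("TimeLapse", function(object) {
  fr <- object@frames
  if (!length(fr)) return("a TimeLapse must contain at least one frame")
  if (!all(vapply(fr, is, logical(1), class2 = "Frame")))
    return("all elements of frames must be Frame objects")
  dims <- vapply(fr, function(f) dim(f@pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    return("all frames must share identical dimensions")
  bd <- vapply(fr, function(f) f@bitDepth, integer(1))
  if (any(bd != bd[1])) return("all frames must share the same bit depth")
  ti <- vapply(fr, function(f) f@timeIndex, integer(1))
  ph <- vapply(fr, function(f) f@phaseLabel, character(1))
  times <- sort(unique(ti))
  if (!identical(times, seq(0L, length.out = length(times))))
    return("time indices must be consecutive starting at 0")
  phases <- sort(unique(ph))
  for (t in times) {
    have <- sort(ph[ti == t])
    if (!identical(have, phases)) {
      missing <- setdiff(phases, have)
      return(sprintf("time point %d is missing phase(s): %s",
                     t, paste(missing, collapse = ", ")))
    }
  }
  ord <- order(ti, ph)
  if (!identical(ord, seq_along(fr)))
    return("frames must be ordered by (timeIndex, phaseLabel)")
  TRUE
})

#' CellDetection: one segmented cell in one frame
#'
#' The pixel set (0-based coordinates), tight bounding box and feature
#' vector of a single detected cell.
#'
#' @slot timeIndex 0-based time point of the detection.
#' @slot phaseLabel phase the detection was made on.
#' @slot pixels integer matrix with columns \code{row}, \code{col}
#'   (0-based) listing the member pixels; non-empty and 8-connected.
#' @slot bbox numeric \code{(min_row, min_col, max_row, max_col)}, half-open
#'   on the max edges, equal to the tight box of the pixel set.
#' @slot features named list produced by [computeRegionFeatures()].
#' @slot detectionId identifier unique within the frame.
#'
#' @exportClass CellDetection
setClass("CellDetection",
  representation(
    timeIndex = "integer",
    phaseLabel = "character",
    pixels = "matrix",
    bbox = "numeric",
    features = "list",
    detectionId = "character"
  )
)

setValidity("CellDetection", function(object) {
  px <- object@pixels
  if (!is.matrix(px) || ncol(px) != 2L || nrow(px) < 1L)
    return("pixels must be a non-empty 2-column (row, col) matrix")
  bb <- c(min(px[, 1]), min(px[, 2]), max(px[, 1]) + 1, max(px[, 2]) + 1)
  if (!isTRUE(all.equal(as.numeric(object@bbox), as.numeric(bb))))
    return("bbox must be the tight half-open bounding box of the pixel set")
  if (!.isConnected8(px))
    return("pixel set must be 8-connected")
  TRUE
})

#' Track: an identity-linked sequence of detections
#'
#' One cell followed through time. Entries are the detections where the cell
#' was found; a jump in \code{timeIndices} marks a bridged gap (frames the
#' tracker allowed the cell to go undetected).
#'
#' @slot trackId unique track identifier.
#' @slot timeIndices strictly increasing 0-based time points of the
#'   detected entries.
#' @slot detections list of [CellDetection-class], parallel to
#'   \code{timeIndices}.
#' @slot stepDistances Euclidean centroid displacement between consecutive
#'   detected entries (length one less than the number of entries).
#'
#' @exportClass Track
setClass("Track",
  representation(
    trackId = "character",
    timeIndices = "integer",
    detections = "list",
    stepDistances = "numeric"
  )
)

setValidity("Track", function(object) {
  ti <- object@timeIndices
  if (!length(ti)) return("a track must contain at least one detection")
  if (any(diff(ti) <= 0)) return("timeIndices must be strictly increasing")
  if (length(object@detections) != length(ti))
    return("detections and timeIndices must have equal length")
  if (length(object@stepDistances) != length(ti) - 1L)
    return("stepDistances must have one value per consecutive pair")
  cents <- t(vapply(object@detections,
                    function(d) d@features$centroid, numeric(2)))
  if (length(ti) > 1L) {
    d <- sqrt(rowSums((cents[-1, , drop = FALSE] -
                         cents[-nrow(cents), , drop = FALSE])^2))
    if (!isTRUE(all.equal(d, object@stepDistances)))
      return("stepDistances must equal centroid distances of consecutive entries")
  }
  TRUE
})

#' SyntheticScene: ground-truth cell states for a simulated time-lapse
#'
#' The hidden state of a simulated field of view: per frame and per cell the
#' center, radius, flash state and visibility, from which frames are
#' rendered and against which detection and tracking can be scored.
#'
#' @slot config the [sceneConfig()] list the scene was generated from.
#' @slot truth data.frame with columns \code{frame}, \code{cell},
#'   \code{row}, \code{col}, \code{radius}, \code{flashing},
#'   \code{visible}; one row per (frame, cell). Invisible cells keep their
#'   (out-of-bounds) center rather than being dropped.
#'
#' @exportClass SyntheticScene
setClass("SyntheticScene",
  representation(
    config = "ANY",
    truth = "data.frame"
  )
)

setValidity("SyntheticScene", function(object) {
  tr <- object@truth
  need <- c("frame", "cell", "row", "col", "radius", "flashing", "visible")
  if (!all(need %in% names(tr)))
    return(paste("truth must contain columns:", paste(need, collapse = ", ")))
  TRUE
})
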
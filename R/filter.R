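#' @include segment.R
NULL

#' Expert acceptance criteria for detected cells
#'
#' Declarative per-feature closed intervals; a detection is kept only if
#' every specified interval contains its feature value. This makes the
#' interactive "domain expert" judgement of which detections are real,
#' active T cells reproducible configuration.
#'
#' @param area,extent,eccentricity,maxIntensity,meanIntensity,majorAxis,minorAxis
#'   optional \code{c(lower, upper)} closed intervals.
#' @param requireActivity when TRUE, \code{maxIntensity} must additionally
#'   reach \code{activationFloor} (cells showing no calcium activity are
#'   noise).
#' @param activationFloor minimum peak intensity of an "active" cell; when
#'   NA it is derived per frame set as background mode + 3 robust noise
#'   scales (median absolute deviation, scaled).
#' @return validated criteria list of class \code{FilterCriteria}.
#' @export
filterCriteria <- function(area = NULL, extent = NULL, eccentricity = NULL,
                           maxIntensity = NULL, meanIntensity = NULL,
                           majorAxis = NULL, minorAxis = NULL,
                           requireActivity = FALSE,
                           activationFloor = NA_real_) {
  iv <- list(area = area, extent = extent, eccentricity = eccentricity,
             maxIntensity = maxIntensity, meanIntensity = meanIntensity,
             majorAxis = majorAxis, minorAxis = minorAxis)
  for (nm in names(iv)) .checkInterval(iv[[nm]], nm)
  structure(c(iv, list(requireActivity = isTRUE(requireActivity),
                       activationFloor = as.numeric(activationFloor))),
            class = c("FilterCriteria", "list"))
}

# feature-list field for each criteria name
.critFields <- c(area = "area", extent = "extent",
                 eccentricity = "eccentricity",
                 maxIntensity = "maxIntensity",
                 meanIntensity = "meanIntensity",
                 majorAxis = "majorAxis", minorAxis = "minorAxis")

#' Partition detections into kept and discarded
#'
#' @param detections list of [CellDetection-class] with complete features.
#' @param criteria a [filterCriteria()].
#' @param frame optional [Frame-class]; needed only when
#'   \code{requireActivity} is set with an NA \code{activationFloor}, to
#'   derive the floor from the frame background.
#' @return list with elements \code{kept} and \code{discarded} (both in the
#'   input order; together they partition the input).
#' @export
applyFilter <- function(detections, criteria = filterCriteria(),
                        frame = NULL) {
  if (!inherits(criteria, "FilterCriteria"))
    stop("criteria must be created by filterCriteria()")
  floorVal <- criteria$activationFloor
  if (criteria$requireActivity && is.na(floorVal)) {
    if (is.null(frame))
      stop("requireActivity with NA activationFloor needs the frame")
    floorVal <- .modalValue(frame@pixels) + 3 * stats::mad(as.numeric(frame@pixels))
  }
  ok <- vapply(detections, function(det) {
    f <- det@features
    for (nm in names(.critFields)) {
      iv <- criteria[[nm]]
      if (is.null(iv)) next
      v <- f[[.critFields[[nm]]]]
      if (is.null(v)) stop(sprintf("detection lacks feature '%s'", nm))
      if (v < iv[1] || v > iv[2]) return(FALSE)
    }
    if (criteria$requireActivity && f$maxIntensity < floorVal) return(FALSE)
    TRUE
  }, logical(1))
  list(kept = detections[ok], discarded = detections[!ok])
}

#' Erase discarded cells from a copy of the frame
#'
#' Returns a new frame in which exactly the union of the discarded
#' detections' pixel sets is reset to a background value; all other pixels
#' are unchanged and the input frame is untouched.
#'
#' @param frame a [Frame-class].
#' @param discarded list of [CellDetection-class] to erase.
#' @param backgroundValue intensity to write; default NA uses the frame's
#'   modal intensity.
#' @return a new [Frame-class].
#' @export
eraseCells <- function(frame, discarded, backgroundValue = NA) {
  px <- frame@pixels
  d <- dim(px)
  if (is.na(backgroundValue)) backgroundValue <- .modalValue(px)
  backgroundValue <- as.integer(backgroundValue)
  for (det in discarded) {
    p <- det@pixels
    if (min(p) < 0L || max(p[, 1]) >= d[1] || max(p[, 2]) >= d[2])
      stop("discarded detection has out-of-bounds pixels")
    px[cbind(p[, 1] + 1L, p[, 2] + 1L)] <- backgroundValue
  }
  new("Frame", pixels = px, bitDepth = frame@bitDepth,
      timeIndex = frame@timeIndex, phaseLabel = frame@phaseLabel)
}
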
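#' @include frame.R
NULL

#' Enhancement configuration
#'
#' @param saturationFraction fraction of pixels saturated at each end of the
#'   intensity range, in \code{[0, 0.5)}. The pipeline default of 0.01
#'   saturates 1 percent of the data at low and at high intensities.
#' @return validated config list of class \code{EnhancementConfig}.
#' @export
enhancementConfig <- function(saturationFraction = 0.01) {
  if (!is.numeric(saturationFraction) || length(saturationFraction) != 1L ||
      is.na(saturationFraction) ||
      saturationFraction < 0 || saturationFraction >= 0.5)
    stop("saturationFraction must lie in [0, 0.5)")
  structure(list(saturationFraction = saturationFraction),
            class = c("EnhancementConfig", "list"))
}

#' Two-sided saturating contrast stretch
#'
#' Remaps frame intensities so that a fixed fraction of pixels saturates at
#' each end of the output range: with saturation fraction s, the s and
#' (1 - s) quantiles of the input (order statistics with linear
#' interpolation) are mapped linearly onto the full bit range, values below
#' the low quantile clip to 0 and values above the high quantile clip to the
#' range maximum. The mapping is monotone non-decreasing. Constant (or
#' otherwise degenerate, low == high quantile) frames pass through
#' unchanged with a warning so a blank time point cannot abort a batch.
#'
#' @param frame a [Frame-class].
#' @param config an [enhancementConfig()].
#' @return a [Frame-class] of identical shape, bit depth and metadata.
#' @examples
#' f <- Frame(matrix(rep(0:255, length.out = 64 * 64), 64, 64), bitDepth = 8)
#' g <- stretchContrast(f, enhancementConfig(0))
#' identical(pixels(g), pixels(f))  # full-range input, zero saturation
#' @export
stretchContrast <- function(frame, config = enhancementConfig()) {
  if (!inherits(config, "EnhancementConfig"))
    stop("config must be created by enhancementConfig()")
  px <- as.numeric(frame@pixels)
  s <- config$saturationFraction
  lo <- stats::quantile(px, s, names = FALSE, type = 7)
  hi <- stats::quantile(px, 1 - s, names = FALSE, type = 7)
  maxv <- .maxval(frame)
  if (hi <= lo) {
    warning(sprintf(
      "degenerate frame (t=%d, phase=%s): saturation quantiles coincide; returned unchanged",
      frame@timeIndex, frame@phaseLabel))
    return(frame)
  }
  out <- (px - lo) / (hi - lo) * maxv
  out <- pmin(pmax(out, 0), maxv)
  out <- as.integer(floor(out + 0.5))
  m <- matrix(out, nrow(frame@pixels), ncol(frame@pixels))
  new("Frame", pixels = m, bitDepth = frame@bitDepth,
      timeIndex = frame@timeIndex, phaseLabel = frame@phaseLabel)
}

#' @rdname stretchContrast
#' @param timelapse a [TimeLapse-class]; every frame is enhanced
#'   independently.
#' @export
enhanceTimeLapse <- function(timelapse, config = enhancementConfig()) {
  TimeLapse(lapply(timelapse@frames, stretchContrast, config = config),
            pixelResolutionNote = timelapse@pixelResolutionNote)
}
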
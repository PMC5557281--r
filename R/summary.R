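#' @include track.R
NULL

# measure name -> features field; "distance" is handled separately
.measureFields <- c(area = "area", perimeter = "perimeter",
                    major_axis = "majorAxis", minor_axis = "minorAxis",
                    extent = "extent", eccentricity = "eccentricity",
                    max_intensity = "maxIntensity",
                    mean_intensity = "meanIntensity")

#' Per-dataset summary statistics
#'
#' Pools all (cell, time point) records and reports min, mean, max and
#' sample (n-1) standard deviation per measure, in the style of a dataset
#' summary table. The \code{distance} measure is the per-step centroid
#' displacement and is defined only for tracked input; stationary datasets
#' typically omit it and add \code{eccentricity} instead.
#'
#' @param x a list of [CellDetection-class] (untracked records) or of
#'   [Track-class] objects.
#' @param measures character vector of measures to report; defaults to the
#'   full morphology/intensity set, plus \code{distance} when \code{x} is
#'   tracked.
#' @return data.frame with columns \code{measure}, \code{n}, \code{min},
#'   \code{mean}, \code{max}, \code{sd}. Measures with no records get
#'   \code{n = 0} and NA statistics.
#' @export
summarizeFeatures <- function(x, measures = NULL) {
  tracked <- length(x) > 0L && methods::is(x[[1]], "Track")
  if (is.null(measures)) {
    measures <- names(.measureFields)
    if (tracked) measures <- c(measures, "distance")
  }
  unknown <- setdiff(measures, c(names(.measureFields), "distance"))
  if (length(unknown))
    stop("unknown measure(s): ", paste(unknown, collapse = ", "))
  if ("distance" %in% measures && !tracked && length(x) > 0L)
    stop("the 'distance' measure requires tracked input")

  dets <- if (tracked) unlist(lapply(x, function(tr) tr@detections),
                              recursive = FALSE)
          else x
  rows <- lapply(measures, function(ms) {
    vals <- if (ms == "distance") {
      if (!length(x)) numeric(0)
      else unlist(lapply(x, function(tr) tr@stepDistances))
    } else {
      vapply(dets, function(d) d@features[[.measureFields[[ms]]]],
             numeric(1))
    }
    n <- length(vals)
    if (n == 0L)
      data.frame(measure = ms, n = 0L, min = NA_real_, mean = NA_real_,
                 max = NA_real_, sd = NA_real_)
    else
      data.frame(measure = ms, n = n, min = min(vals), mean = mean(vals),
                 max = max(vals),
                 sd = if (n > 1L) stats::sd(vals) else 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
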
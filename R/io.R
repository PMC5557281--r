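#' @include frame.R track.R
NULL

.defaultPhasePattern <- "^t(\\d+)_(.+)\\.tiff?$"

.readOneTiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  bits <- attr(img, "bits.per.sample")
  if (is.null(bits)) bits <- if (max(img) > 255) 16L else 8L
  if (is.array(img) && length(dim(img)) == 3L) img <- img[, , 1]
  img <- matrix(as.integer(img), nrow(img), ncol(img))
  list(pixels = img, bitDepth = as.integer(bits))
}

#' Read a time-lapse from TIFF files
#'
#' Reads either a multi-page TIFF (pages become time points of a single
#' phase) or a directory of single-page TIFFs whose names encode time point
#' and phase. Frame order is a deterministic function of the parsed names,
#' independent of directory listing order; observed time values are
#' remapped to consecutive 0-based indices.
#'
#' @param sourcePath a TIFF file or a directory of TIFF files.
#' @param phasePattern regular expression with two capture groups, the time
#'   value and the phase label (default matches names such as
#'   \code{t00_p1.tif} or \code{t003_phase1.tif}).
#' @return a [TimeLapse-class].
#' @export
readTimeLapse <- function(sourcePath, phasePattern = .defaultPhasePattern) {
  if (!file.exists(sourcePath))
    stop(sprintf("cannot read '%s': no such file or directory", sourcePath))
  if (!dir.exists(sourcePath)) {
    pages <- tiff::readTIFF(sourcePath, all = TRUE, as.is = TRUE,
                            info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(seq_along(pages), function(t) {
      img <- pages[[t]]
      bits <- attr(img, "bits.per.sample")
      if (is.null(bits)) bits <- if (max(img) > 255) 16L else 8L
      if (is.array(img) && length(dim(img)) == 3L) img <- img[, , 1]
      img <- matrix(as.integer(img), nrow(img), ncol(img))
      new("Frame", pixels = img, bitDepth = as.integer(bits),
          timeIndex = t - 1L, phaseLabel = "phase1")
    })
    return(TimeLapse(frames))
  }
  files <- list.files(sourcePath)
  hit <- grepl(phasePattern, files)
  files <- files[hit]
  if (!length(files))
    stop(sprintf("no files in '%s' match the phase pattern", sourcePath))
  m <- regmatches(files, regexec(phasePattern, files))
  times <- vapply(m, function(x) as.integer(x[2]), integer(1))
  phases <- vapply(m, function(x) x[3], character(1))
  tIdx <- match(times, sort(unique(times))) - 1L
  allPhases <- sort(unique(phases))
  for (t in sort(unique(tIdx))) {
    have <- phases[tIdx == t]
    gap <- setdiff(allPhases, have)
    if (length(gap))
      stop(sprintf("time %d is missing phase %s", t,
                   paste(gap, collapse = ", ")))
  }
  frames <- lapply(seq_along(files), function(i) {
    img <- .readOneTiff(file.path(sourcePath, files[i]))
    new("Frame", pixels = img$pixels, bitDepth = img$bitDepth,
        timeIndex = tIdx[i], phaseLabel = phases[i])
  })
  TimeLapse(frames)
}

#' Write a time-lapse as one TIFF per frame
#'
#' Frames are written losslessly at their native bit depth as
#' \code{t<NNN>_<phase>.tif}, a naming scheme [readTimeLapse()] parses by
#' default.
#'
#' @param timelapse a [TimeLapse-class].
#' @param destPath output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeTimeLapse <- function(timelapse, destPath) {
  if (!length(timelapse@frames)) stop("nothing to write: empty TimeLapse")
  dir.create(destPath, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(destPath))
    stop(sprintf("cannot create destination '%s'", destPath))
  paths <- vapply(timelapse@frames, function(f) {
    p <- file.path(destPath,
                   sprintf("t%03d_%s.tif", f@timeIndex, f@phaseLabel))
    tiff::writeTIFF(f@pixels / .maxval(f), p,
                    bits.per.sample = f@bitDepth)
    p
  }, character(1))
  invisible(paths)
}

.metadataColumns <- c("track_id", "time_index", "centroid_row",
                      "centroid_col", "area", "perimeter", "major_axis",
                      "minor_axis", "extent", "eccentricity",
                      "max_intensity", "mean_intensity",
                      "distance_from_previous")

.featNum <- function(det, field) {
  v <- det@features[[field]]
  if (is.null(v) || !length(v) || any(!is.finite(v)))
    stop(sprintf("incomplete feature record: missing or non-finite '%s'",
                 field))
  v
}

.fmt <- function(x) {
  if (is.na(x)) "" else if (x == round(x) && abs(x) < 2^31)
    sprintf("%d", as.integer(x)) else sprintf("%.17g", x)
}

.metadataRow <- function(det, trackLabel, dist) {
  cen <- .featNum(det, "centroid")
  c(trackLabel, .fmt(det@timeIndex), .fmt(cen[1]), .fmt(cen[2]),
    .fmt(.featNum(det, "area")), .fmt(.featNum(det, "perimeter")),
    .fmt(.featNum(det, "majorAxis")), .fmt(.featNum(det, "minorAxis")),
    .fmt(.featNum(det, "extent")), .fmt(.featNum(det, "eccentricity")),
    .fmt(.featNum(det, "maxIntensity")), .fmt(.featNum(det, "meanIntensity")),
    if (is.na(dist)) "" else .fmt(dist))
}

#' Export per-cell metadata as CSV
#'
#' Writes one row per (cell, time point) with the full measure set: mean
#' and max pixel intensity, major and minor axis length, area, perimeter
#' (circumference), extent, eccentricity and centroid position; tracked
#' input additionally carries the track id and the centroid displacement
#' from the previous detected time point. Numeric values are printed at
#' full precision and re-parse exactly. The header row is always present.
#'
#' @param x list of [CellDetection-class] or list of [Track-class].
#' @param destPath output CSV path.
#' @return invisibly, \code{destPath}.
#' @export
writeMetadata <- function(x, destPath) {
  rows <- list()
  if (length(x) && methods::is(x[[1]], "Track")) {
    for (tk in x) {
      for (e in seq_along(tk@detections)) {
        dist <- if (e == 1L) NA_real_ else tk@stepDistances[e - 1L]
        rows[[length(rows) + 1L]] <-
          .metadataRow(tk@detections[[e]], tk@trackId, dist)
      }
    }
  } else {
    for (det in x)
      rows[[length(rows) + 1L]] <- .metadataRow(det, "", NA_real_)
  }
  con <- file(destPath, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(.metadataColumns, collapse = ","), con)
  for (r in rows) writeLines(paste(r, collapse = ","), con)
  invisible(destPath)
}

# --- annotated renders ------------------------------------------------------

# 3x5 bitmap digits for overlay labels
.digitFont <- list(
  "0" = c("111", "101", "101", "101", "111"),
  "1" = c("010", "110", "010", "010", "111"),
  "2" = c("111", "001", "111", "100", "111"),
  "3" = c("111", "001", "111", "001", "111"),
  "4" = c("101", "101", "111", "001", "001"),
  "5" = c("111", "100", "111", "001", "111"),
  "6" = c("111", "100", "111", "101", "111"),
  "7" = c("111", "001", "010", "010", "010"),
  "8" = c("111", "101", "111", "101", "111"),
  "9" = c("111", "101", "111", "001", "111"))

.stampText <- function(channel, text, r0, c0, value) {
  h <- nrow(channel); w <- ncol(channel)
  cpos <- c0
  for (ch in strsplit(text, "")[[1]]) {
    glyph <- .digitFont[[ch]]
    if (!is.null(glyph)) {
      for (gr in 1:5) for (gc in 1:3) {
        if (substr(glyph[gr], gc, gc) == "1") {
          rr <- r0 + gr; cc <- cpos + gc
          if (rr >= 1 && rr <= h && cc >= 1 && cc <= w)
            channel[rr, cc] <- value
        }
      }
    }
    cpos <- cpos + 4L
  }
  channel
}

.drawSegment <- function(channel, a, b, value) {
  n <- max(2L, ceiling(max(abs(b - a))) + 1L)
  rr <- round(seq(a[1], b[1], length.out = n)) + 1L
  cc <- round(seq(a[2], b[2], length.out = n)) + 1L
  ok <- rr >= 1 & rr <= nrow(channel) & cc >= 1 & cc <= ncol(channel)
  channel[cbind(rr[ok], cc[ok])] <- value
  channel
}

# boundary pixels of a detection (pixels with some non-member 8-neighbor)
.detectionOutline <- function(det) {
  px <- det@pixels
  keys <- px[, 1] * 1e6 + px[, 2]
  isB <- vapply(seq_len(nrow(px)), function(i) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      if (!((px[i, 1] + dr) * 1e6 + (px[i, 2] + dc)) %in% keys) return(TRUE)
    }
    FALSE
  }, logical(1))
  px[isB, , drop = FALSE]
}

#' Write annotated renders of a time-lapse
#'
#' For each time point, writes a PNG of the (enhanced) frame with detected
#' cell outlines; tracked input additionally gets a persistent numeric
#' label per track and the track's trailing centroid path.
#'
#' @param timelapse the (enhanced) [TimeLapse-class] that was segmented.
#' @param x list of [CellDetection-class] or of [Track-class].
#' @param destPath output directory for \code{t<NNN>_annotated.png} files.
#' @param phase phase used as the grayscale underlay (default first).
#' @return invisibly, the written file paths.
#' @export
writeAnnotated <- function(timelapse, x, destPath,
                           phase = phaseLabels(timelapse)[1]) {
  TT <- nTimePoints(timelapse)
  tracked <- length(x) && methods::is(x[[1]], "Track")
  detsAt <- vector("list", TT)   # list of list(det, label, path)
  if (tracked) {
    for (tk in x) {
      if (any(tk@timeIndices >= TT) || any(tk@timeIndices < 0))
        stop("track references an out-of-range frame")
      lab <- gsub("[^0-9]", "", tk@trackId)
      cents <- t(vapply(tk@detections, function(d) d@features$centroid,
                        numeric(2)))
      for (e in seq_along(tk@detections)) {
        t <- tk@timeIndices[e] + 1L
        detsAt[[t]] <- c(detsAt[[t]], list(list(
          det = tk@detections[[e]], label = lab,
          path = cents[seq_len(e), , drop = FALSE])))
      }
    }
  } else {
    for (det in x) {
      if (det@timeIndex >= TT || det@timeIndex < 0)
        stop("detection references an out-of-range frame")
      detsAt[[det@timeIndex + 1L]] <-
        c(detsAt[[det@timeIndex + 1L]], list(list(det = det, label = NULL,
                                                  path = NULL)))
    }
  }
  dir.create(destPath, showWarnings = FALSE, recursive = TRUE)
  paths <- character(TT)
  for (t in seq_len(TT)) {
    f <- getFrame(timelapse, t - 1L, phase)
    g <- f@pixels / .maxval(f)
    R <- g; G <- g; B <- g
    for (item in detsAt[[t]]) {
      ol <- .detectionOutline(item$det)
      idx <- cbind(ol[, 1] + 1L, ol[, 2] + 1L)
      R[idx] <- 1; G[idx] <- 0; B[idx] <- 0
      if (!is.null(item$path) && nrow(item$path) > 1L) {
        for (s in seq_len(nrow(item$path) - 1L)) {
          G <- .drawSegment(G, item$path[s, ], item$path[s + 1L, ], 1)
          R <- .drawSegment(R, item$path[s, ], item$path[s + 1L, ], 0)
          B <- .drawSegment(B, item$path[s, ], item$path[s + 1L, ], 0)
        }
      }
      if (!is.null(item$label) && nzchar(item$label)) {
        bb <- item$det@bbox
        r0 <- as.integer(bb[1]) - 7L; c0 <- as.integer(bb[2])
        R <- .stampText(R, item$label, r0, c0, 1)
        G <- .stampText(G, item$label, r0, c0, 1)
        B <- .stampText(B, item$label, r0, c0, 0)
      }
    }
    arr <- array(c(R, G, B), c(nrow(g), ncol(g), 3))
    paths[t] <- file.path(destPath, sprintf("t%03d_annotated.png", t - 1L))
    png::writePNG(arr, paths[t])
  }
  invisible(paths)
}
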
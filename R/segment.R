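#' @include frame.R features.R
NULL

#' Segmentation configuration
#'
#' Parameters for tiled constrained thresholding and circle seeding. The
#' frame is split into \code{tileSize} x \code{tileSize} sub-images (32 px,
#' slightly larger than a typical T cell diameter) that are thresholded
#' independently, which absorbs slowly varying illumination. Tiles whose
#' between-class-variance threshold falls outside \code{thresholdBounds}
#' (normalized to \code{[0, 1]} of the bit range) are declared cell-free so
#' that empty sub-images contribute no noise.
#'
#' @param tileSize sub-image edge length in pixels (default 32).
#' @param thresholdBounds \code{c(tMin, tMax)} normalized threshold
#'   constraints (default \code{c(0.08, 0.95)}).
#' @param autoThresholdBounds when TRUE (default), [segmentFrame()]
#'   re-derives the lower constraint per frame from the enhanced
#'   background's modal intensity and robust noise scale; explicit bounds
#'   are used as given by [thresholdTile()] either way. See the methods
#'   vignette for the calibration rationale.
#' @param circleRadiusRange \code{c(rMin, rMax)} seed radii in pixels
#'   (default \code{c(4, 16)}, i.e. cell diameters of roughly 8-32 px).
#' @param minComponentArea,maxComponentArea accepted component area range in
#'   pixels (defaults 75 and 450, mirroring the observed area range of
#'   segmented T cells).
#' @param boundaryMargin distance in pixels from a tile edge at which a
#'   component triggers boundary re-processing (default 2).
#' @param circleSensitivity minimum fraction of a candidate circle's
#'   circumference that must vote coherently for a seed (default 0.33).
#' @return validated config list of class \code{SegmentationConfig}.
#' @export
segmentationConfig <- function(tileSize = 32L,
                               thresholdBounds = c(0.08, 0.95),
                               autoThresholdBounds = TRUE,
                               circleRadiusRange = c(4, 16),
                               minComponentArea = 75,
                               maxComponentArea = 450,
                               boundaryMargin = 2L,
                               circleSensitivity = 0.33) {
  .checkInterval(thresholdBounds, "thresholdBounds")
  .checkInterval(circleRadiusRange, "circleRadiusRange")
  if (thresholdBounds[1] >= thresholdBounds[2])
    stop("thresholdBounds must satisfy tMin < tMax")
  if (minComponentArea >= maxComponentArea)
    stop("minComponentArea must be < maxComponentArea")
  if (boundaryMargin >= tileSize / 2)
    stop("boundaryMargin must be < tileSize/2")
  structure(list(
    tileSize = as.integer(tileSize),
    thresholdBounds = as.numeric(thresholdBounds),
    autoThresholdBounds = isTRUE(autoThresholdBounds),
    circleRadiusRange = as.numeric(circleRadiusRange),
    minComponentArea = as.numeric(minComponentArea),
    maxComponentArea = as.numeric(maxComponentArea),
    boundaryMargin = as.integer(boundaryMargin),
    circleSensitivity = as.numeric(circleSensitivity)
  ), class = c("SegmentationConfig", "list"))
}

# Between-class-variance maximizing split of an integer sample.
# Returns NULL when fewer than two distinct values exist; otherwise a list
# with the split value (largest member of the background class, smallest
# variance-maximizing split on ties) and the reported threshold, defined as
# the midpoint between the two classes' facing values so that it separates
# them strictly.
.otsuSplit <- function(values) {
  vs <- sort(as.integer(values))
  r <- rle(vs)
  v <- r$values; cnt <- r$lengths
  k <- length(v)
  if (k < 2L) return(NULL)
  n <- length(vs)
  cw <- cumsum(cnt)
  cs <- cumsum(as.numeric(cnt) * v)
  tot <- cs[k]
  i <- seq_len(k - 1L)
  w0 <- cw[i] / n
  w1 <- 1 - w0
  mu0 <- cs[i] / cw[i]
  mu1 <- (tot - cs[i]) / (n - cw[i])
  sigma <- w0 * w1 * (mu0 - mu1)^2
  best <- which.max(sigma)  # first maximum = smallest split on ties
  list(split = v[best],
       threshold = (v[best] + v[best + 1L]) / 2,
       betweenClassVariance = sigma[best])
}

#' Partition a frame into tiles
#'
#' Tiles partition the frame exactly: interior tiles are
#' \code{tileSize} x \code{tileSize}; tiles in the last row/column band are
#' truncated to the remaining pixels.
#'
#' @param frame a [Frame-class].
#' @param config a [segmentationConfig()].
#' @return list of tiles, each a list with elements \code{pixels}
#'   (sub-matrix), \code{origin} (0-based \code{(row, col)} offset, a
#'   multiple of the tile size) and \code{bitDepth}.
#' @export
tileFrame <- function(frame, config = segmentationConfig()) {
  d <- dim(frame@pixels)
  ts <- config$tileSize
  rOrig <- seq(0L, d[1] - 1L, by = ts)
  cOrig <- seq(0L, d[2] - 1L, by = ts)
  tiles <- vector("list", length(rOrig) * length(cOrig))
  k <- 0L
  for (r0 in rOrig) for (c0 in cOrig) {
    k <- k + 1L
    h <- min(ts, d[1] - r0)
    w <- min(ts, d[2] - c0)
    tiles[[k]] <- list(
      pixels = frame@pixels[(r0 + 1L):(r0 + h), (c0 + 1L):(c0 + w),
                            drop = FALSE],
      origin = c(r0, c0),
      bitDepth = frame@bitDepth
    )
  }
  tiles
}

#' Threshold one tile by between-class-variance maximization
#'
#' Computes the tile's threshold by maximizing the between-class variance of
#' its intensity histogram (Otsu's criterion; the reported threshold is the
#' midpoint between the two classes so it separates them strictly). If the
#' threshold, normalized to \code{[0, 1]} of the bit range, falls outside
#' \code{config$thresholdBounds}, the tile is declared cell-free: empty
#' sub-images must not contribute noise. Tiles with a single intensity value
#' are cell-free by construction.
#'
#' @param tile one element of [tileFrame()] output.
#' @param config a [segmentationConfig()]; \code{thresholdBounds} are used
#'   as given.
#' @return list with \code{cellFree} (logical), \code{mask} (logical matrix,
#'   pixels strictly above the threshold; all-FALSE when cell-free) and
#'   \code{threshold} (numeric, NA when no split exists).
#' @export
thresholdTile <- function(tile, config = segmentationConfig()) {
  sp <- .otsuSplit(tile$pixels)
  empty <- matrix(FALSE, nrow(tile$pixels), ncol(tile$pixels))
  if (is.null(sp))
    return(list(cellFree = TRUE, mask = empty, threshold = NA_real_))
  maxv <- 2^tile$bitDepth - 1
  tNorm <- sp$threshold / maxv
  b <- config$thresholdBounds
  if (tNorm < b[1] || tNorm > b[2])
    return(list(cellFree = TRUE, mask = empty, threshold = sp$threshold))
  list(cellFree = FALSE,
       mask = tile$pixels > sp$threshold,
       threshold = sp$threshold)
}

# --- circle seeding ---------------------------------------------------------

# Sobel gradients; returns row- and col-direction derivatives (same shape,
# zero on the 1-px border).
.sobel <- function(m) {
  h <- nrow(m); w <- ncol(m)
  gr <- matrix(0, h, w); gc <- matrix(0, h, w)
  ri <- 2:(h - 1); ci <- 2:(w - 1)
  gr[ri, ci] <- (m[ri + 1, ci - 1] + 2 * m[ri + 1, ci] + m[ri + 1, ci + 1]) -
                (m[ri - 1, ci - 1] + 2 * m[ri - 1, ci] + m[ri - 1, ci + 1])
  gc[ri, ci] <- (m[ri - 1, ci + 1] + 2 * m[ri, ci + 1] + m[ri + 1, ci + 1]) -
                (m[ri - 1, ci - 1] + 2 * m[ri, ci - 1] + m[ri + 1, ci - 1])
  list(gr = gr, gc = gc)
}

# 3x3 box sum with zero padding.
.box3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(0, h + 2, w + 2)
  p[2:(h + 1), 2:(w + 1)] <- m
  out <- matrix(0, h, w)
  for (dr in 0:2) for (dc in 0:2)
    out <- out + p[(1 + dr):(h + dr), (1 + dc):(w + dc)]
  out
}

#' Detect circular cell seeds by gradient Hough accumulation
#'
#' Bright, approximately circular objects vote along their rim gradients
#' into a (center, radius) accumulator; peaks whose normalized response
#' (votes per circumference pixel) exceeds \code{circleSensitivity} become
#' seeds, thinned by non-maximum suppression at spacing \code{rMin}.
#'
#' @param frame an enhanced [Frame-class].
#' @param config a [segmentationConfig()].
#' @return data.frame with columns \code{row}, \code{col} (0-based center),
#'   \code{radius} and \code{response}, sorted by descending response.
#'   Pairwise center distances are at least \code{rMin}.
#' @export
detectCircles <- function(frame, config = segmentationConfig()) {
  rr <- config$circleRadiusRange
  if (rr[1] < 1) stop("minimum circle radius must be >= 1")
  m <- matrix(as.numeric(frame@pixels), nrow(frame@pixels))
  h <- nrow(m); w <- ncol(m)
  g <- .sobel(m)
  mag <- sqrt(g$gr^2 + g$gc^2)
  mmax <- max(mag)
  none <- data.frame(row = numeric(0), col = numeric(0),
                     radius = numeric(0), response = numeric(0))
  if (mmax == 0) return(none)
  edge <- which(mag > 0.25 * mmax)
  if (!length(edge)) return(none)
  er <- ((edge - 1L) %% h) + 1L
  ec <- ((edge - 1L) %/% h) + 1L
  ur <- g$gr[edge] / mag[edge]
  uc <- g$gc[edge] / mag[edge]
  radii <- seq(ceiling(rr[1]), floor(rr[2]))
  cand <- list()
  for (r in radii) {
    cr <- as.integer(round(er + r * ur))
    cc <- as.integer(round(ec + r * uc))
    ok <- cr >= 1L & cr <= h & cc >= 1L & cc <= w
    if (!any(ok)) next
    acc <- matrix(tabulate((cc[ok] - 1L) * h + cr[ok], nbins = h * w), h, w)
    sm <- .box3(acc)
    resp <- sm / (2 * pi * r)
    hits <- which(resp >= config$circleSensitivity)
    if (length(hits)) {
      cand[[length(cand) + 1L]] <- data.frame(
        row = ((hits - 1L) %% h),
        col = ((hits - 1L) %/% h),
        radius = r,
        response = resp[hits])
    }
  }
  if (!length(cand)) return(none)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$response, cand$row, cand$col, cand$radius), ,
               drop = FALSE]
  keep <- logical(nrow(cand))
  accR <- numeric(0); accC <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    if (length(accR)) {
      d2 <- (accR - cand$row[i])^2 + (accC - cand$col[i])^2
      if (min(d2) < rr[1]^2) next
    }
    keep[i] <- TRUE
    accR <- c(accR, cand$row[i]); accC <- c(accC, cand$col[i])
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- component extraction ---------------------------------------------------

# Build a CellDetection from a 0-based (row, col) pixel matrix.
.makeDetection <- function(pxFrame, frame, id = "") {
  feats <- computeRegionFeatures(pxFrame, frame)
  storage.mode(pxFrame) <- "integer"
  new("CellDetection",
      timeIndex = frame@timeIndex, phaseLabel = frame@phaseLabel,
      pixels = pxFrame,
      bbox = c(min(pxFrame[, 1]), min(pxFrame[, 2]),
               max(pxFrame[, 1]) + 1, max(pxFrame[, 2]) + 1),
      features = feats, detectionId = id)
}

#' Extract connected components from a tile mask
#'
#' Labels the mask's 8-connected components, translates them to frame
#' coordinates and retains those whose area lies within the configured
#' component area bounds; each retained component carries a full feature
#' record computed from \code{intensityFrame}.
#'
#' @param mask logical matrix aligned to \code{tile$pixels}.
#' @param tile the tile the mask was computed from.
#' @param intensityFrame the [Frame-class] supplying intensities.
#' @param config a [segmentationConfig()].
#' @return list of [CellDetection-class] objects.
#' @export
extractComponents <- function(mask, tile, intensityFrame,
                              config = segmentationConfig()) {
  if (!identical(dim(mask), dim(tile$pixels)))
    stop("mask dimensions must match the tile")
  lab <- .labelComponents(mask)
  k <- max(lab)
  out <- list()
  if (k == 0L) return(out)
  for (i in seq_len(k)) {
    idx <- which(lab == i, arr.ind = TRUE)
    area <- nrow(idx)
    if (area < config$minComponentArea || area > config$maxComponentArea)
      next
    pxF <- cbind(idx[, 1] - 1L + tile$origin[1],
                 idx[, 2] - 1L + tile$origin[2])
    colnames(pxF) <- c("row", "col")
    out[[length(out) + 1L]] <- .makeDetection(pxF, intensityFrame)
  }
  out
}

# Threshold and extract components inside a rectangular window of the frame.
# Components touching a window edge are discarded unless that edge is also
# the frame border (they belong to a neighbouring cell only partially
# covered by the window and must keep their first-pass record).
.segmentWindow <- function(frame, origin, h, w, config) {
  d <- dim(frame@pixels)
  sub <- frame@pixels[(origin[1] + 1L):(origin[1] + h),
                      (origin[2] + 1L):(origin[2] + w), drop = FALSE]
  tile <- list(pixels = sub, origin = origin, bitDepth = frame@bitDepth)
  th <- thresholdTile(tile, config)
  if (th$cellFree) return(list())
  lab <- .labelComponents(th$mask)
  k <- max(lab)
  out <- list()
  if (k == 0L) return(out)
  for (i in seq_len(k)) {
    idx <- which(lab == i, arr.ind = TRUE)
    touchTop <- any(idx[, 1] == 1L) && origin[1] > 0L
    touchBot <- any(idx[, 1] == h) && origin[1] + h < d[1]
    touchLeft <- any(idx[, 2] == 1L) && origin[2] > 0L
    touchRight <- any(idx[, 2] == w) && origin[2] + w < d[2]
    if (touchTop || touchBot || touchLeft || touchRight) next
    area <- nrow(idx)
    if (area < config$minComponentArea || area > config$maxComponentArea)
      next
    pxF <- cbind(idx[, 1] - 1L + origin[1], idx[, 2] - 1L + origin[2])
    colnames(pxF) <- c("row", "col")
    out[[length(out) + 1L]] <- .makeDetection(pxF, frame)
  }
  out
}

# Linearized pixel keys of a detection, for overlap tests.
.pixelKeys <- function(det, width) det@pixels[, 1] * width + det@pixels[, 2]

# Remove duplicate detections: whenever two detections share a pixel, the
# smaller-area one is dropped.
.dedupDetections <- function(dets, width) {
  if (length(dets) < 2L) return(dets)
  areas <- vapply(dets, function(d) nrow(d@pixels), integer(1))
  ord <- order(-areas)
  taken <- new.env(hash = TRUE, size = 4096L)
  keep <- logical(length(dets))
  for (i in ord) {
    keys <- as.character(.pixelKeys(dets[[i]], width))
    clash <- any(vapply(keys, function(k) !is.null(taken[[k]]), logical(1)))
    if (clash) next
    keep[i] <- TRUE
    for (k in keys) taken[[k]] <- TRUE
  }
  dets[keep]
}

#' Re-process detections near tile boundaries
#'
#' Cells falling on a tile edge are split across tiles or missed by per-tile
#' thresholding. Every detection whose bounding box comes within
#' \code{boundaryMargin} of an interior tile edge triggers re-thresholding
#' of a tile-sized window centered on it (a shifted focal point); detections
#' overlapping the window's findings are replaced by them, and the final
#' list contains no two detections sharing a pixel.
#'
#' @param frame the enhanced [Frame-class].
#' @param detections first-pass detections from the tiled pass.
#' @param config a [segmentationConfig()].
#' @return deduplicated list of [CellDetection-class] objects.
#' @export
resolveBoundaries <- function(frame, detections,
                              config = segmentationConfig()) {
  if (!length(detections)) return(detections)
  d <- dim(frame@pixels)
  ts <- config$tileSize
  margin <- config$boundaryMargin
  rowLines <- seq(ts, d[1] - 1L, by = ts)
  colLines <- seq(ts, d[2] - 1L, by = ts)

  # 1. fuse fragments of one cell split by per-tile thresholding: any two
  # detections whose pixel sets touch (8-adjacency) are the same object
  detections <- .mergeAdjacent(detections, frame, d[2])

  # bbox interval [lo, hiEx) vs the boundary between pixels L-1 and L;
  # returns the straddled/nearest line, or NA when none is within margin
  whichLine <- function(lo, hiEx, lines) {
    if (!length(lines)) return(NA_real_)
    near <- lines[(lo - margin) < lines & lines < (hiEx + margin)]
    if (!length(near)) return(NA_real_)
    near[which.min(abs(near - (lo + hiEx) / 2))]
  }

  flagged <- logical(length(detections))
  winKey <- character(0)
  winDets <- list()
  for (i in seq_along(detections)) {
    bb <- detections[[i]]@bbox
    lr <- whichLine(bb[1], bb[3], rowLines)
    lc <- whichLine(bb[2], bb[4], colLines)
    if (is.na(lr) && is.na(lc)) next
    flagged[i] <- TRUE
    # 2. shifted focal point: window centered on the offending edge region
    # (the straddled grid line; bbox center along the other axis)
    ctrR <- if (is.na(lr)) (bb[1] + bb[3]) / 2 else lr
    ctrC <- if (is.na(lc)) (bb[2] + bb[4]) / 2 else lc
    r0 <- max(0L, min(d[1] - ts, as.integer(round(ctrR - ts / 2))))
    c0 <- max(0L, min(d[2] - ts, as.integer(round(ctrC - ts / 2))))
    key <- paste(r0, c0)
    if (key %in% winKey) next
    winKey <- c(winKey, key)
    winDets <- c(winDets, .segmentWindow(frame, c(r0, c0), ts, ts, config))
  }
  if (!any(flagged)) return(detections)
  winDets <- .dedupDetections(winDets, d[2])
  if (!length(winDets))
    return(.dedupDetections(detections, d[2]))

  # 3. replace: first-pass detections overlapping the windows' findings
  # give way; everything else is untouched
  winKeys <- unlist(lapply(winDets, .pixelKeys, width = d[2]))
  replaced <- vapply(detections, function(det)
    any(.pixelKeys(det, d[2]) %in% winKeys), logical(1))
  .dedupDetections(c(detections[!replaced], winDets), d[2])
}

# Union detections whose pixel sets are 8-adjacent (or overlapping) into
# single detections with recomputed features.
.mergeAdjacent <- function(dets, frame, width) {
  n <- length(dets)
  if (n < 2L) return(dets)
  keysets <- lapply(dets, .pixelKeys, width = width)
  # dilated key set: all 8-neighbors (and self) of each pixel
  grown <- lapply(dets, function(det) {
    px <- det@pixels
    ks <- integer(0)
    for (dr in -1:1) for (dc in -1:1)
      ks <- c(ks, (px[, 1] + dr) * width + (px[, 2] + dc))
    unique(ks)
  })
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    bi <- dets[[i]]@bbox; bj <- dets[[j]]@bbox
    if (bj[1] > bi[3] || bi[1] > bj[3] || bj[2] > bi[4] || bi[2] > bj[4])
      next  # bboxes (padded by half-open edge) cannot touch
    if (any(keysets[[j]] %in% grown[[i]])) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- list()
  for (r in unique(roots)) {
    members <- which(roots == r)
    if (length(members) == 1L) {
      out[[length(out) + 1L]] <- dets[[members]]
    } else {
      px <- unique(do.call(rbind, lapply(dets[members],
                                         function(x) x@pixels)))
      colnames(px) <- c("row", "col")
      out[[length(out) + 1L]] <- .makeDetection(px, frame)
    }
  }
  out
}

# Frame-adaptive threshold constraints: the background dominates the frame,
# so its level is the median and its noise the MAD of the enhanced pixels.
# A tile containing only background has its between-class split inside the
# noise, within ~1 MAD of the median; a tile containing a cell splits well
# above. The lower constraint sits 1.5 MADs above the median.
.calibrateBounds <- function(frame, config) {
  maxv <- .maxval(frame)
  px <- as.numeric(frame@pixels)
  lower <- min(0.9, max(config$thresholdBounds[1],
                        (stats::median(px) + 1.5 * stats::mad(px)) / maxv))
  c(lower, max(config$thresholdBounds[2], 0.95))
}

#' Segment one frame into cell detections
#'
#' Full single-frame detection: circle seeding, 32x32 tiled constrained
#' thresholding with component extraction, boundary re-processing with a
#' shifted focal point, seed/component merging and deduplication. A circle
#' seed whose center falls inside an extracted component is absorbed by it;
#' an unabsorbed seed spawns a detection from a local threshold in a
#' \code{(2r+2)}-square window around it. Component area bounds are applied
#' after boundary resolution so that fragments of boundary-straddling cells
#' can still trigger re-processing.
#'
#' @param frame an enhanced [Frame-class].
#' @param config a [segmentationConfig()].
#' @return list of [CellDetection-class], ids assigned in scan order of the
#'   centroid.
#' @export
segmentFrame <- function(frame, config = segmentationConfig()) {
  cfg <- config
  if (cfg$autoThresholdBounds)
    cfg$thresholdBounds <- .calibrateBounds(frame, cfg)
  d <- dim(frame@pixels)

  # relaxed area floor during extraction: boundary fragments of a split cell
  # must survive long enough to trigger window re-processing
  relax <- cfg
  relax$minComponentArea <- max(5, floor(cfg$minComponentArea / 4))

  dets <- list()
  for (tile in tileFrame(frame, cfg)) {
    th <- thresholdTile(tile, cfg)
    if (!th$cellFree)
      dets <- c(dets, extractComponents(th$mask, tile, frame, relax))
  }
  dets <- resolveBoundaries(frame, dets, relax)

  # merge circle seeds
  seeds <- detectCircles(frame, cfg)
  if (nrow(seeds)) {
    allKeys <- unlist(lapply(dets, .pixelKeys, width = d[2]))
    for (i in seq_len(nrow(seeds))) {
      key <- round(seeds$row[i]) * d[2] + round(seeds$col[i])
      if (key %in% allKeys) next  # absorbed by an existing component
      r <- seeds$radius[i]
      half <- floor((2 * r + 2) / 2)
      r0 <- max(0L, min(d[1] - (2L * half), as.integer(seeds$row[i]) - half))
      c0 <- max(0L, min(d[2] - (2L * half), as.integer(seeds$col[i]) - half))
      wd <- .segmentWindow(frame, c(r0, c0), 2L * half, 2L * half, relax)
      if (!length(wd)) next
      cen <- t(vapply(wd, function(x) x@features$centroid, numeric(2)))
      dd <- sqrt((cen[, 1] - seeds$row[i])^2 + (cen[, 2] - seeds$col[i])^2)
      j <- which.min(dd)
      if (dd[j] > r) next
      newKeys <- .pixelKeys(wd[[j]], d[2])
      if (any(newKeys %in% allKeys)) next
      dets <- c(dets, wd[j])
      allKeys <- c(allKeys, newKeys)
    }
  }

  # final area filter at the configured bounds
  areas <- vapply(dets, function(x) nrow(x@pixels), integer(1))
  dets <- dets[areas >= cfg$minComponentArea & areas <= cfg$maxComponentArea]
  if (!length(dets)) return(dets)

  cen <- t(vapply(dets, function(x) x@features$centroid, numeric(2)))
  ord <- order(cen[, 1], cen[, 2])
  dets <- dets[ord]
  for (i in seq_along(dets))
    dets[[i]]@detectionId <- sprintf("d%03d", i)
  dets
}

#' @rdname segmentFrame
#' @param timelapse an enhanced [TimeLapse-class].
#' @param phase phase to segment (default: first phase label).
#' @return for \code{segmentTimeLapse}: a list (one element per time point)
#'   of detection lists.
#' @export
segmentTimeLapse <- function(timelapse, config = segmentationConfig(),
                             phase = phaseLabels(timelapse)[1]) {
  lapply(seq_len(nTimePoints(timelapse)) - 1L, function(t)
    segmentFrame(getFrame(timelapse, t, phase), config))
}
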
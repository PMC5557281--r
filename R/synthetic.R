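#' @include track.R
NULL

#' Synthetic scene configuration
#'
#' Parameters of the simulated field of view. Defaults emulate the imaging
#' conditions the pipeline targets: a 512x512 16-bit phase-like frame,
#' two dozen cells of 5-12 px radius, cell contrast eight times the
#' background noise, Brownian motility of 1.5 px/frame and occasional
#' whole-cell intensity flashes mimicking calcium-indicator activity.
#'
#' @param frameShape \code{c(rows, cols)} (default \code{c(512, 512)}).
#' @param nFrames number of time points (default 60).
#' @param nCells number of cells (default 25).
#' @param radiusRange \code{c(min, max)} cell radii in px (default
#'   \code{c(5, 12)}).
#' @param cellContrast additive disk height above background in intensity
#'   units (default 4000).
#' @param backgroundLevel background intensity (default 6000).
#' @param noiseSd additive Gaussian noise sd, clipped to the bit range
#'   (default 500).
#' @param illuminationGradient fraction of \code{cellContrast} spanned by a
#'   linear left-to-right illumination ramp (default 0).
#' @param motionSd isotropic Gaussian step sd in px/frame (default 1.5).
#' @param drift deterministic \code{c(row, col)} displacement per frame
#'   (default \code{c(0, 0)}).
#' @param flashProbability per cell per frame probability of a flash
#'   (default 0.02).
#' @param flashGain multiplicative factor on the cell's disk height during
#'   a flash (default 1.8).
#' @param entryExit allow cells to enter/leave the field of view across the
#'   frame border (default FALSE).
#' @param nEnter,nExit when \code{entryExit}, how many cells follow scripted
#'   entering / leaving trajectories (defaults 3 and 3).
#' @param bitDepth 8 or 16 (default 16).
#' @param seed RNG seed making the scene fully reproducible (default 1).
#' @return validated config list of class \code{SceneConfig}.
#' @export
sceneConfig <- function(frameShape = c(512L, 512L), nFrames = 60L,
                        nCells = 25L, radiusRange = c(5, 12),
                        cellContrast = 4000, backgroundLevel = 6000,
                        noiseSd = 500, illuminationGradient = 0,
                        motionSd = 1.5, drift = c(0, 0),
                        flashProbability = 0.02, flashGain = 1.8,
                        entryExit = FALSE, nEnter = 3L, nExit = 3L,
                        bitDepth = 16L, seed = 1L) {
  maxv <- 2^bitDepth - 1
  if (any(frameShape < 32L)) stop("frameShape must be at least 32x32")
  if (nFrames < 1L) stop("nFrames must be >= 1")
  if (nCells < 0L) stop("nCells must be >= 0")
  .checkInterval(radiusRange, "radiusRange")
  if (radiusRange[1] < 1) stop("minimum radius must be >= 1")
  if (backgroundLevel < 0 || backgroundLevel > maxv ||
      backgroundLevel + cellContrast > maxv * 1.5)
    stop("intensity levels must fit the bit range")
  if (flashProbability < 0 || flashProbability > 1)
    stop("flashProbability must lie in [0, 1]")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (!entryExit) { nEnter <- 0L; nExit <- 0L }
  if (nEnter + nExit > nCells)
    stop("nEnter + nExit cannot exceed nCells")
  structure(list(
    frameShape = as.integer(frameShape), nFrames = as.integer(nFrames),
    nCells = as.integer(nCells), radiusRange = as.numeric(radiusRange),
    cellContrast = as.numeric(cellContrast),
    backgroundLevel = as.numeric(backgroundLevel),
    noiseSd = as.numeric(noiseSd),
    illuminationGradient = as.numeric(illuminationGradient),
    motionSd = as.numeric(motionSd), drift = as.numeric(drift),
    flashProbability = as.numeric(flashProbability),
    flashGain = as.numeric(flashGain), entryExit = isTRUE(entryExit),
    nEnter = as.integer(nEnter), nExit = as.integer(nExit),
    bitDepth = as.integer(bitDepth), seed = as.integer(seed)
  ), class = c("SceneConfig", "list"))
}

#' Generate a ground-truth scene
#'
#' Samples initial cell centers uniformly with pairwise separation of at
#' least twice the maximum radius (rejection sampling), then evolves them by
#' Brownian steps plus drift. Scripted entering cells approach from outside
#' the border along a linear inward path (with tangential diffusion) and
#' cross it mid-sequence; scripted leaving cells do the reverse. Flash
#' states switch on independently per cell and frame with
#' \code{flashProbability}. Fully deterministic given the seed.
#'
#' @param config a [sceneConfig()].
#' @return a [SyntheticScene-class].
#' @export
generateScene <- function(config = sceneConfig()) {
  stopifnot(inherits(config, "SceneConfig"))
  .withSeed(config$seed, .generateSceneImpl(config))
}

.generateSceneImpl <- function(cfg) {
  h <- cfg$frameShape[1]; w <- cfg$frameShape[2]
  n <- cfg$nCells; TT <- cfg$nFrames
  rmax <- cfg$radiusRange[2]
  radii <- stats::runif(n, cfg$radiusRange[1], cfg$radiusRange[2])
  nEnter <- cfg$nEnter
  nInside <- n - nEnter

  # initial interior placement with pairwise separation >= 2*rmax
  pos <- matrix(NA_real_, n, 2)
  margin <- rmax + 1
  attempts <- 0L
  placed <- 0L
  while (placed < nInside) {
    attempts <- attempts + 1L
    if (attempts > 2000L * max(1L, nInside))
      stop("could not place cells with the required separation; reduce cell density")
    cand <- c(stats::runif(1, margin, h - 1 - margin),
              stats::runif(1, margin, w - 1 - margin))
    if (placed > 0L) {
      d2 <- (pos[seq_len(placed), 1] - cand[1])^2 +
            (pos[seq_len(placed), 2] - cand[2])^2
      if (min(d2) < (2 * rmax)^2) next
    }
    placed <- placed + 1L
    pos[placed, ] <- cand
  }

  centers <- array(NA_real_, c(TT, n, 2))
  role <- rep("interior", n)
  exitIdx <- if (cfg$nExit > 0L) seq_len(cfg$nExit) else integer(0)
  enterIdx <- if (nEnter > 0L) nInside + seq_len(nEnter) else integer(0)
  role[exitIdx] <- "exit"; role[enterIdx] <- "enter"
  speed <- 4  # px/frame crossing speed for scripted entry/exit

  crossingPath <- function(tCross, outward) {
    # linear path along +/- outward crossing the border at frame tCross
    # (1-based); tangential Brownian wiggle only, so the crossing frame is
    # exact. The path position at t is relative to the crossing point.
    tang <- c(outward[2], -outward[1])
    wiggle <- c(0, cumsum(stats::rnorm(TT - 1L, 0, cfg$motionSd)))
    list(tang = tang, wiggle = wiggle)
  }

  for (i in seq_len(nInside)) {
    if (i %in% exitIdx && TT > 1L) {
      # scripted leaver: crosses the border outward at tExit exactly
      tExit <- sample(seq(max(2L, TT %/% 4L), TT - 3L), 1L)
      side <- sample.int(4L, 1L)
      outward <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))[side, ]
      cross <- switch(side,
        c(0, stats::runif(1, margin, w - 1 - margin)),
        c(h - 1, stats::runif(1, margin, w - 1 - margin)),
        c(stats::runif(1, margin, h - 1 - margin), 0),
        c(stats::runif(1, margin, h - 1 - margin), w - 1))
      p <- crossingPath(tExit, outward)
      for (t in seq_len(TT))
        centers[t, i, ] <- cross + (t - tExit) * speed * outward +
          p$wiggle[t] * p$tang
    } else {
      centers[1, i, ] <- pos[i, ]
      if (TT > 1L) {
        sr <- stats::rnorm(TT - 1L, cfg$drift[1], cfg$motionSd)
        sc <- stats::rnorm(TT - 1L, cfg$drift[2], cfg$motionSd)
        centers[, i, 1] <- pos[i, 1] + c(0, cumsum(sr))
        centers[, i, 2] <- pos[i, 2] + c(0, cumsum(sc))
      }
    }
  }
  for (i in enterIdx) {
    # scripted enterer: crosses the border inward at tEnter exactly
    tEnter <- sample(seq(max(2L, TT %/% 6L), max(3L, (2L * TT) %/% 3L)), 1L)
    side <- sample.int(4L, 1L)
    inward <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))[side, ]
    cross <- switch(side,
      c(0, stats::runif(1, margin, w - 1 - margin)),
      c(h - 1, stats::runif(1, margin, w - 1 - margin)),
      c(stats::runif(1, margin, h - 1 - margin), 0),
      c(stats::runif(1, margin, h - 1 - margin), w - 1))
    p <- crossingPath(tEnter, -inward)
    for (t in seq_len(TT))
      centers[t, i, ] <- cross + (t - tEnter) * speed * inward +
        p$wiggle[t] * p$tang
  }

  flashing <- matrix(stats::runif(TT * n) < cfg$flashProbability, TT, n)
  visible <- matrix(FALSE, TT, n)
  for (t in seq_len(TT))
    visible[t, ] <- centers[t, , 1] >= 0 & centers[t, , 1] <= h - 1 &
                    centers[t, , 2] >= 0 & centers[t, , 2] <= w - 1

  truth <- if (n > 0L) data.frame(
    frame = rep(seq_len(TT) - 1L, each = n),
    cell = rep(seq_len(n), times = TT),
    row = as.vector(t(centers[, , 1, drop = FALSE][, , 1])),
    col = as.vector(t(centers[, , 2, drop = FALSE][, , 1])),
    radius = rep(radii, times = TT),
    flashing = as.vector(t(flashing)),
    visible = as.vector(t(visible)),
    role = rep(role, times = TT)
  ) else data.frame(frame = integer(0), cell = integer(0),
                    row = numeric(0), col = numeric(0),
                    radius = numeric(0), flashing = logical(0),
                    visible = logical(0), role = character(0))
  new("SyntheticScene", config = cfg, truth = truth)
}

#' @rdname SyntheticScene
#' @param x a \code{SyntheticScene}
#' @export
setMethod("sceneTruth", "SyntheticScene", function(x) x@truth)

setMethod("show", "SyntheticScene", function(object) {
  cfg <- object@config
  cat(sprintf(
    "SyntheticScene: %d frame(s), %d cell(s), %dx%d, %d-bit, seed %d\n",
    cfg$nFrames, cfg$nCells, cfg$frameShape[1], cfg$frameShape[2],
    cfg$bitDepth, cfg$seed))
})

#' Render a scene into a time-lapse with ground-truth masks
#'
#' Each frame is background plus the illumination ramp, plus one
#' anti-aliased disk per cell (additive height \code{cellContrast},
#' multiplied by \code{flashGain} while flashing; rim smoothed over 1 px),
#' plus Gaussian noise, clipped and rounded to the bit range. Label masks
#' assign each pixel within a cell's radius to that cell (nearest center on
#' overlap).
#'
#' @param scene a [SyntheticScene-class].
#' @return list with \code{timelapse} (a [TimeLapse-class]), \code{truth}
#'   (the scene's truth table) and \code{masks} (list of integer label
#'   matrices, 0 = background).
#' @export
renderTimeLapse <- function(scene) {
  cfg <- scene@config
  .withSeed(cfg$seed + 104729L, .renderImpl(scene))
}

.renderImpl <- function(scene) {
  cfg <- scene@config
  h <- cfg$frameShape[1]; w <- cfg$frameShape[2]
  maxv <- 2^cfg$bitDepth - 1
  ramp <- if (w > 1)
    matrix(rep(cfg$illuminationGradient * cfg$cellContrast *
                 (seq_len(w) - 1) / (w - 1), each = h), h, w)
  else matrix(0, h, w)
  frames <- vector("list", cfg$nFrames)
  masks <- vector("list", cfg$nFrames)
  tr <- scene@truth
  for (t in seq_len(cfg$nFrames)) {
    img <- matrix(cfg$backgroundLevel, h, w) + ramp
    lab <- matrix(0L, h, w)
    bestD <- matrix(Inf, h, w)
    sub <- tr[tr$frame == t - 1L, , drop = FALSE]
    for (k in seq_len(nrow(sub))) {
      r0 <- sub$row[k]; c0 <- sub$col[k]; rad <- sub$radius[k]
      lo_r <- max(1L, floor(r0 - rad - 1) + 1L)
      hi_r <- min(h, ceiling(r0 + rad + 1) + 1L)
      lo_c <- max(1L, floor(c0 - rad - 1) + 1L)
      hi_c <- min(w, ceiling(c0 + rad + 1) + 1L)
      if (lo_r > hi_r || lo_c > hi_c) next
      rr <- lo_r:hi_r; cc <- lo_c:hi_c
      dr <- (rr - 1) - r0; dc <- (cc - 1) - c0
      d <- sqrt(outer(dr^2, dc^2, `+`))
      cov <- pmin(1, pmax(0, rad + 0.5 - d))
      gain <- if (sub$flashing[k]) cfg$flashGain else 1
      img[rr, cc] <- img[rr, cc] + cfg$cellContrast * gain * cov
      inside <- d <= rad & d < bestD[rr, cc]
      if (any(inside)) {
        labPatch <- lab[rr, cc]; bPatch <- bestD[rr, cc]
        labPatch[inside] <- sub$cell[k]
        bPatch[inside] <- d[inside]
        lab[rr, cc] <- labPatch; bestD[rr, cc] <- bPatch
      }
    }
    if (cfg$noiseSd > 0)
      img <- img + matrix(stats::rnorm(h * w, 0, cfg$noiseSd), h, w)
    img <- matrix(as.integer(floor(pmin(pmax(img, 0), maxv) + 0.5)), h, w)
    frames[[t]] <- new("Frame", pixels = img, bitDepth = cfg$bitDepth,
                       timeIndex = t - 1L, phaseLabel = "phase1")
    masks[[t]] <- lab
  }
  list(timelapse = TimeLapse(frames), truth = tr, masks = masks)
}

# --- scoring against ground truth ------------------------------------------

# One-to-one nearest matching of two point sets within maxDist (a scalar
# or per-truth-row gate). Returns a 2-column index matrix
# (truth index, detection index).
.matchPoints <- function(truthXY, detXY, maxDist) {
  nT <- nrow(truthXY); nD <- nrow(detXY)
  if (!nT || !nD) return(matrix(integer(0), 0, 2))
  d <- sqrt(outer(truthXY[, 1], detXY[, 1], `-`)^2 +
            outer(truthXY[, 2], detXY[, 2], `-`)^2)
  cost <- ifelse(d <= maxDist, d, .BIGCOST)
  if (all(cost >= .BIGCOST)) return(matrix(integer(0), 0, 2))
  transposed <- nT > nD
  work <- if (transposed) t(cost) else cost
  assign <- .solveAssignment(work)
  pairs <- matrix(integer(0), 0, 2)
  for (i in seq_along(assign)) {
    j <- assign[i]
    if (j < 1L) next
    a <- if (transposed) j else i
    b <- if (transposed) i else j
    if (cost[a, b] < .BIGCOST) pairs <- rbind(pairs, c(a, b))
  }
  pairs
}

#' Score detections against a scene's ground truth
#'
#' Matches detected centroids one-to-one to the true centers of visible
#' cells (optimal assignment within \code{maxDist}) and reports detection
#' precision, recall and the RMSE of matched centroids.
#'
#' @param scene a [SyntheticScene-class].
#' @param detectionsByTime list of per-time-point detection lists (as from
#'   [segmentTimeLapse()]).
#' @param maxDist maximum centroid distance for a true-positive match
#'   (default 3 px).
#' @return list with \code{precision}, \code{recall}, \code{rmse},
#'   \code{nTrue}, \code{nDetected}, \code{nMatched}.
#' @export
scoreDetections <- function(scene, detectionsByTime, maxDist = 3) {
  tr <- scene@truth
  nMatch <- 0L; nTrue <- 0L; nDet <- 0L; sq <- 0
  for (t in seq_along(detectionsByTime)) {
    sub <- tr[tr$frame == t - 1L & tr$visible, , drop = FALSE]
    dets <- detectionsByTime[[t]]
    cen <- if (length(dets))
      t(vapply(dets, function(d) d@features$centroid, numeric(2)))
    else matrix(numeric(0), 0, 2)
    pairs <- .matchPoints(cbind(sub$row, sub$col), cen, maxDist)
    nTrue <- nTrue + nrow(sub)
    nDet <- nDet + length(dets)
    nMatch <- nMatch + nrow(pairs)
    if (nrow(pairs))
      sq <- sq + sum((sub$row[pairs[, 1]] - cen[pairs[, 2], 1])^2 +
                     (sub$col[pairs[, 1]] - cen[pairs[, 2], 2])^2)
  }
  list(precision = if (nDet) nMatch / nDet else NA_real_,
       recall = if (nTrue) nMatch / nTrue else NA_real_,
       rmse = if (nMatch) sqrt(sq / nMatch) else NA_real_,
       nTrue = nTrue, nDetected = nDet, nMatched = nMatch)
}

#' Score tracking against a scene's ground truth
#'
#' For every pair of consecutive frames in which a true cell is visible in
#' both, the link is reproduced when the detections matched to that cell at
#' the two time points exist and belong to the same track.
#'
#' @param scene a [SyntheticScene-class].
#' @param tracks list of [Track-class] from [buildTracks()].
#' @param maxDist matching tolerance in px (default 3).
#' @return list with \code{linkAccuracy}, \code{nLinks} (ground-truth
#'   links evaluated), \code{nCorrect}, and \code{cellTrackMap}, a
#'   data.frame mapping each true cell to the track holding the majority of
#'   its matched detections, with \code{firstFrame}/\code{lastFrame} the
#'   first and last frames at which the cell was matched to any tracked
#'   detection (its recovered entry and exit).
#' @details Cells partially outside the field of view have centroids biased
#'   toward the interior by up to about half a radius, so the matching gate
#'   for a truth cell is \code{max(maxDist, 0.6 * radius)}.
#' @export
scoreLinks <- function(scene, tracks, maxDist = 3) {
  tr <- scene@truth
  TT <- scene@config$nFrames
  # per-frame tracked detections
  detByTime <- vector("list", TT)
  whoByTime <- vector("list", TT)
  for (k in seq_along(tracks)) {
    tk <- tracks[[k]]
    for (e in seq_along(tk@detections)) {
      t <- tk@timeIndices[e] + 1L
      detByTime[[t]] <- c(detByTime[[t]], tk@detections[e])
      whoByTime[[t]] <- c(whoByTime[[t]], k)
    }
  }
  # cellAt[t, cell] = track index matched, NA if undetected
  cells <- unique(tr$cell)
  cellAt <- matrix(NA_integer_, TT, max(c(cells, 1L)))
  for (t in seq_len(TT)) {
    sub <- tr[tr$frame == t - 1L & tr$visible, , drop = FALSE]
    dets <- detByTime[[t]]
    cen <- if (length(dets))
      t(vapply(dets, function(d) d@features$centroid, numeric(2)))
    else matrix(numeric(0), 0, 2)
    pairs <- .matchPoints(cbind(sub$row, sub$col), cen,
                          pmax(maxDist, 0.6 * sub$radius))
    if (nrow(pairs))
      cellAt[t, sub$cell[pairs[, 1]]] <- whoByTime[[t]][pairs[, 2]]
  }
  nLinks <- 0L; nCorrect <- 0L
  for (cell in cells) {
    vis <- tr$visible[tr$cell == cell][order(tr$frame[tr$cell == cell])]
    for (t in seq_len(TT - 1L)) {
      if (vis[t] && vis[t + 1L]) {
        nLinks <- nLinks + 1L
        a <- cellAt[t, cell]; b <- cellAt[t + 1L, cell]
        if (!is.na(a) && !is.na(b) && a == b) nCorrect <- nCorrect + 1L
      }
    }
  }
  maps <- lapply(cells, function(cell) {
    hits <- which(!is.na(cellAt[, cell]))
    if (!length(hits))
      return(data.frame(cell = cell, track = NA_integer_,
                        firstFrame = NA_integer_, lastFrame = NA_integer_))
    tab <- table(cellAt[hits, cell])
    best <- as.integer(names(tab)[which.max(tab)])
    data.frame(cell = cell, track = best,
               firstFrame = min(hits) - 1L, lastFrame = max(hits) - 1L)
  })
  list(linkAccuracy = if (nLinks) nCorrect / nLinks else NA_real_,
       nLinks = nLinks, nCorrect = nCorrect,
       cellTrackMap = do.call(rbind, maps))
}
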
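#' @include filter.R
NULL

#' Tracking configuration
#'
#' @param gateRadius maximum admissible centroid displacement per frame step
#'   in pixels (default 20, consistent with the largest per-step distances
#'   seen in migrating T cells). For a track bridged over a gap of g frames
#'   the gate is enlarged to \code{gateRadius * g}.
#' @param featureWeights non-negative weights for the normalized feature
#'   differences entering the link cost, in the order relative area
#'   difference, mean-intensity difference over the bit range, relative
#'   major-axis difference. Default \code{c(1, 1, 0.5)}.
#' @param maxMissedFrames frames a track may go undetected before it is
#'   terminated (default 2).
#' @param intensityRange intensity normalizer for the mean-intensity
#'   difference (default 65535, the 16-bit range).
#' @return validated config list of class \code{TrackingConfig}.
#' @export
trackingConfig <- function(gateRadius = 20, featureWeights = c(1, 1, 0.5),
                           maxMissedFrames = 2L, intensityRange = 65535) {
  if (!is.numeric(gateRadius) || gateRadius <= 0)
    stop("gateRadius must be > 0")
  if (length(featureWeights) != 3L || any(featureWeights < 0))
    stop("featureWeights must be 3 non-negative numbers")
  if (maxMissedFrames < 0L) stop("maxMissedFrames must be >= 0")
  structure(list(gateRadius = as.numeric(gateRadius),
                 featureWeights = as.numeric(featureWeights),
                 maxMissedFrames = as.integer(maxMissedFrames),
                 intensityRange = as.numeric(intensityRange)),
            class = c("TrackingConfig", "list"))
}

# Shortest-augmenting-path solution of the rectangular minimum-cost
# assignment problem (Hungarian method with potentials, O(n^2 m)).
# cost: n x m matrix, n <= m. Returns for each row the assigned column.
.solveAssignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  u <- numeric(n + 1)
  v <- numeric(m + 1)
  p <- integer(m + 1)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0L) assign[p[j + 1]] <- j
  assign
}

.BIGCOST <- 1e9

# Link cost matrix between two detection lists; inadmissible pairs (centroid
# distance beyond the per-row gate) get .BIGCOST.
.linkCostMatrix <- function(detsA, detsB, config, gates) {
  nA <- length(detsA); nB <- length(detsB)
  fa <- lapply(detsA, function(d) d@features)
  fb <- lapply(detsB, function(d) d@features)
  ca <- t(vapply(fa, `[[`, numeric(2), "centroid"))
  cb <- t(vapply(fb, `[[`, numeric(2), "centroid"))
  w <- config$featureWeights
  cost <- matrix(.BIGCOST, nA, nB)
  for (i in seq_len(nA)) {
    d <- sqrt((cb[, 1] - ca[i, 1])^2 + (cb[, 2] - ca[i, 2])^2)
    ok <- d <= gates[i]
    if (!any(ok)) next
    aA <- fa[[i]]$area; mA <- fa[[i]]$meanIntensity; jA <- fa[[i]]$majorAxis
    for (j in which(ok)) {
      cost[i, j] <- d[j] +
        w[1] * abs(fb[[j]]$area - aA) / aA +
        w[2] * abs(fb[[j]]$meanIntensity - mA) / config$intensityRange +
        w[3] * abs(fb[[j]]$majorAxis - jA) / jA
    }
  }
  cost
}

# Solve a gated assignment between two detection lists. Returns matched
# index pairs, unmatched indices on both sides, and the total matched cost.
.linkAssign <- function(detsA, detsB, config, gates) {
  nA <- length(detsA); nB <- length(detsB)
  empty <- list(pairs = matrix(integer(0), 0, 2,
                               dimnames = list(NULL, c("from", "to"))),
                unmatchedFrom = seq_len(nA), unmatchedTo = seq_len(nB),
                totalCost = 0)
  if (nA == 0L || nB == 0L) return(empty)
  cost <- .linkCostMatrix(detsA, detsB, config, gates)
  if (all(cost >= .BIGCOST)) return(empty)
  transposed <- nA > nB
  work <- if (transposed) t(cost) else cost
  m <- ncol(work)
  assign <- .solveAssignment(work)
  pairs <- matrix(integer(0), 0, 2)
  total <- 0
  for (i in seq_along(assign)) {
    j <- assign[i]
    if (j >= 1L && j <= m) {
      a <- if (transposed) j else i
      b <- if (transposed) i else j
      if (cost[a, b] < .BIGCOST) {
        pairs <- rbind(pairs, c(a, b))
        total <- total + cost[a, b]
      }
    }
  }
  colnames(pairs) <- c("from", "to")
  list(pairs = pairs,
       unmatchedFrom = setdiff(seq_len(nA), pairs[, 1]),
       unmatchedTo = setdiff(seq_len(nB), pairs[, 2]),
       totalCost = total)
}

#' Link detections between two consecutive time points
#'
#' Builds the gated link cost (centroid distance plus weighted normalized
#' feature differences; pairs farther apart than \code{gateRadius} are
#' inadmissible) and solves the one-to-one assignment optimally: among
#' assignments with the largest number of admissible links, the one with
#' minimum total cost. Detections with no admissible partner stay unmatched.
#'
#' @param detsT,detsNext detection lists at time t and t+1.
#' @param config a [trackingConfig()].
#' @param gateFactor multiplier on \code{gateRadius} (used when bridging a
#'   gap of more than one frame).
#' @return list with \code{pairs} (2-column index matrix \code{from, to}),
#'   \code{unmatchedFrom}, \code{unmatchedTo} and \code{totalCost} (sum of
#'   matched link costs).
#' @export
linkFrames <- function(detsT, detsNext, config = trackingConfig(),
                       gateFactor = 1) {
  gates <- rep(config$gateRadius * gateFactor, length(detsT))
  .linkAssign(detsT, detsNext, config, gates)
}

#' Build tracks across all time points
#'
#' Iterates frame-to-frame linking: unmatched detections start new tracks
#' (cells entering the field of view), tracks undetected for more than
#' \code{maxMissedFrames} frames terminate (cells leaving), and a track
#' missed for at most that many frames may re-link within a gate enlarged
#' proportionally to the gap. Every detection ends up in exactly one track.
#'
#' @param detectionsByTime list whose element \code{t+1} holds the
#'   detections at 0-based time point t (empty lists allowed).
#' @param config a [trackingConfig()].
#' @return list of [Track-class] objects in birth order.
#' @export
buildTracks <- function(detectionsByTime, config = trackingConfig()) {
  T <- length(detectionsByTime)
  for (t in seq_len(T)) {
    for (det in detectionsByTime[[t]]) {
      if (det@timeIndex != t - 1L)
        stop(sprintf(
          "detection at slot %d has time index %d; time points must be consecutive from 0",
          t - 1L, det@timeIndex))
    }
  }
  store <- list()   # each: list(dets = list, times = integer)
  active <- integer(0)
  lastTime <- integer(0)

  birth <- function(det, t) {
    store[[length(store) + 1L]] <<- list(dets = list(det), times = t)
    active <<- c(active, length(store))
    lastTime <<- c(lastTime, t)
  }

  if (T >= 1L) for (det in detectionsByTime[[1]]) birth(det, 0L)

  for (t in seq_len(T - 1L)) {  # linking into 0-based time t
    newDets <- detectionsByTime[[t + 1L]]
    gaps <- t - lastTime
    alive <- which(gaps <= config$maxMissedFrames + 1L)
    heads <- lapply(active[alive],
                    function(k) store[[k]]$dets[[length(store[[k]]$dets)]])
    gates <- config$gateRadius * gaps[alive]
    res <- .linkAssign(heads, newDets, config, gates)
    matchedDet <- integer(0)
    if (nrow(res$pairs)) {
      for (r in seq_len(nrow(res$pairs))) {
        k <- active[alive[res$pairs[r, 1]]]
        det <- newDets[[res$pairs[r, 2]]]
        store[[k]]$dets <- c(store[[k]]$dets, list(det))
        store[[k]]$times <- c(store[[k]]$times, t)
        lastTime[active == k] <- t
      }
      matchedDet <- res$pairs[, 2]
    }
    # retire tracks whose gap is exhausted
    gaps <- t - lastTime
    active <- active[gaps <= config$maxMissedFrames]
    lastTime <- lastTime[gaps <= config$maxMissedFrames]
    for (j in setdiff(seq_along(newDets), matchedDet))
      birth(newDets[[j]], t)
  }

  out <- vector("list", length(store))
  for (k in seq_along(store)) {
    dets <- store[[k]]$dets
    cen <- t(vapply(dets, function(d) d@features$centroid, numeric(2)))
    sd <- if (length(dets) > 1L)
      sqrt(rowSums((cen[-1, , drop = FALSE] -
                      cen[-nrow(cen), , drop = FALSE])^2))
    else numeric(0)
    out[[k]] <- new("Track", trackId = sprintf("T%03d", k),
                    timeIndices = as.integer(store[[k]]$times),
                    detections = dets, stepDistances = sd)
  }
  out
}

#' @rdname Track
#' @param x a \code{Track}
#' @export
setMethod("trackId", "Track", function(x) x@trackId)

#' @rdname Track
#' @export
setMethod("stepDistances", "Track", function(x) x@stepDistances)

#' @rdname Track
#' @export
setMethod("length", "Track", function(x) length(x@detections))

setMethod("show", "Track", function(object) {
  cat(sprintf("Track %s: %d detections, t=%d..%d, total path %.1f px\n",
              object@trackId, length(object@detections),
              min(object@timeIndices), max(object@timeIndices),
              sum(object@stepDistances)))
})
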
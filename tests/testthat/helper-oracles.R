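# Independent brute-force oracles and small scene builders used across the
# suite. These deliberately avoid the package's own code paths.

# --- geometry helpers -------------------------------------------------------

# pixel set of a digital disk: all (row, col) with distance^2 <= r^2
diskPixels <- function(centerRow, centerCol, r) {
  g <- expand.grid(row = floor(centerRow - r - 1):ceiling(centerRow + r + 1),
                   col = floor(centerCol - r - 1):ceiling(centerCol + r + 1))
  keep <- (g$row - centerRow)^2 + (g$col - centerCol)^2 <= r^2
  m <- as.matrix(g[keep, , drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- NULL
  m
}

# paint hard-edged disks of a given intensity onto a constant background
renderDiskFrame <- function(shape, centers, radii, bg, fg, bitDepth = 16L,
                            timeIndex = 0L) {
  m <- matrix(as.integer(bg), shape[1], shape[2])
  for (k in seq_along(radii)) {
    px <- diskPixels(centers[k, 1], centers[k, 2], radii[k])
    ok <- px[, 1] >= 0 & px[, 1] < shape[1] & px[, 2] >= 0 & px[, 2] < shape[2]
    px <- px[ok, , drop = FALSE]
    m[cbind(px[, 1] + 1L, px[, 2] + 1L)] <- as.integer(fg)
  }
  Frame(m, bitDepth = bitDepth, timeIndex = timeIndex)
}

# a random 8-connected blob of roughly the requested area, grown by a
# random walk from a start pixel (deterministic under the caller's seed)
randomBlob <- function(area, startRow, startCol, maxRow, maxCol) {
  cur <- c(startRow, startCol)
  seen <- new.env(hash = TRUE)
  px <- matrix(cur, 1, 2)
  assign(paste(cur, collapse = ","), TRUE, envir = seen)
  while (nrow(px) < area) {
    step <- sample(c(-1L, 0L, 1L), 2, replace = TRUE)
    cand <- pmin(pmax(cur + step, c(0L, 0L)), c(maxRow, maxCol))
    cur <- cand
    key <- paste(cand, collapse = ",")
    if (!exists(key, envir = seen)) {
      assign(key, TRUE, envir = seen)
      px <- rbind(px, cand)
    }
  }
  colnames(px) <- c("row", "col")
  storage.mode(px) <- "integer"
  px
}

# --- feature oracle ---------------------------------------------------------

# naive per-pixel recomputation of the exactly-defined measures
bruteFeatures <- function(px, frameMat) {
  n <- nrow(px)
  rs <- 0; cs <- 0
  minr <- Inf; maxr <- -Inf; minc <- Inf; maxc <- -Inf
  mx <- -Inf; sm <- 0
  for (i in seq_len(n)) {
    r <- px[i, 1]; cc <- px[i, 2]
    rs <- rs + r; cs <- cs + cc
    minr <- min(minr, r); maxr <- max(maxr, r)
    minc <- min(minc, cc); maxc <- max(maxc, cc)
    v <- frameMat[r + 1, cc + 1]
    mx <- max(mx, v); sm <- sm + v
  }
  list(area = n, centroid = c(rs / n, cs / n),
       extent = n / ((maxr - minr + 1) * (maxc - minc + 1)),
       maxIntensity = mx, meanIntensity = sm / n)
}

# independent second-moment ellipse computation (loop sums, no matrix code)
bruteMoments <- function(px) {
  n <- nrow(px)
  rbar <- sum(px[, 1]) / n; cbar <- sum(px[, 2]) / n
  srr <- 0; scc <- 0; src <- 0
  for (i in seq_len(n)) {
    dr <- px[i, 1] - rbar; dc <- px[i, 2] - cbar
    srr <- srr + dr * dr; scc <- scc + dc * dc; src <- src + dr * dc
  }
  murr <- srr / n + 1 / 12; mucc <- scc / n + 1 / 12; murc <- src / n
  disc <- sqrt((murr - mucc)^2 + 4 * murc^2)
  l1 <- (murr + mucc + disc) / 2; l2 <- (murr + mucc - disc) / 2
  list(majorAxis = 4 * sqrt(l1), minorAxis = 4 * sqrt(l2),
       eccentricity = sqrt(1 - l2 / l1))
}

# --- threshold oracle -------------------------------------------------------

# exhaustive between-class-variance scan over every integer level; the
# reported threshold is the midpoint between the classes of the smallest
# variance-maximizing split
bruteOtsu <- function(values) {
  v <- as.integer(values)
  lev <- min(v):(max(v) - 1L)
  if (!length(lev) || min(v) == max(v)) return(NULL)
  n <- length(v)
  best <- -Inf; bestT <- NA_integer_
  for (t in lev) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / n; w1 <- 1 - w0
    s <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (s > best + 1e-12) { best <- s; bestT <- t }
  }
  (max(v[v <= bestT]) + min(v[v > bestT])) / 2
}

# --- enhancement oracle -----------------------------------------------------

# sort-based quantile with linear interpolation (type-7 order statistics),
# computed by hand, then a per-pixel loop applying the saturating map
bruteStretch <- function(mat, s, maxv) {
  v <- sort(as.numeric(mat))
  n <- length(v)
  q <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    v[lo] + (h - lo) * (v[hi] - v[lo])
  }
  lo <- q(s); hi <- q(1 - s)
  if (hi <= lo) return(mat)
  out <- mat
  for (i in seq_along(mat)) {
    y <- (mat[i] - lo) / (hi - lo) * maxv
    y <- min(max(y, 0), maxv)
    out[i] <- floor(y + 0.5)
  }
  storage.mode(out) <- "integer"
  out
}

# --- assignment oracle ------------------------------------------------------

allPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in allPermutations(n - 1L)) {
    for (k in seq_len(n)) out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  }
  out
}

# minimum total cost over all complete assignments of the BIG-padded square
# matrix; entries >= big are treated as "unmatched" and excluded from the
# reported matched cost
bruteAssignment <- function(cost, big = 1e9) {
  nA <- nrow(cost); nB <- ncol(cost)
  m <- max(nA, nB)
  pad <- matrix(big, m, m)
  pad[seq_len(nA), seq_len(nB)] <- cost
  best <- Inf; bestMatched <- NULL
  for (p in allPermutations(m)) {
    tot <- sum(pad[cbind(seq_len(m), p)])
    if (tot < best - 1e-12) {
      best <- tot
      keep <- which(seq_len(m) <= nA & p <= nB & pad[cbind(seq_len(m), p)] < big)
      bestMatched <- cbind(seq_len(m)[keep], p[keep])
    }
  }
  list(matchedCost = if (is.null(bestMatched) || !nrow(bestMatched)) 0
         else sum(cost[bestMatched]),
       nMatched = if (is.null(bestMatched)) 0L else nrow(bestMatched))
}

# --- detection builders -----------------------------------------------------

# fabricate a CellDetection at a given centroid with given feature values
# (a square pixel patch placed to hit the requested centroid)
fakeDetection <- function(centroid, timeIndex = 0L, area = 100,
                          meanIntensity = 30000, majorAxis = 12,
                          frame = NULL) {
  side <- max(1L, as.integer(round(sqrt(area))))
  r0 <- as.integer(round(centroid[1] - (side - 1) / 2))
  c0 <- as.integer(round(centroid[2] - (side - 1) / 2))
  px <- as.matrix(expand.grid(row = r0:(r0 + side - 1L),
                              col = c0:(c0 + side - 1L)))
  storage.mode(px) <- "integer"
  feats <- list(centroid = centroid, area = area, perimeter = 4 * (side - 1),
                majorAxis = majorAxis, minorAxis = majorAxis * 0.8,
                extent = 1, eccentricity = 0.3,
                maxIntensity = meanIntensity * 1.2,
                meanIntensity = meanIntensity)
  new("CellDetection", timeIndex = as.integer(timeIndex),
      phaseLabel = "phase1", pixels = px,
      bbox = c(min(px[, 1]), min(px[, 2]), max(px[, 1]) + 1, max(px[, 2]) + 1),
      features = feats, detectionId = "")
}
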
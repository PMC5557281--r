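# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Modal value of an integer vector (smallest value on ties).
.modalValue <- function(x) {
  x <- as.integer(x)
  offset <- min(x)
  counts <- tabulate(x - offset + 1L)
  offset + which.max(counts) - 1L
}

# Is a (row, col) pixel-set matrix a single 8-connected component?
.isConnected8 <- function(px) {
  n <- nrow(px)
  if (n == 1L) return(TRUE)
  r0 <- min(px[, 1]); c0 <- min(px[, 2])
  h <- max(px[, 1]) - r0 + 1L; w <- max(px[, 2]) - c0 + 1L
  m <- matrix(FALSE, h, w)
  m[cbind(px[, 1] - r0 + 1L, px[, 2] - c0 + 1L)] <- TRUE
  lab <- .labelComponents(m)
  max(lab) == 1L
}

# 8-connected component labeling of a logical matrix.
# Returns an integer matrix of the same shape; 0 = background, components
# numbered 1..k in order of their first pixel in column-major scan order.
.labelComponents <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  nextLab <- 0L
  # neighbor offsets in linear (column-major) indexing, guarded per-pixel
  for (start in idx) {
    if (lab[start] != 0L) next
    nextLab <- nextLab + 1L
    queue <- start
    lab[start] <- nextLab
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((p - 1L) %% h) + 1L
      cc <- ((p - 1L) %/% h) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        rr <- r + dr; ccc <- cc + dc
        if (rr < 1L || rr > h || ccc < 1L || ccc > w) next
        q <- (ccc - 1L) * h + rr
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- nextLab
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# Closed-interval check helper for config validation.
.checkInterval <- function(iv, name) {
  if (is.null(iv)) return(invisible(TRUE))
  if (length(iv) != 2L || any(!is.finite(iv)) || iv[1] > iv[2])
    stop(sprintf("'%s' must be a finite interval with lower <= upper", name),
         call. = FALSE)
  invisible(TRUE)
}

.maxval <- function(frame) 2^frame@bitDepth - 1

# Euclidean distance between 0-based (row, col) centroids.

#' Euclidean distance between two centroids
#'
#' @param a,b numeric length-2 centroids \code{(row, col)} in pixel units.
#' @return the Euclidean distance in pixels.
#' @examples
#' computeDistance(c(0, 0), c(3, 4))  # 5
#' @export
computeDistance <- function(a, b) {
  stopifnot(length(a) == 2L, length(b) == 2L,
            all(is.finite(a)), all(is.finite(b)))
  sqrt(sum((a - b)^2))
}
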
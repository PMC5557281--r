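#' @include AllClasses.R utils.R
NULL

# Outer-contour length of a single 8-connected region, by Moore-neighbor
# boundary tracing with Jacob's stopping criterion. Steps between
# consecutive contour pixels are weighted 1 (orthogonal) or sqrt(2)
# (diagonal). A single-pixel region has length 0.
.contourLength <- function(mask) {
  if (sum(mask) <= 1L) return(0)
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask, arr.ind = TRUE)
  ord <- order(fg[, 1], fg[, 2])
  s <- as.integer(fg[ord[1], ])
  # clockwise Moore neighborhood starting at West
  off <- matrix(c(0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L,
                  0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L),
                ncol = 2, byrow = TRUE)
  inside <- function(r, c) r >= 1L && r <= h && c >= 1L && c <= w && mask[r, c]
  p <- s; bdir <- 1L
  total <- 0; steps <- 0L; maxSteps <- 8L * (h * w) + 8L
  firstMove <- NULL; startP <- NULL
  repeat {
    k <- bdir; found <- FALSE
    for (j in 1:8) {
      k <- (k %% 8L) + 1L
      r <- p[1] + off[k, 1]; cc <- p[2] + off[k, 2]
      if (inside(r, cc)) { found <- TRUE; break }
    }
    if (!found) return(0)
    stepLen <- if (off[k, 1] != 0L && off[k, 2] != 0L) sqrt(2) else 1
    prev <- p
    p <- c(r, cc)
    if (is.null(firstMove)) {
      startP <- prev; firstMove <- p
      total <- total + stepLen
    } else if (all(p == firstMove) && all(prev == startP)) {
      break  # first transition recurred: contour closed
    } else {
      total <- total + stepLen
    }
    dd <- prev - p
    bdir <- which(off[, 1] == dd[1] & off[, 2] == dd[2])
    steps <- steps + 1L
    if (steps > maxSteps) break
  }
  total
}

#' Compute the per-cell measure set for a pixel region
#'
#' Given the pixel set of one segmented cell and the intensity frame it was
#' detected in, computes the full feature vector: centroid (unweighted mean
#' of pixel coordinates, 0-based), area (pixel count), extent (area over
#' bounding-box area), perimeter (weighted boundary-step contour length:
#' orthogonal steps 1, diagonal steps sqrt(2)), major/minor axis lengths and
#' eccentricity of the ellipse with the same normalized second central
#' moments as the region (per-pixel 1/12 variance correction, the standard
#' regionprops convention), and max/mean intensity over the region.
#'
#' @param pixelSet integer matrix with columns \code{(row, col)}, 0-based,
#'   non-empty, 8-connected, within the frame bounds.
#' @param intensityFrame the [Frame-class] supplying intensities (normally
#'   the enhanced frame that was segmented).
#' @return named list with elements \code{centroid}, \code{area},
#'   \code{perimeter}, \code{majorAxis}, \code{minorAxis}, \code{extent},
#'   \code{eccentricity}, \code{maxIntensity}, \code{meanIntensity}.
#' @examples
#' f <- Frame(matrix(10L, 32, 32))
#' sq <- as.matrix(expand.grid(row = 0:2, col = 0:2))
#' computeRegionFeatures(sq, f)$eccentricity  # 0: four-fold symmetry
#' @export
computeRegionFeatures <- function(pixelSet, intensityFrame) {
  px <- pixelSet
  if (is.null(dim(px))) px <- matrix(px, ncol = 2)
  if (!nrow(px)) stop("pixelSet must be non-empty")
  storage.mode(px) <- "integer"
  d <- dim(intensityFrame@pixels)
  if (min(px) < 0L || max(px[, 1]) >= d[1] || max(px[, 2]) >= d[2])
    stop("pixelSet contains out-of-bounds pixels")
  n <- nrow(px)
  r <- px[, 1]; cc <- px[, 2]
  rbar <- mean(r); cbar <- mean(cc)
  bbR <- max(r) - min(r) + 1L
  bbC <- max(cc) - min(cc) + 1L
  # normalized second central moments with per-pixel 1/12 correction
  murr <- mean((r - rbar)^2) + 1 / 12
  mucc <- mean((cc - cbar)^2) + 1 / 12
  murc <- mean((r - rbar) * (cc - cbar))
  common <- sqrt((murr - mucc)^2 + 4 * murc^2)
  l1 <- (murr + mucc + common) / 2
  l2 <- (murr + mucc - common) / 2
  mask <- matrix(FALSE, bbR, bbC)
  mask[cbind(r - min(r) + 1L, cc - min(cc) + 1L)] <- TRUE
  vals <- intensityFrame@pixels[cbind(r + 1L, cc + 1L)]
  list(
    centroid = c(rbar, cbar),
    area = n,
    perimeter = .contourLength(mask),
    majorAxis = 4 * sqrt(l1),
    minorAxis = 4 * sqrt(l2),
    extent = n / (bbR * bbC),
    eccentricity = sqrt(max(0, 1 - l2 / l1)),
    maxIntensity = max(vals),
    meanIntensity = mean(vals)
  )
}
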
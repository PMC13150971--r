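# Linear filtering and edge detection. Convolution goes through
# EBImage::filter2 (FFT, replicate boundary); kernels wider than the image
# are capped at the largest odd size that fits.

.oddCap <- function(n, M, N) {
  n <- as.integer(n)
  if (n %% 2L == 0L) n <- n + 1L
  cap <- min(M, N)
  if (cap %% 2L == 0L) cap <- cap - 1L
  max(3L, min(n, cap))
}

.convolve2 <- function(img, kernel) {
  matrix(as.numeric(EBImage::filter2(img, kernel, boundary = "replicate")),
    nrow(img))
}

.gaussKernel <- function(sigma, n) {
  half <- (n - 1) / 2
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

.logKernel <- function(sigma, n) {
  half <- (n - 1) / 2
  x <- matrix(rep(-half:half, n), n, n)
  y <- t(x)
  r2 <- x^2 + y^2
  k <- (r2 - 2 * sigma^2) / (sigma^4) * exp(-r2 / (2 * sigma^2))
  k - mean(k)   # zero-sum: flat regions give exactly zero response
}

# 3x3 median via a full compare-exchange network (exact, vectorised)
.median3x3 <- function(img) {
  v <- vector("list", 9L)
  i <- 1L
  for (dr in -1:1) for (dc in -1:1) { v[[i]] <- .shiftRep(img, dr, dc); i <- i + 1L }
  for (a in 1:8) for (b in seq(a + 1L, 9L)) {
    lo <- pmin(v[[a]], v[[b]]); hi <- pmax(v[[a]], v[[b]])
    v[[a]] <- lo; v[[b]] <- hi
  }
  v[[5L]]
}

# 3x3 grayscale min filter (erosion with a 3x3 square of ones)
.min3x3 <- function(img) {
  out <- img
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- pmin(out, .shiftRep(img, dr, dc))
  }
  out
}

#' Laplacian-of-Gaussian edge detection
#'
#' Filters the image with a zero-sum LoG kernel of variance \code{sigma2}
#' (kernel standard deviation \code{sqrt(sigma2)}) and side
#' \code{ceiling(sigma2 * 3) * 2 + 1} (capped at the image), then marks
#' zero-crossing pixels whose absolute response reaches the 75th percentile
#' of the absolute response over all crossings. Zero-crossings of the LoG
#' trace closed contours around blob-like regions such as the lung fields.
#'
#' @param img numeric matrix in \[0, 1\].
#' @param sigma2 filter variance (> 0); values of 0 are floored to 0.5 with
#'   a warning.
#' @return list with logical \code{edges}, the \code{sigma2} used and the
#'   kernel side \code{n}.
#' @export
logEdgeDetect <- function(img, sigma2) {
  img <- imgPixels(img)
  if (sigma2 <= 0) { warning("sigma2 floored to 0.5"); sigma2 <- 0.5 }
  n <- .oddCap(ceiling(sigma2 * 3) * 2 + 1, nrow(img), ncol(img))
  resp <- .convolve2(img, .logKernel(sqrt(sigma2), n))
  if (max(abs(resp)) < 1e-9) {
    return(list(edges = matrix(FALSE, nrow(img), ncol(img)), sigma2 = sigma2,
      n = n))
  }
  s <- sign(resp)
  cross <- matrix(FALSE, nrow(img), ncol(img))
  for (sh in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    nb <- .shiftRep(s, sh[1], sh[2])
    cross <- cross | (s * nb < 0)
  }
  if (!any(cross)) {
    return(list(edges = cross, sigma2 = sigma2, n = n))
  }
  thr <- stats::quantile(abs(resp[cross]), 0.75, names = FALSE)
  list(edges = cross & abs(resp) >= thr, sigma2 = sigma2, n = n)
}

#' Canny edge detection with median-relative thresholds
#'
#' Gaussian smoothing at variance \code{sigma2} (kernel side
#' \code{ceiling(sigma2 * 3) * 2 + 1}, capped at the image), central-difference
#' gradients, non-maximum suppression over four quantised directions, and
#' dual-threshold hysteresis. The nominal thresholds \code{t1 < t2} are
#' multipliers of the median of the max-normalised gradient magnitude:
#' \code{low = t1 * med}, \code{high = t2 * med}, both clamped to (0, 1].
#' Hysteresis keeps every weak-edge component 8-connected to a strong pixel.
#'
#' @param img numeric matrix in \[0, 1\].
#' @param t1,t2 nominal low/high threshold multipliers.
#' @param sigma2 smoothing variance (> 0, floored to 0.5 with warning).
#' @return logical edge map.
#' @export
cannyEdges <- function(img, t1, t2, sigma2) {
  img <- imgPixels(img)
  M <- nrow(img); N <- ncol(img)
  if (sigma2 <= 0) { warning("sigma2 floored to 0.5"); sigma2 <- 0.5 }
  n <- .oddCap(ceiling(sigma2 * 3) * 2 + 1, M, N)
  sm <- .convolve2(img, .gaussKernel(sqrt(sigma2), n))
  gx <- (.shiftRep(sm, 0L, -1L) - .shiftRep(sm, 0L, 1L)) / 2  # d/dcol
  gy <- (.shiftRep(sm, -1L, 0L) - .shiftRep(sm, 1L, 0L)) / 2  # d/drow
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  if (mmax < 1e-9) return(matrix(FALSE, M, N))
  mag <- mag / mmax
  # quantise direction into 4 bins: 0 = horizontal gradient (vertical edge)
  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  bin <- floor((ang + pi / 8) / (pi / 4)) %% 4
  nms <- matrix(FALSE, M, N)
  nbr <- list(
    list(c(0L, -1L), c(0L, 1L)),    # gradient along columns
    list(c(-1L, -1L), c(1L, 1L)),   # diagonal
    list(c(-1L, 0L), c(1L, 0L)),    # gradient along rows
    list(c(-1L, 1L), c(1L, -1L))    # anti-diagonal
  )
  for (b in 0:3) {
    sel <- bin == b
    a <- .shiftRep(mag, nbr[[b + 1]][[1]][1], nbr[[b + 1]][[1]][2])
    c2 <- .shiftRep(mag, nbr[[b + 1]][[2]][1], nbr[[b + 1]][[2]][2])
    nms <- nms | (sel & mag >= a & mag >= c2)
  }
  med <- stats::median(mag[mag > 0])
  low  <- min(max(t1 * med, 1e-6), 1)
  high <- min(max(t2 * med, 1e-6), 1)
  if (high < low) high <- low
  weak <- nms & mag >= low
  strong <- nms & mag >= high
  if (!any(strong)) return(strong)
  reconstructComponents(weak, strong)
}
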
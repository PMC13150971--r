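# Basic intensity primitives. All functions operate on numeric matrices in
# [0,1] (GrayImage objects are unwrapped transparently) and are pure.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

.checkMask <- function(m, name = "mask") {
  if (is(m, "GrayImage")) stop(name, " must be a logical mask, not a GrayImage")
  if (!is.matrix(m) || !is.logical(m)) stop(name, " must be a logical matrix")
  m
}

.sameShape <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch: ",
    paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"))
  invisible(TRUE)
}

# shift a matrix by (dr, dc) with replicate padding
.shiftRep <- function(x, dr, dc) {
  M <- nrow(x); N <- ncol(x)
  ri <- pmin(pmax(seq_len(M) - dr, 1L), M)
  ci <- pmin(pmax(seq_len(N) - dc, 1L), N)
  x[ri, ci, drop = FALSE]
}

# shift a logical matrix by (dr, dc) padding with FALSE (or numeric with 0)
.shiftZero <- function(x, dr, dc) {
  M <- nrow(x); N <- ncol(x)
  out <- x
  out[] <- if (is.logical(x)) FALSE else 0
  rs <- max(1L, 1L + dr):min(M, M + dr)
  cs <- max(1L, 1L + dc):min(N, N + dc)
  if (length(rs) > 0 && length(cs) > 0) out[rs, cs] <- x[rs - dr, cs - dc]
  out
}

#' Linear contrast stretch
#'
#' Maps intensities through \code{clamp((x - lo) / (hi - lo), 0, 1)}: values
#' at or below \code{lo} go to 0, values at or above \code{hi} go to 1, and
#' the map is monotone non-decreasing in between.
#'
#' @param img GrayImage or numeric matrix in \[0, 1\].
#' @param lo,hi stretch bounds, \code{0 <= lo < hi <= 1}.
#' @return numeric matrix in \[0, 1\] of the same shape.
#' @examples
#' contrastStretch(matrix(c(0.05, 0.5, 0.95), 1, 3), 0.05, 0.95)
#' @export
contrastStretch <- function(img, lo, hi) {
  p <- imgPixels(img)
  if (!is.numeric(lo) || !is.numeric(hi) || lo >= hi || lo < 0 || hi > 1)
    stop("require 0 <= lo < hi <= 1")
  clamp01((p - lo) / (hi - lo))
}

#' Average local standard deviation statistic
#'
#' For every pixel, the population standard deviation of the m x n window
#' centred on it (clipped at the image borders) is computed; the mean of
#' these local deviations, divided by the image maximum, gives the adaptive
#' scale statistic used throughout the heuristic stage (filter variances and
#' structuring-element sizes are proportional to it). The statistic is 0 for
#' a constant image and invariant under multiplicative rescaling of the
#' image. The default window is half the image in each dimension
#' (\code{m = round(0.5 M)}, \code{n = round(0.5 N)}); callers may supply a
#' different window via \code{window}, e.g. \code{c(3, 3)} for a noise-scale
#' estimate.
#'
#' Implemented with summed-area tables, so cost is O(MN) regardless of the
#' window. Even window sizes are centred with the extra row/column toward
#' larger indices.
#'
#' @param img GrayImage or numeric matrix.
#' @param window integer pair (rows, cols); \code{NULL} means half the image.
#' @return list with \code{epsilon}, \code{m}, \code{n}.
#' @examples
#' localStdEpsilon(matrix(0.5, 8, 8))$epsilon   # 0: constant image
#' @export
localStdEpsilon <- function(img, window = NULL) {
  p <- imgPixels(img)
  M <- nrow(p); N <- ncol(p)
  if (M < 1 || N < 1) stop("empty image")
  if (is.null(window)) window <- c(round(0.5 * M), round(0.5 * N))
  m <- max(1L, as.integer(window[1])); n <- max(1L, as.integer(window[2]))
  mx <- max(p)
  if (mx == 0 || mx == min(p)) return(list(epsilon = 0, m = m, n = n))
  # window centred at (x, y): rows x - floor((m-1)/2) .. x + ceiling((m-1)/2)
  up <- floor((m - 1) / 2); dn <- m - 1L - up
  lf <- floor((n - 1) / 2); rt <- n - 1L - lf
  # summed-area tables with a zero first row/col
  cumsum2d <- function(x) {
    for (j in seq_len(ncol(x))) x[, j] <- cumsum(x[, j])
    for (i in seq_len(nrow(x))) x[i, ] <- cumsum(x[i, ])
    x
  }
  S  <- matrix(0, M + 1L, N + 1L)
  S2 <- matrix(0, M + 1L, N + 1L)
  S[-1, -1]  <- cumsum2d(p)
  S2[-1, -1] <- cumsum2d(p * p)
  r1 <- pmax(seq_len(M) - up, 1L); r2 <- pmin(seq_len(M) + dn, M)
  c1 <- pmax(seq_len(N) - lf, 1L); c2 <- pmin(seq_len(N) + rt, N)
  cnt <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  boxSum <- function(T) {
    T[r2 + 1L, c2 + 1L] - T[r1, c2 + 1L] - T[r2 + 1L, c1] + T[r1, c1]
  }
  s <- boxSum(S); s2 <- boxSum(S2)
  v <- pmax(s2 / cnt - (s / cnt)^2, 0)
  v[v < 1e-13 * mx^2] <- 0   # summed-area float residue on flat windows
  eps <- mean(sqrt(v)) / mx
  list(epsilon = eps, m = m, n = n)
}

#' Histogram-valley threshold on the 8-bit scale
#'
#' Builds a 256-bin histogram of the image on the 8-bit scale, smooths it
#' with a centred 5-bin moving average, and returns the location of the
#' minimum within \code{range8} (inclusive), divided by 255, as a threshold
#' in \[0, 1\]. Ties break to the lowest bin index. If the histogram is zero
#' or monotone across the range (no interior valley information), the
#' midpoint of \code{range8} is returned.
#'
#' @param img GrayImage or numeric matrix in \[0, 1\].
#' @param range8 integer pair within \[0, 255\], e.g. \code{c(130, 170)}.
#' @return threshold in \[0, 1\].
#' @export
histogramValleyThreshold <- function(img, range8 = c(130L, 170L)) {
  p <- imgPixels(img)
  r <- as.integer(range8)
  if (length(r) != 2L || r[1] < 0L || r[2] > 255L || r[1] > r[2])
    stop("range8 must be an increasing pair within [0, 255]")
  bins <- pmin(pmax(floor(p * 255 + 0.5), 0), 255)
  h <- tabulate(bins + 1L, nbins = 256L)
  # centred 5-bin moving average, edges clipped
  hs <- vapply(seq_len(256L), function(i) {
    mean(h[max(1L, i - 2L):min(256L, i + 2L)])
  }, numeric(1))
  win <- hs[(r[1] + 1L):(r[2] + 1L)]
  mid <- (r[1] + r[2]) / 2 / 255
  if (all(win == 0)) return(mid)
  d <- diff(win)
  if (all(d >= 0) || all(d <= 0)) return(mid)  # monotone: no valley
  idx <- which.min(win)  # which.min takes the lowest index on ties
  (r[1] + idx - 1L) / 255
}

#' Adaptive structuring-element size
#'
#' The structuring-element size used throughout the heuristic stage:
#' \code{round(min(M, N) * eps * c)}, floored at 1, where \code{eps} is the
#' local-deviation statistic of the image the operation runs on and \code{c}
#' a stage-specific constant. Sizes therefore scale with both image
#' resolution and image statistics.
#'
#' @param M,N image dimensions.
#' @param eps adaptive scale statistic (>= 0).
#' @param c positive stage constant.
#' @return integer size >= 1.
#' @examples
#' adaptiveSeSize(1024, 1024, 0.01, 6)   # 61
#' @export
adaptiveSeSize <- function(M, N, eps, c) {
  if (eps < 0 || c <= 0) stop("require eps >= 0 and c > 0")
  max(1L, as.integer(round(min(M, N) * eps * c)))
}
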
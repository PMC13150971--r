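# Contrast-limited adaptive histogram equalisation with a uniform or
# Rayleigh target distribution (MATLAB-style normalised clip limit in
# [0, 1]: the per-bin ceiling is clip * tile pixel count, redistributed
# excess included). Tile mappings are blended by bilinear interpolation
# between tile centres; a 1 x 1 grid degenerates to global equalisation.

.tileEdges <- function(M, k) floor(seq(0, M, length.out = k + 1))

.claheLut <- function(vals, bins, clipNorm, dist, alpha) {
  b <- pmin(floor(vals * bins), bins - 1L)
  h <- tabulate(b + 1L, nbins = bins)
  total <- sum(h)
  clip <- clipNorm * total
  if (clip > 0 && clip < total) {
    for (it in 1:16) {
      over <- h > clip
      if (!any(over)) break
      excess <- sum(h[over] - clip)
      h[over] <- clip
      h <- h + excess / bins
    }
  }
  u <- cumsum(h) / sum(h)
  if (dist == "uniform") {
    u
  } else {
    fmax <- 1 - exp(-1 / (2 * alpha^2))
    alpha * sqrt(2 * log(1 / (1 - u * fmax)))
  }
}

#' CLAHE with uniform or Rayleigh target distribution
#'
#' Tile-based histogram equalisation with clip-limit redistribution. Each
#' tile's clipped histogram defines a mapping whose target cumulative
#' distribution is uniform or Rayleigh with scale \code{alpha} (truncated
#' and rescaled so the output covers \[0, 1\]); per-pixel output blends the
#' four neighbouring tile mappings bilinearly. A globally constant image is
#' returned unchanged.
#'
#' @param img GrayImage or numeric matrix in \[0, 1\].
#' @param tiles integer pair, tile grid (rows, cols), each >= 1.
#' @param clip normalised clip limit in (0, 1\]; 1 disables clipping.
#' @param dist "uniform" or "rayleigh".
#' @param bins histogram bins (>= 2).
#' @param alpha Rayleigh scale; required iff \code{dist == "rayleigh"}.
#' @return numeric matrix in \[0, 1\].
#' @export
claheEnhance <- function(img, tiles = c(8L, 8L), clip = 0.01,
                         dist = c("uniform", "rayleigh"), bins = 256L,
                         alpha = NULL) {
  dist <- match.arg(dist)
  p <- imgPixels(img)
  if (dist == "rayleigh" && is.null(alpha)) stop("alpha required for rayleigh")
  if (bins < 2L) stop("bins must be >= 2")
  tr <- max(1L, as.integer(tiles[1])); tc <- max(1L, as.integer(tiles[2]))
  M <- nrow(p); N <- ncol(p)
  if (max(p) == min(p)) return(p)
  re <- .tileEdges(M, tr); ce <- .tileEdges(N, tc)
  lut <- array(0, dim = c(tr, tc, bins))
  for (i in seq_len(tr)) for (j in seq_len(tc)) {
    v <- p[(re[i] + 1):re[i + 1], (ce[j] + 1):ce[j + 1]]
    lut[i, j, ] <- .claheLut(as.numeric(v), bins, clip, dist, alpha)
  }
  binIdx <- pmin(floor(p * bins), bins - 1L) + 1L
  interp1 <- function(pos, edges, k) {
    centers <- (edges[-length(edges)] + 1 + edges[-1]) / 2
    if (k == 1L) return(list(lo = rep(1L, length(pos)), hi = rep(1L, length(pos)),
      w = rep(0, length(pos))))
    lo <- findInterval(pos, centers)
    lo <- pmin(pmax(lo, 1L), k - 1L)
    w <- (pos - centers[lo]) / (centers[lo + 1L] - centers[lo])
    w <- pmin(pmax(w, 0), 1)
    list(lo = lo, hi = lo + 1L, w = w)
  }
  ri <- interp1(seq_len(M), re, tr)
  ci <- interp1(seq_len(N), ce, tc)
  rl <- matrix(ri$lo, M, N); rh <- matrix(ri$hi, M, N); rw <- matrix(ri$w, M, N)
  cl <- matrix(ci$lo, M, N, byrow = TRUE); ch <- matrix(ci$hi, M, N, byrow = TRUE)
  cw <- matrix(ci$w, M, N, byrow = TRUE)
  g <- function(tri, tcj) lut[cbind(as.vector(tri), as.vector(tcj), as.vector(binIdx))]
  out <- (1 - rw) * (1 - cw) * g(rl, cl) + (1 - rw) * cw * g(rl, ch) +
         rw * (1 - cw) * g(rh, cl) + rw * cw * g(rh, ch)
  clamp01(matrix(out, M, N))
}
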
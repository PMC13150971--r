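# Stage 1, step 3: spine modelling and removal. A vertical band at the
# centroid of the lung hull localises the spine; bone-tissue Canny edges,
# skeletonised and intersected with the band, are summarised per row and
# fitted with a smoothing spline; the rasterised, thickened spline removes
# whole paraspinal edge components from the lung representation.

#' Vertical spine band at the hull centroid
#'
#' Band of total width \code{2 * (bandFrac * w)} centred on the centroid
#' column of \code{hullC1}, where \code{w} is the width of the hull's
#' bounding box; the band spans all rows and is clipped to the image.
#'
#' @param hullC1 convex hull of the refined lung ROI.
#' @param bandFrac half-width as a fraction of the hull width (default 0.15).
#' @return logical band mask (empty, with warning, for an empty hull).
#' @export
spineBand <- function(hullC1, bandFrac = 0.15) {
  .checkMask(hullC1, "hullC1")
  if (!any(hullC1)) { warning("empty hull: empty spine band"); return(hullC1) }
  idx <- which(hullC1, arr.ind = TRUE)
  w <- diff(range(idx[, 2])) + 1L
  ccol <- mean(idx[, 2])
  lo <- as.integer(round(ccol - bandFrac * w))
  hi <- lo + as.integer(round(2 * bandFrac * w)) - 1L
  lo <- max(1L, lo); hi <- min(ncol(hullC1), hi)
  out <- matrix(FALSE, nrow(hullC1), ncol(hullC1))
  if (hi >= lo) out[, lo:hi] <- TRUE
  out
}

#' Bone-tissue edge extraction
#'
#' Rayleigh CLAHE (clip 1, alpha 0.2) and a \[0.4, 1\] stretch isolate the
#' bright bone intensities; Canny with thresholds (eps, 2) at variance
#' \code{min(M, N) * eps * 0.67} extracts the bone edges \code{X0}, which
#' are closed with the adaptive element (constant 1) and skeletonised into
#' \code{X1}.
#'
#' @param Ic preconditioned image.
#' @param epsC adaptive scale statistic of \code{Ic}.
#' @param params heuristic parameters.
#' @return list with \code{X0}, \code{X1}.
#' @export
boneEdges <- function(Ic, epsC, params = heuristicParams()) {
  p <- imgPixels(Ic)
  M <- nrow(p); N <- ncol(p)
  cl <- params$claheBone
  E <- claheEnhance(p, tiles = cl$tiles, clip = cl$clip, dist = "rayleigh",
    bins = cl$bins, alpha = cl$alpha)
  E <- contrastStretch(E, params$stretchBone[1], params$stretchBone[2])
  X0 <- cannyEdges(E, t1 = epsC, t2 = 2, sigma2 = min(M, N) * epsC * params$cSpineSigma)
  X1 <- skeletonize(.closeMask(X0,
    structElem("disk", adaptiveSeSize(M, N, epsC, params$cX0Close))))
  list(X0 = X0, X1 = X1)
}

#' Spine skeleton inside the band
#'
#' \code{X2 = skeletonize(fillHoles(X1)) & B1 & hullC1}: the medial-axis
#' pixels that fall inside both the spine band and the lung hull.
#'
#' @param X1 skeletonised bone edges.
#' @param B1 spine band.
#' @param hullC1 lung hull.
#' @return logical \code{X2}.
#' @export
spineSkeleton <- function(X1, B1, hullC1) {
  .checkMask(X1, "X1"); .sameShape(X1, B1); .sameShape(X1, hullC1)
  skeletonize(fillHoles(X1)) & B1 & hullC1
}

#' Fit and rasterise the spine spline
#'
#' Per row with skeleton pixels, the mean column is taken; a smoothing cubic
#' spline \code{col = f(row)} is fitted with smoothness chosen so the
#' residual RMS is at most 2 px, rasterised over all image rows (linear
#' extrapolation beyond the fitted span) into \code{X3}, and thickened by a
#' disk of radius half the band width into \code{Xm}. With fewer than 4
#' pixels or rows, the fallback is the band centreline with \code{Xm} the
#' band eroded to half width.
#'
#' @param X2 spine skeleton pixels.
#' @param B1 spine band.
#' @return list with \code{X3}, \code{Xm}, \code{knots} (row, col matrix).
#' @export
fitSpineSpline <- function(X2, B1) {
  .checkMask(X2, "X2"); .sameShape(X2, B1)
  M <- nrow(X2); N <- ncol(X2)
  bandCols <- which(apply(B1, 2, any))
  bandW <- if (length(bandCols)) diff(range(bandCols)) + 1L else 0L
  fallback <- function() {
    X3 <- matrix(FALSE, M, N)
    Xm <- matrix(FALSE, M, N)
    if (bandW > 0) {
      ctr <- as.integer(round(mean(range(bandCols))))
      X3[, ctr] <- TRUE
      q <- as.integer(floor(bandW / 4))
      lo <- max(1L, ctr - q); hi <- min(N, ctr + q)
      Xm[, lo:hi] <- TRUE
    }
    list(X3 = X3, Xm = Xm, knots = matrix(numeric(0), 0, 2))
  }
  idx <- which(X2, arr.ind = TRUE)
  rows <- sort(unique(idx[, 1]))
  if (nrow(idx) < 4L || length(rows) < 4L) return(fallback())
  meanCol <- vapply(rows, function(r) mean(idx[idx[, 1] == r, 2]), numeric(1))
  # robust pass: a stiff initial fit flags rows whose mean column is pulled
  # sideways by ribs or clavicles crossing the band; the smoothing level is
  # then chosen on the remaining rows so their residual RMS is <= 2 px
  fit0 <- stats::smooth.spline(rows, meanCol, df = min(4, length(rows) - 1))
  res0 <- meanCol - stats::predict(fit0, rows)$y
  tol <- max(0.05 * bandW, 5)
  keep <- abs(res0) <= tol
  if (sum(keep) < 4L || length(unique(rows[keep])) < 4L) keep <- rep(TRUE, length(rows))
  rK <- rows[keep]; mK <- meanCol[keep]
  # the spine is a low-curvature, near-vertical curve: flexibility is capped
  # at df 8, and within that cap the smallest df reaching residual RMS <= 2
  # px on the kept rows is used
  fit <- NULL
  for (dfTry in c(4, 6, 8)) {
    fit <- stats::smooth.spline(rK, mK, df = min(dfTry, length(rK) - 1))
    rms <- sqrt(mean((stats::predict(fit, rK)$y - mK)^2))
    if (rms <= 2) break
  }
  colAt <- stats::predict(fit, seq_len(M))$y
  colAt <- pmin(pmax(round(colAt), 1L), N)
  X3 <- matrix(FALSE, M, N)
  X3[cbind(seq_len(M), as.integer(colAt))] <- TRUE
  Xm <- .dilateDisk(X3, max(1L, as.integer(round(0.5 * bandW))))
  list(X3 = X3, Xm = Xm, knots = cbind(row = rows, col = meanCol))
}

#' Remove spine-touching edge components
#'
#' \code{ILX = IF - reconstruct(IF, Xm)}: any edge component of the lung
#' representation that touches the thickened spine model is removed whole.
#'
#' @param IF refined lung LoG edges.
#' @param Xm thickened spine model.
#' @return edge map \code{ILX}.
#' @export
removeSpine <- function(IF, Xm) {
  .checkMask(IF, "IF"); .sameShape(IF, Xm)
  IF & !reconstructComponents(IF, Xm)
}

#' Run the full spine step
#'
#' @param Ic preconditioned image.
#' @param IF refined lung LoG edges.
#' @param hullC1 lung hull.
#' @param epsC adaptive scale statistic of \code{Ic}.
#' @param params heuristic parameters.
#' @return list of artifacts \code{B1}, \code{X0}, \code{X1}, \code{X2},
#'   \code{X3}, \code{Xm}, \code{knots}, \code{ILX}, \code{warnings}.
#' @export
spineStage <- function(Ic, IF, hullC1, epsC, params = heuristicParams()) {
  warns <- character()
  B1 <- withCallingHandlers(spineBand(hullC1, params$bandFrac),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  be <- boneEdges(Ic, epsC, params)
  X2 <- spineSkeleton(be$X1, B1, hullC1)
  sp <- fitSpineSpline(X2, B1)
  ILX <- removeSpine(IF, sp$Xm)
  list(B1 = B1, X0 = be$X0, X1 = be$X1, X2 = X2, X3 = sp$X3, Xm = sp$Xm,
    knots = sp$knots, ILX = ILX, warnings = warns)
}
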
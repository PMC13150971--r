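# Stage 1, step 4: dual Canny extraction, pruning against the spine model
# and a saturation mask, left/right lung separation, and the final
# combination of LoG and Canny regions into the heuristic predicted mask.

#' Dual adaptive Canny edge maps
#'
#' Both variants run on the \[0.4, 0.73\] stretch of the enhanced image.
#' Variant 1 uses thresholds \code{(max(0.01, eps * 10 - 0.4), 2)} at
#' variance \code{min(M, N) * eps}; variant 2 uses \code{(eps, 2)} at
#' variance \code{min(M, N) * eps * 0.7}. The two intensity regimes keep
#' the lung outline detectable in both low-variance and consolidated films.
#'
#' @param Id enhanced image.
#' @param epsD adaptive scale statistic of \code{Id}.
#' @param params heuristic parameters.
#' @return list with \code{canny1}, \code{canny2}.
#' @export
cannyPair <- function(Id, epsD, params = heuristicParams()) {
  p <- imgPixels(Id)
  M <- nrow(p); N <- ncol(p)
  s <- contrastStretch(p, params$stretchCanny[1], params$stretchCanny[2])
  t1a <- max(0.01, epsD * 10 - 0.4)
  c1 <- cannyEdges(s, t1 = t1a, t2 = 2, sigma2 = min(M, N) * epsD * params$cCanny1Sigma)
  c2 <- cannyEdges(s, t1 = epsD, t2 = 2, sigma2 = min(M, N) * epsD * params$cCanny2Sigma)
  list(canny1 = c1, canny2 = c2)
}

#' Extract lung Canny features via the LoG hull
#'
#' \code{XL}: filled convex hull of the spine-removed LoG representation;
#' \code{CF}: components of \code{canny1 | canny2} that intersect \code{XL}.
#'
#' @param canny1,canny2 Canny edge maps.
#' @param ILX spine-removed lung LoG edges.
#' @return list with \code{XL}, \code{CF} (empty, with warning, if
#'   \code{ILX} is empty).
#' @export
extractLungCanny <- function(canny1, canny2, ILX) {
  .checkMask(canny1, "canny1"); .sameShape(canny1, canny2); .sameShape(canny1, ILX)
  if (!any(ILX)) {
    warning("empty LoG representation: no Canny lung features")
    return(list(XL = ILX, CF = ILX))
  }
  XL <- fillHoles(convexHullMask(ILX))
  CF <- reconstructComponents(canny1 | canny2, XL)
  list(XL = XL, CF = CF)
}

#' Prune spine and saturated components from the Canny features
#'
#' Components touching the thickened spine model are removed; a saturation
#' mask (Rayleigh CLAHE, clip 1, alpha 0.7; stretched from \code{0.9} if
#' \code{2 * mean(Id) > 1}, else from \code{clamp(2 * mean(Id) - 1, 0,
#' 0.89)}; binarised at 0.5) then removes components over the spine,
#' ribcage boundary and abdomen.
#'
#' @param CF lung Canny features.
#' @param Xm thickened spine model.
#' @param Id enhanced image.
#' @param params heuristic parameters.
#' @return list with \code{CP}, \code{SM}, \code{ICN}.
#' @export
pruneSpineAndSaturation <- function(CF, Xm, Id, params = heuristicParams()) {
  .checkMask(CF, "CF"); .sameShape(CF, Xm)
  p <- imgPixels(Id)
  CP <- CF & !reconstructComponents(CF, Xm)
  cl <- params$claheSaturation
  E <- claheEnhance(p, tiles = cl$tiles, clip = cl$clip, dist = "rayleigh",
    bins = cl$bins, alpha = cl$alpha)
  mu <- mean(p)
  # 8-bit-scale rule: stretch from 0.9 when 2 * mean exceeds full scale,
  # otherwise from (2 * mean8 - 1) / 255, so the mask keeps only saturated
  # structures in both branches
  lo <- if (2 * mu > 1) 0.9 else min(max((2 * mu * 255 - 1) / 255, 0), 0.99)
  SM <- contrastStretch(E, lo, 1) >= 0.5
  ICN <- CP & !reconstructComponents(CP, SM)
  list(CP = CP, SM = SM, ICN = ICN)
}

.bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(top = min(idx[, 1]), left = min(idx[, 2]),
    bottom = max(idx[, 1]), right = max(idx[, 2]))
}

#' Separate and refine the left and right lung representations
#'
#' The complement of the spine model splits the frame into lateral segments;
#' the two largest become the side seeds (left = smaller mean column; if the
#' complement does not split, the fallback splits at the vertical midline).
#' Each side's Canny components are dilated (adaptive to the hull height,
#' constant 0.006), reduced to the two largest components, hulled and used
#' to reconstruct the LoG representation; the per-side results are closed
#' (constant 0.005) and dilated (constant 0.03), ORed and hole-filled into
#' the minimal lung representation \code{CM}.
#'
#' @param ICN pruned Canny features.
#' @param Xm thickened spine model.
#' @param ILX spine-removed lung LoG edges.
#' @param XL filled hull of \code{ILX}.
#' @param params heuristic parameters.
#' @return list with \code{LS}, \code{RS}, \code{LeftL}, \code{RightL},
#'   \code{Lp}, \code{Rp}, \code{CM}, \code{ht}, \code{warnings}.
#' @export
separateLungs <- function(ICN, Xm, ILX, XL, params = heuristicParams()) {
  .checkMask(ICN, "ICN"); .sameShape(ICN, Xm); .sameShape(ICN, ILX)
  M <- nrow(ICN); N <- ncol(ICN)
  warns <- character()
  empty <- ICN & FALSE
  comp <- !Xm
  L <- labelComponents(comp, 8L)
  nl <- max(L)
  if (nl >= 2L) {
    areas <- tabulate(L[L > 0L])
    big <- order(areas, decreasing = TRUE)[1:2]
    segA <- L == big[1]; segB <- L == big[2]
  } else {
    warns <- c(warns, "spine model does not split the frame: midline fallback")
    half <- matrix(FALSE, M, N); half[, seq_len(floor(N / 2))] <- TRUE
    segA <- half & comp; segB <- (!half) & comp
  }
  meanColOf <- function(m) if (any(m)) mean(which(m, arr.ind = TRUE)[, 2]) else Inf
  if (meanColOf(segA) <= meanColOf(segB)) { LS <- segA; RS <- segB }
  else { LS <- segB; RS <- segA }
  LeftL <- reconstructComponents(ICN, LS)
  RightL <- reconstructComponents(ICN, RS)
  ht <- if (any(XL)) {
    bb <- .bbox(XL); as.integer(bb["bottom"] - bb["top"] + 1L)
  } else 0L
  dDil <- max(1L, as.integer(round(ht * params$cSideDilate)))
  dClose <- max(1L, as.integer(round(ht * params$cSideClose)))
  dGrow <- max(1L, as.integer(round(ht * params$cSideGrow)))
  refineSide <- function(sideL) {
    if (!any(sideL)) return(empty)
    sideC <- .dilateDisk(sideL, dDil)
    kept <- largestComponents(sideC, 2L)
    hull <- convexHullMask(kept)
    p0 <- reconstructComponents(ILX, hull)
    if (!any(p0)) return(empty)
    .dilateDisk(.closeMask(p0, structElem("disk", dClose)), dGrow)
  }
  Lp <- refineSide(LeftL)
  Rp <- refineSide(RightL)
  if (!any(Lp) && !any(Rp)) {
    warns <- c(warns, "no lung Canny representation on either side")
    CM <- empty
  } else {
    if (!any(Lp) || !any(Rp))
      warns <- c(warns, "one lung side empty: using the other side only")
    CM <- fillHoles(Lp | Rp)
  }
  list(LS = LS, RS = RS, LeftL = LeftL, RightL = RightL, Lp = Lp, Rp = Rp,
    CM = CM, ht = ht, warnings = warns)
}

#' Combine LoG and Canny regions into the final heuristic mask
#'
#' \code{IX = reconstruct(ILX, CM)}; \code{ML} is its filled convex hull.
#' The bounding boxes of the two lung components of \code{CM} define a
#' four-vertex abdominal polygon which is subtracted from \code{ML}; the
#' remainder ORed with \code{CM} and hole-filled is the predicted lung-field
#' mask. With an empty \code{CM}, the fallback is the filled LoG hull
#' intersected with the ribcage mask.
#'
#' @param ILX spine-removed lung LoG edges.
#' @param CM minimal Canny lung representation.
#' @param XL filled LoG hull (fallback).
#' @param MR ribcage mask (fallback).
#' @return list with \code{IX}, \code{ML}, \code{T1poly} (vertex matrix),
#'   \code{T1}, \code{P1}, \code{LFfinal}, \code{warnings}.
#' @export
combineRois <- function(ILX, CM, XL = NULL, MR = NULL) {
  .checkMask(ILX, "ILX"); .sameShape(ILX, CM)
  M <- nrow(ILX); N <- ncol(ILX)
  empty <- ILX & FALSE
  warns <- character()
  if (!any(CM)) {
    warns <- c(warns, "empty minimal representation: hull-ribcage fallback")
    LFfinal <- if (!is.null(XL) && !is.null(MR)) XL & MR else empty
    return(list(IX = empty, ML = empty, T1poly = matrix(numeric(0), 0, 2),
      T1 = empty, P1 = empty, LFfinal = LFfinal, warnings = warns))
  }
  IX <- reconstructComponents(ILX, CM)
  ML <- fillHoles(convexHullMask(if (any(IX)) IX else CM))
  comps <- labelComponents(CM, 8L)
  ncomp <- max(comps)
  if (ncomp >= 2L) {
    areas <- tabulate(comps[comps > 0L])
    big <- order(areas, decreasing = TRUE)[1:2]
    mcol <- vapply(big, function(b) mean(which(comps == b, arr.ind = TRUE)[, 2]),
      numeric(1))
    leftB <- .bbox(comps == big[which.min(mcol)])
    rightB <- .bbox(comps == big[which.max(mcol)])
  } else {
    leftB <- rightB <- .bbox(CM)
  }
  TLx <- leftB["left"];  TLy <- leftB["top"]
  BLx <- leftB["right"]; BLy <- leftB["bottom"]
  TRx <- rightB["left"];  TRy <- rightB["top"]
  BRx <- rightB["right"]; BRy <- rightB["bottom"]
  verts <- rbind(
    c(BRx, TRy + (BRy - TRy) / 2),
    c(TLx, TLy + (BLy - TLy) / 2),
    c(BLx, BLy),
    c(TRx, BRy))
  colnames(verts) <- c("x", "y")
  rr <- range(verts[, 2]); cc <- range(verts[, 1])
  r1 <- max(1L, floor(rr[1])); r2 <- min(M, ceiling(rr[2]))
  c1 <- max(1L, floor(cc[1])); c2 <- min(N, ceiling(cc[2]))
  T1 <- matrix(FALSE, M, N)
  if (r2 >= r1 && c2 >= c1) {
    py <- rep(r1:r2, times = c2 - c1 + 1L)
    px <- rep(c1:c2, each = r2 - r1 + 1L)
    T1[r1:r2, c1:c2] <- matrix(.pointInPoly(px, py, verts[, 1], verts[, 2]),
      nrow = r2 - r1 + 1L)
  }
  P1 <- ML & !T1
  LFfinal <- fillHoles(P1 | CM)
  list(IX = IX, ML = ML, T1poly = verts, T1 = T1, P1 = P1,
    LFfinal = LFfinal, warnings = warns)
}
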
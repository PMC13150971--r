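# Stage 1, step 2: contrast conditioning, LoG edge detection, boundary
# subtraction, ribcage/shoulder masking and ROI refinement. The LoG
# zero-crossings trace the lung fields as closed contours; reconstruction
# against the ribcage mask MR keeps contours inside the chest, and the
# shoulder mask MS removes contours that belong to the shoulder girdle.

#' Precondition the radiograph for LoG detection
#'
#' CLAHE (5 x 5 tiles, uniform target, clip 0.001, 256 bins) followed by a
#' 3 x 3 median filter (impulse noise) and a 3 x 3 min filter, which widens
#' the dark lung fields the LoG step must outline.
#'
#' @param Io working-resolution radiograph.
#' @param params heuristic parameters.
#' @return matrix \code{Ic}.
#' @export
preconditionLog <- function(Io, params = heuristicParams()) {
  p <- imgPixels(Io)
  cl <- params$claheLog
  e <- claheEnhance(p, tiles = cl$tiles, clip = cl$clip, dist = "uniform",
    bins = cl$bins)
  .min3x3(.median3x3(e))
}

#' Rayleigh-CLAHE enhancement
#'
#' Contrast stretch to \[0.05, 0.95\] then CLAHE with a Rayleigh target
#' (5 x 5 tiles, clip 0.005, alpha 0.7): lifts mid-dark lung texture while
#' compressing saturated bone.
#'
#' @param Ic preconditioned image.
#' @param params heuristic parameters.
#' @return matrix \code{Id}.
#' @export
enhanceRayleigh <- function(Ic, params = heuristicParams()) {
  cl <- params$claheRayleigh
  s <- contrastStretch(Ic, params$stretchLog[1], params$stretchLog[2])
  claheEnhance(s, tiles = cl$tiles, clip = cl$clip, dist = "rayleigh",
    bins = cl$bins, alpha = cl$alpha)
}

#' Adaptive LoG edge extraction
#'
#' Variance \code{sigma2 = min(M, N) * eps * c} with \code{c} the LoG scale
#' constant (default 0.6), so detection scale follows both resolution and
#' image statistics.
#'
#' @param Id enhanced image.
#' @param epsC adaptive scale statistic of the preconditioned image.
#' @param c scale constant.
#' @return list with \code{IL} (edges), \code{sigma2}, \code{n}.
#' @export
logStageEdges <- function(Id, epsC, c = 0.6) {
  p <- imgPixels(Id)
  sigma2 <- min(dim(p)) * epsC * c
  r <- logEdgeDetect(p, sigma2)
  list(IL = r$edges, sigma2 = r$sigma2, n = r$n)
}

#' Subtract the body boundary from the LoG edges
#'
#' Pixelwise removal \code{IL & !Mb}: disconnects contours that cross the
#' body outline so that body-boundary edges fall apart into removable
#' components.
#'
#' @param IL LoG edge map.
#' @param Mb dilated body-boundary band.
#' @return edge map \code{L1}.
#' @export
subtractBoundary <- function(IL, Mb) {
  .checkMask(IL, "IL"); .checkMask(Mb, "Mb"); .sameShape(IL, Mb)
  IL & !Mb
}

#' Ribcage and shoulder masks
#'
#' \code{MR}: the body blob closed with a disk of size
#' \code{round(min(M, N) * 0.7)} then eroded with the adaptive element
#' (constant 6) -- expected to encompass the ribcage. \code{MS}: the
#' complement of \code{MR} restricted to the upper half of the rows,
#' dilated with the adaptive element (constant 0.05) -- the shoulder
#' region.
#'
#' @param Ib body blob.
#' @param epsC adaptive scale statistic.
#' @param params heuristic parameters.
#' @return list with \code{MR}, \code{MS} (possibly empty, with warning).
#' @export
buildRegionMasks <- function(Ib, epsC, params = heuristicParams()) {
  .checkMask(Ib, "Ib")
  M <- nrow(Ib); N <- ncol(Ib)
  if (!any(Ib)) {
    warning("empty body blob: empty region masks")
    return(list(MR = Ib, MS = Ib))
  }
  closeN <- max(1L, as.integer(round(min(M, N) * params$mrCloseFrac)))
  MR <- .closeMask(Ib, structElem("disk", closeN))
  MR <- .erodeDisk(MR, adaptiveSeSize(M, N, epsC, params$cMrErode))
  upper <- matrix(FALSE, M, N)
  upper[seq_len(floor(M / 2)), ] <- TRUE
  MSpre <- upper & !MR
  MS <- .dilateDisk(MSpre, adaptiveSeSize(M, N, epsC, params$cMsDilate))
  list(MR = MR, MS = MS)
}

#' Extract the lung LoG representation
#'
#' Removes whole edge components that touch the shoulder mask, then keeps
#' the components that intersect the ribcage mask.
#'
#' @param L1 boundary-subtracted LoG edges.
#' @param MR,MS region masks.
#' @return list with \code{IR} and \code{LF0}.
#' @export
extractLungLog <- function(L1, MR, MS) {
  .checkMask(L1, "L1"); .sameShape(L1, MR); .sameShape(L1, MS)
  IR <- L1 & !reconstructComponents(L1, MS)
  LF0 <- reconstructComponents(IR, MR)
  list(IR = IR, LF0 = LF0)
}

#' Refine the LoG region of interest
#'
#' Rebuilds edge context around the initial lung contours: reconstruct all
#' of \code{L1} touching the convex hull of \code{LF0}; dilate, hole-fill
#' and close (adaptive element, constant 1.5) into \code{S1}; open into
#' \code{S2}; keep the parts reconstructable from an eroded ribcage mask
#' (constant 3) as \code{S3}; hull \code{S3} into \code{hullC1}; and
#' reconstruct \code{LF0} from the eroded hull (constant 2) into \code{IF}.
#'
#' @param LF0 initial lung LoG edges.
#' @param L1 boundary-subtracted LoG edges.
#' @param MR ribcage mask.
#' @param epsC adaptive scale statistic.
#' @param params heuristic parameters.
#' @return list with \code{S1}, \code{S2}, \code{S3}, \code{hullC1},
#'   \code{IF}.
#' @export
refineRoi <- function(LF0, L1, MR, epsC, params = heuristicParams()) {
  .checkMask(LF0, "LF0"); .sameShape(LF0, L1)
  M <- nrow(LF0); N <- ncol(LF0)
  empty <- LF0 & FALSE
  if (!any(LF0)) {
    warning("empty lung LoG representation: ROI refinement skipped")
    return(list(S1 = empty, S2 = empty, S3 = empty, hullC1 = empty,
      IF = empty))
  }
  se15 <- structElem("disk", adaptiveSeSize(M, N, epsC, params$cS1))
  rec <- reconstructComponents(L1, convexHullMask(LF0))
  S1 <- .closeMask(fillHoles(.dilateDisk(rec, se15$n)), se15)
  S2 <- .openMask(S1, se15)
  seedMr <- .erodeDisk(MR, adaptiveSeSize(M, N, epsC, params$cS3))
  S3 <- reconstructComponents(S2, seedMr)
  hullC1 <- convexHullMask(S3)
  IF <- reconstructComponents(LF0,
    .erodeDisk(hullC1, adaptiveSeSize(M, N, epsC, params$cHullErode)))
  list(S1 = S1, S2 = S2, S3 = S3, hullC1 = hullC1, IF = IF)
}
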
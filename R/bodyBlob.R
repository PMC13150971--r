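# Stage 1, step 1: body-blob detection. The radiograph is rescaled to a
# fixed working width, log-enhanced and stretched, thresholded at a
# histogram valley on the 8-bit scale, and the binarisation is cleaned into
# a single body blob whose dilated boundary is used downstream to disconnect
# edge contours that cross the body outline.

#' Rescale a radiograph to the working width
#'
#' Output has exactly \code{width} columns; rows are
#' \code{round(width * M / N)} so the aspect ratio is preserved. Bilinear
#' interpolation; values remain in \[0, 1\].
#'
#' @param raw GrayImage or numeric matrix.
#' @param width target column count (default 1024).
#' @return numeric matrix.
#' @export
rescaleInput <- function(raw, width = 1024L) {
  p <- imgPixels(raw)
  M <- nrow(p); N <- ncol(p)
  if (N == width) return(p)
  rows <- as.integer(round(width * M / N))
  out <- EBImage::resize(p, w = rows, h = width)  # first margin = rows
  clamp01(matrix(as.numeric(out), rows, width))
}

#' Log-transform and full-range stretch of the input radiograph
#'
#' Computes the adaptive scale statistic on the input, applies
#' \code{log(Io + eps)} to lift the dark background and lung fields, min-max
#' normalises the log image and stretches it across the full \[0, 1\] range.
#' A constant input is returned unchanged with a warning flag.
#'
#' @param Io GrayImage or matrix in \[0, 1\].
#' @param epsWindow window for \code{\link{localStdEpsilon}} (NULL = half
#'   image).
#' @return list with \code{Ip}, \code{eps} (the EpsilonStats list) and
#'   logical \code{degenerate}.
#' @export
enhanceBody <- function(Io, epsWindow = NULL) {
  p <- imgPixels(Io)
  eps <- localStdEpsilon(p, epsWindow)
  if (max(p) == min(p)) {
    return(list(Ip = p, eps = eps, degenerate = TRUE))
  }
  lg <- log(p + max(eps$epsilon, 1e-6))
  lg <- (lg - min(lg)) / (max(lg) - min(lg))
  list(Ip = contrastStretch(lg, 0, 1), eps = eps, degenerate = FALSE)
}

#' Threshold the enhanced image at a histogram valley
#'
#' The body is bright in a chest radiograph, so the foreground is
#' \code{Ip >= Tb} with \code{Tb} the histogram-valley threshold within the
#' 8-bit window \code{range8}.
#'
#' @param Ip enhanced image matrix.
#' @param range8 8-bit search window (default \code{c(130, 170)}).
#' @return list with \code{Ir} (logical mask) and \code{Tb}.
#' @export
binarizeBody <- function(Ip, range8 = c(130L, 170L)) {
  Tb <- histogramValleyThreshold(Ip, range8)
  list(Ir = imgPixels(Ip) >= Tb, Tb = Tb)
}

#' Refine the raw binarisation into a single body blob
#'
#' Spur pruning (3 passes), isolated-pixel cleaning, closing with a disk of
#' size \code{round(min(M, N) * closeFrac)}, hole filling, and retention of
#' the largest 8-connected component. Removes overexposure labels and text
#' artifacts, which are never the largest region.
#'
#' @param Ir raw binary mask.
#' @param closeFrac closing-disk size as a fraction of \code{min(M, N)}.
#' @return logical body mask (empty, with a warning, on empty input).
#' @export
refineBlob <- function(Ir, closeFrac = 0.1) {
  .checkMask(Ir, "Ir")
  if (!any(Ir)) { warning("empty binarisation: empty body blob"); return(Ir) }
  m <- pruneSpurs(Ir, 3L)
  m <- cleanIsolated(m)
  n <- max(1L, as.integer(round(min(dim(Ir)) * closeFrac)))
  m <- .closeMask(m, structElem("disk", n))
  m <- fillHoles(m)
  largestComponents(m, 1L)
}

#' Dilated boundary of the body blob
#'
#' The one-pixel boundary \code{Ib XOR erode(Ib, 3x3)} dilated by a 3x3
#' square of ones: a width-3 band along the blob outline.
#'
#' @param Ib body blob mask.
#' @return logical boundary band (empty for empty input).
#' @export
blobBoundary <- function(Ib) {
  .checkMask(Ib, "Ib")
  if (!any(Ib)) return(Ib)
  ring <- xor(Ib, .erodeSquare(Ib, 3L))
  .dilateSquare(ring, 3L)
}

#' Run the full body-blob step
#'
#' @param Io working-resolution radiograph (matrix or GrayImage).
#' @param params \code{\link{heuristicParams}} list.
#' @return list of artifacts: \code{Io}, \code{Ip}, \code{Tb}, \code{Ir},
#'   \code{Ib}, \code{Mb}, \code{epsO}, \code{warnings}.
#' @export
bodyBlobStage <- function(Io, params = heuristicParams()) {
  p <- imgPixels(Io)
  warns <- character()
  enh <- enhanceBody(p, params$epsWindow)
  if (enh$degenerate) warns <- c(warns, "constant input image")
  bz <- binarizeBody(enh$Ip, params$valleyRange8)
  Ib <- withCallingHandlers(
    refineBlob(bz$Ir, params$blobCloseFrac),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  Mb <- blobBoundary(Ib)
  list(Io = p, Ip = enh$Ip, Tb = bz$Tb, Ir = bz$Ir, Ib = Ib, Mb = Mb,
    epsO = enh$eps, warnings = warns)
}
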
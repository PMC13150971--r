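# Stage-1 orchestration: parameters, image I/O and the pipeline driver that
# ties the body-blob, LoG, spine and Canny steps into the five-plane channel
# set. Degenerate content produces warnings and empty planes, never errors:
# batch extraction must not halt on one bad film.

#' Heuristic-stage parameters
#'
#' Every constant of the edge-extraction stage in one serialisable object,
#' so parameter ablations are configuration rather than code edits. The
#' adaptive structuring-element constants multiply
#' \code{min(M, N) * eps}; CLAHE parameter sets are given per use site.
#' \code{epsWindow} is the window of \code{\link{localStdEpsilon}} used by
#' the pipeline: the default 3 x 3 estimates the noise-scale deviation,
#' which keeps the derived filter variances and element sizes at the scale
#' the stage constants assume.
#'
#' @param inputWidth working width in columns (default 1024).
#' @param epsWindow integer pair for the adaptive statistic (default 3 x 3).
#' @param ... overrides for any listed constant.
#' @return named list of class \code{HeuristicParams}.
#' @export
heuristicParams <- function(inputWidth = 1024L, epsWindow = c(3L, 3L), ...) {
  p <- list(
    inputWidth = as.integer(inputWidth),
    epsWindow = epsWindow,
    valleyRange8 = c(130L, 170L),
    blobCloseFrac = 0.1,
    mrCloseFrac = 0.7,
    cMrErode = 6,
    cMsDilate = 0.05,
    cLog = 0.6,
    cS1 = 1.5,
    cS3 = 3,
    cHullErode = 2,
    cX0Close = 1,
    cSpineSigma = 0.67,
    cCanny1Sigma = 1.0,
    cCanny2Sigma = 0.7,
    bandFrac = 0.15,
    cSideDilate = 0.006,
    cSideClose = 0.005,
    cSideGrow = 0.03,
    stretchLog = c(0.05, 0.95),
    stretchBone = c(0.4, 1),
    stretchCanny = c(0.4, 0.73),
    claheLog = list(tiles = c(5L, 5L), clip = 0.001, bins = 256L),
    claheRayleigh = list(tiles = c(5L, 5L), clip = 0.005, bins = 256L, alpha = 0.7),
    claheBone = list(tiles = c(5L, 5L), clip = 1, bins = 256L, alpha = 0.2),
    claheSaturation = list(tiles = c(5L, 5L), clip = 1, bins = 256L, alpha = 0.7)
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  stopifnot(all(vapply(
    p[c("blobCloseFrac", "mrCloseFrac", "cMrErode", "cMsDilate", "cLog",
        "cS1", "cS3", "cHullErode", "cX0Close", "cSpineSigma",
        "cCanny1Sigma", "cCanny2Sigma", "bandFrac", "cSideDilate",
        "cSideClose", "cSideGrow")],
    function(x) is.numeric(x) && x > 0, logical(1))))
  class(p) <- c("HeuristicParams", "list")
  p
}

#' Read a grayscale radiograph from PNG or TIFF
#'
#' 8- or 16-bit grayscale input; RGB files whose channels are identical are
#' accepted as grayscale, genuinely coloured input is rejected. Values are
#' returned in \[0, 1\] with the source depth recorded.
#'
#' @param path file path (.png, .tif, .tiff).
#' @return \linkS4class{GrayImage}.
#' @export
readGrayImage <- function(path) {
  if (!file.exists(path)) stop("cannot read ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    depth <- if (is.null(attr(a, "bitdepth"))) 8L else as.integer(attr(a, "bitdepth"))
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' required")
    a <- tiff::readTIFF(path)
    depth <- if (is.null(attr(a, "bits.per.sample"))) 16L else
      as.integer(attr(a, "bits.per.sample"))
  } else stop("unsupported extension: ", ext)
  if (length(dim(a)) == 3L) {
    ch <- dim(a)[3]
    for (k in seq_len(min(ch, 3L))[-1]) {
      if (max(abs(a[, , 1] - a[, , k])) > 1e-6)
        stop("colour input not supported: ", path)
    }
    a <- a[, , 1]
  }
  if (!depth %in% c(8L, 16L)) depth <- if (depth > 8L) 16L else 8L
  GrayImage(clamp01(a), depth)
}

#' Write a matrix or mask as an 8-bit grayscale PNG
#'
#' @param x numeric matrix in \[0, 1\] or logical mask.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeGrayPng <- function(x, path) {
  m <- imgPixels(x)
  if (is.logical(m)) m <- m * 1
  png::writePNG(clamp01(m), path)
  invisible(path)
}

#' Run the full heuristic stage on one radiograph
#'
#' Executes body-blob detection, LoG edge extraction and pruning, spine
#' modelling and removal, the dual-Canny refinement and the final mask
#' combination, then assembles the five-plane channel set (grayscale,
#' canny variant 1, canny variant 2, pruned LoG, predicted mask) at
#' 256 x 256. Degenerate content degrades to empty planes with warnings
#' collected in the result.
#'
#' @param input file path or \linkS4class{GrayImage}.
#' @param params \code{\link{heuristicParams}}.
#' @param qcDir optional directory; when given, all intermediate masks and
#'   images are written there as PNG for visual QC.
#' @return list with \code{channels} (\linkS4class{ChannelSet}),
#'   \code{artifacts} (all named intermediates), \code{warnings} and
#'   \code{manifest}.
#' @export
runStage1 <- function(input, params = heuristicParams(), qcDir = NULL) {
  img <- if (is.character(input)) readGrayImage(input) else input
  t0 <- proc.time()[["elapsed"]]
  Io <- rescaleInput(img, params$inputWidth)
  M <- nrow(Io); N <- ncol(Io)
  warns <- character()
  grab <- function(x) { warns <<- c(warns, x$warnings); x }

  bb <- grab(bodyBlobStage(Io, params))

  Ic <- preconditionLog(Io, params)
  epsC <- localStdEpsilon(Ic, params$epsWindow)$epsilon
  Id <- enhanceRayleigh(Ic, params)
  le <- logStageEdges(Id, epsC, params$cLog)
  L1 <- subtractBoundary(le$IL, bb$Mb)
  rm1 <- withCallingHandlers(buildRegionMasks(bb$Ib, epsC, params),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  ll <- extractLungLog(L1, rm1$MR, rm1$MS)
  ro <- withCallingHandlers(refineRoi(ll$LF0, L1, rm1$MR, epsC, params),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
    })

  sp <- grab(spineStage(Ic, ro$IF, ro$hullC1, epsC, params))

  epsD <- localStdEpsilon(Id, params$epsWindow)$epsilon
  cp <- cannyPair(Id, epsD, params)
  lc <- withCallingHandlers(extractLungCanny(cp$canny1, cp$canny2, sp$ILX),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  ps <- pruneSpineAndSaturation(lc$CF, sp$Xm, Id, params)
  sl <- grab(separateLungs(ps$ICN, sp$Xm, sp$ILX, lc$XL, params))
  cr <- grab(combineRois(sp$ILX, sl$CM, lc$XL, rm1$MR))

  channels <- buildChannelSet(Io, cp$canny1, cp$canny2, sp$ILX, cr$LFfinal)
  artifacts <- c(
    list(Io = Io, epsC = epsC, epsD = epsD, sigma2Log = le$sigma2,
      Ic = Ic, Id = Id, IL = le$IL, L1 = L1),
    bb[setdiff(names(bb), c("warnings", "Io"))],
    rm1, ll, ro,
    sp[setdiff(names(sp), "warnings")],
    list(canny1 = cp$canny1, canny2 = cp$canny2, XL = lc$XL, CF = lc$CF),
    ps,
    sl[setdiff(names(sl), "warnings")],
    cr[setdiff(names(cr), "warnings")]
  )
  if (!is.null(qcDir)) {
    dir.create(qcDir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(artifacts)) {
      a <- artifacts[[nm]]
      if (is.matrix(a) && (is.logical(a) || is.numeric(a)) && nrow(a) > 1)
        writeGrayPng(a, file.path(qcDir, paste0(nm, ".png")))
    }
  }
  manifest <- list(
    input = if (is.character(input)) input else "<in-memory>",
    dims = c(M, N), params = unclass(params),
    packageVersion = as.character(utils::packageVersion("lungfuse")),
    warnings = warns, elapsed = proc.time()[["elapsed"]] - t0)
  list(channels = channels, artifacts = artifacts, warnings = warns,
    manifest = manifest)
}
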
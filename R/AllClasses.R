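#' @import methods
#' @importFrom stats median quantile rnorm runif sd smooth.spline predict
#' @importFrom utils head tail write.csv
NULL

#' Grayscale image container
#'
#' A 2-D intensity field stored as a numeric matrix with values in \[0, 1\].
#' The bit depth of the source file (8 or 16) is recorded so that rules
#' stated on the 8-bit scale (for example histogram windows such as
#' \[130, 170\]) can be applied consistently regardless of origin.
#'
#' @slot pixels numeric matrix, values in \[0, 1\], at least 8 x 8.
#' @slot sourceDepth integer, 8 or 16, bit depth of the originating file.
#' @export
setClass("GrayImage",
  representation(pixels = "matrix", sourceDepth = "integer"),
  prototype(pixels = matrix(0, 8, 8), sourceDepth = 8L)
)

setValidity("GrayImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) < 8L || ncol(p) < 8L) return("image must be at least 8 x 8")
  if (any(!is.finite(p))) return("pixels must be finite")
  if (min(p) < 0 || max(p) > 1) return("pixels must lie in [0, 1]")
  if (!object@sourceDepth %in% c(8L, 16L)) return("sourceDepth must be 8 or 16")
  TRUE
})

#' Construct a GrayImage
#'
#' @param pixels numeric matrix in \[0, 1\].
#' @param sourceDepth 8 or 16.
#' @return A \linkS4class{GrayImage}.
#' @examples
#' img <- GrayImage(matrix(runif(64), 8, 8))
#' dim(imgPixels(img))
#' @export
GrayImage <- function(pixels, sourceDepth = 8L) {
  new("GrayImage", pixels = pixels, sourceDepth = as.integer(sourceDepth))
}

#' @describeIn GrayImage pixel matrix accessor
#' @param x a GrayImage
#' @export
imgPixels <- function(x) {
  if (is(x, "GrayImage")) x@pixels else x
}

#' @describeIn GrayImage source bit depth accessor
#' @export
sourceDepth <- function(x) x@sourceDepth

setMethod("show", "GrayImage", function(object) {
  p <- object@pixels
  cat(sprintf("GrayImage %d x %d (%d-bit source), range [%.4g, %.4g]\n",
    nrow(p), ncol(p), object@sourceDepth, min(p), max(p)))
})

setMethod("dim", "GrayImage", function(x) dim(x@pixels))

#' Five-plane channel set consumed by the fusion front end
#'
#' Aligned per-image planes: the rescaled input radiograph \code{Io}, the two
#' Canny edge variants \code{cn1} and \code{cn2}, the pruned LoG lung
#' representation \code{log}, and the heuristic predicted lung mask
#' \code{pm}. All planes are 256 x 256 with values in \[0, 1\]; binary planes
#' are stored as \{0, 1\} floats.
#'
#' @slot planes numeric array 256 x 256 x 5 with dimnames
#'   \code{c("Io","cn1","cn2","log","pm")} on the third margin.
#' @export
setClass("ChannelSet", representation(planes = "array"))

setValidity("ChannelSet", function(object) {
  a <- object@planes
  if (length(dim(a)) != 3L) return("planes must be a 3-D array")
  if (!all(dim(a)[1:2] == c(256L, 256L))) return("planes must be 256 x 256")
  if (dim(a)[3] != 5L) return("exactly five planes required")
  if (!identical(dimnames(a)[[3]], c("Io", "cn1", "cn2", "log", "pm")))
    return("plane names must be Io, cn1, cn2, log, pm")
  if (any(!is.finite(a)) || min(a) < 0 || max(a) > 1)
    return("plane values must be finite and in [0, 1]")
  TRUE
})

#' Construct a ChannelSet from five 256 x 256 planes
#'
#' @param Io,cn1,cn2,log,pm numeric 256 x 256 matrices in \[0, 1\]
#'   (logical matrices are cast to \{0, 1\}).
#' @return A \linkS4class{ChannelSet}.
#' @export
ChannelSet <- function(Io, cn1, cn2, log, pm) {
  pl <- lapply(list(Io, cn1, cn2, log, pm), function(m) {
    m <- imgPixels(m)
    if (is.logical(m)) m <- m * 1
    m
  })
  a <- array(unlist(pl), dim = c(dim(pl[[1]]), 5L),
    dimnames = list(NULL, NULL, c("Io", "cn1", "cn2", "log", "pm")))
  new("ChannelSet", planes = a)
}

#' @describeIn ChannelSet names of the five planes
#' @param x a ChannelSet
#' @export
channelNames <- function(x) dimnames(x@planes)[[3]]

#' @describeIn ChannelSet extract one plane as a matrix
#' @param name plane name, one of \code{channelNames(x)}
#' @export
channelPlane <- function(x, name) {
  stopifnot(name %in% channelNames(x))
  x@planes[, , name]
}

#' @describeIn ChannelSet the full 5 x H x W stack (channels-first array)
#' @export
channelStack <- function(x) aperm(x@planes, c(3, 1, 2))

setMethod("show", "ChannelSet", function(object) {
  act <- apply(object@planes, 3, function(m) any(m > 0))
  cat(sprintf("ChannelSet 256 x 256 x 5; nonzero planes: %s\n",
    paste(channelNames(object)[act], collapse = ", ")))
})

#' Learnable 1 x 1 channel-mixer parameters
#'
#' Projects the selected five-plane stack to the three-plane representation
#' consumed by the segmentation network. At initialisation the column acting
#' on the grayscale plane \code{Io} is 1.0 in every output row and all other
#' weights and biases are 0, so the mixer reproduces the grayscale image
#' exactly before any training.
#'
#' @slot weights 3 x 5 numeric matrix (output channels x input planes).
#' @slot bias numeric length-3 vector.
#' @export
setClass("MixerParams", representation(weights = "matrix", bias = "numeric"))

setValidity("MixerParams", function(object) {
  if (!all(dim(object@weights) == c(3L, 5L))) return("weights must be 3 x 5")
  if (length(object@bias) != 3L) return("bias must have length 3")
  if (any(!is.finite(object@weights)) || any(!is.finite(object@bias)))
    return("parameters must be finite")
  TRUE
})

#' Construct mixer parameters
#'
#' @param weights 3 x 5 matrix; default is the identity-preserving
#'   initialisation (Io column = 1, rest 0).
#' @param bias length-3 numeric; default zeros.
#' @return A \linkS4class{MixerParams}.
#' @examples
#' p <- MixerParams()
#' mixerWeights(p)[, 1]   # all 1: Io is passed through
#' @export
MixerParams <- function(weights = NULL, bias = NULL) {
  if (is.null(weights)) {
    weights <- matrix(0, 3, 5)
    weights[, 1] <- 1
  }
  if (is.null(bias)) bias <- numeric(3)
  new("MixerParams", weights = weights, bias = as.numeric(bias))
}

#' @describeIn MixerParams weight matrix accessor
#' @param x a MixerParams
#' @export
mixerWeights <- function(x) x@weights

#' @describeIn MixerParams bias accessor
#' @export
mixerBias <- function(x) x@bias

setMethod("show", "MixerParams", function(object) {
  cat("MixerParams 3 x 5 (+bias); Io column:",
    paste(format(object@weights[, 1], digits = 3), collapse = " "), "\n")
})
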
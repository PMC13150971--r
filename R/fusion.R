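# Early fusion: assemble the five aligned planes, enumerate the 16 channel
# combinations, apply the binary selection mask and project through the
# learnable 1x1 mixer.

.resizePlane <- function(m, size = 256L, nearest = FALSE) {
  if (is.logical(m)) m <- m * 1
  if (all(dim(m) == size)) return(clamp01(m))
  out <- if (nearest) {
    ri <- pmin(pmax(ceiling(seq_len(size) * nrow(m) / size), 1L), nrow(m))
    ci <- pmin(pmax(ceiling(seq_len(size) * ncol(m) / size), 1L), ncol(m))
    m[ri, ci]
  } else {
    matrix(as.numeric(EBImage::resize(m, w = size, h = size)), size, size)
  }
  clamp01(out)
}

#' Assemble the five-plane channel set
#'
#' The grayscale input is resized bilinearly to 256 x 256; the two raw
#' Canny variant edge maps, the pruned LoG lung representation and the
#' heuristic predicted mask are resized nearest-neighbour so they stay
#' binary.
#'
#' @param Io grayscale working image.
#' @param canny1,canny2 Canny variant edge maps.
#' @param ILX pruned LoG lung representation.
#' @param LFfinal heuristic predicted lung mask.
#' @return \linkS4class{ChannelSet}.
#' @export
buildChannelSet <- function(Io, canny1, canny2, ILX, LFfinal) {
  miss <- c(Io = missing(Io), canny1 = missing(canny1),
    canny2 = missing(canny2), ILX = missing(ILX), LFfinal = missing(LFfinal))
  if (any(miss)) stop("missing stage-1 artifact: ",
    paste(names(miss)[miss], collapse = ", "))
  ChannelSet(
    Io = .resizePlane(imgPixels(Io)),
    cn1 = .resizePlane(canny1, nearest = TRUE),
    cn2 = .resizePlane(canny2, nearest = TRUE),
    log = .resizePlane(ILX, nearest = TRUE),
    pm = .resizePlane(LFfinal, nearest = TRUE))
}

#' Enumerate the 16 channel combinations
#'
#' All subsets of the heuristic channels \{cn1, cn2, log, pm\}, each unioned
#' with the always-active grayscale base channel: 2^4 = 16 combinations, in
#' deterministic order (subset size, then lexicographic). Labels follow the
#' \code{"Io_cn2_log_pm"} style.
#'
#' @return data.frame with columns \code{k}, \code{label} and logical
#'   selector columns \code{cn1}, \code{cn2}, \code{log}, \code{pm}.
#' @examples
#' nrow(enumerateCombinations())   # 16
#' @export
enumerateCombinations <- function() {
  H <- c("cn1", "cn2", "log", "pm")
  sel <- expand.grid(rep(list(c(FALSE, TRUE)), 4))
  names(sel) <- H
  size <- rowSums(sel)
  lab <- apply(sel, 1, function(r) paste(c("Io", H[as.logical(r)]), collapse = "_"))
  ord <- order(size, lab)
  sel <- sel[ord, , drop = FALSE]
  out <- cbind(data.frame(k = seq_len(16L), label = lab[ord],
    stringsAsFactors = FALSE), sel)
  rownames(out) <- NULL
  out
}

.selectorVector <- function(combo) {
  if (is.data.frame(combo)) combo <- as.list(combo)
  m <- as.numeric(c(1, combo$cn1, combo$cn2, combo$log, combo$pm))
  if (length(m) != 5L || any(is.na(m))) stop("invalid combination selector")
  m
}

#' Apply the binary channel selection
#'
#' Multiplies each plane of a (5, H, W) stack by its selector entry; the
#' grayscale plane is always kept (its selector is implicitly 1);
#' deselected planes become exactly zero. Idempotent.
#'
#' @param X numeric array (5, H, W) or \linkS4class{ChannelSet}.
#' @param combo one row of \code{\link{enumerateCombinations}} (or a list
#'   with logical \code{cn1}, \code{cn2}, \code{log}, \code{pm}).
#' @return numeric array (5, H, W).
#' @export
applySelection <- function(X, combo) {
  if (is(X, "ChannelSet")) X <- channelStack(X)
  stopifnot(length(dim(X)) == 3L, dim(X)[1] == 5L)
  m <- .selectorVector(combo)
  X * m   # recycles along the first (channel) margin
}

#' Project the selected stack through the 1 x 1 channel mixer
#'
#' Per pixel, \code{Xfused[c] = sum_i w[c, i] * X[i] + b[c]}: a linear map
#' from the five selected planes to a three-plane representation. With the
#' default initialisation every output plane equals the grayscale plane
#' exactly, so an untrained mixer reduces the fusion input to the plain
#' radiograph.
#'
#' @param X numeric array (5, H, W).
#' @param p \linkS4class{MixerParams}.
#' @return numeric array (3, H, W).
#' @export
channelMixer <- function(X, p = MixerParams()) {
  stopifnot(is(p, "MixerParams"))
  if (is(X, "ChannelSet")) X <- channelStack(X)
  d <- dim(X)
  if (length(d) != 3L || d[1] != 5L) stop("X must be a (5, H, W) stack")
  W <- p@weights
  if (!all(dim(W) == c(3L, 5L))) stop("mixer weights must be 3 x 5")
  flat <- matrix(X, nrow = 5L)          # 5 x (H*W)
  out <- W %*% flat + p@bias            # 3 x (H*W), bias recycled by column
  array(out, dim = c(3L, d[2], d[3]))
}
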
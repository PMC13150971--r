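# Binary morphology. Masks are logical matrices; foreground is 8-connected,
# holes are 4-connected. Disk elements of size n are the all-ones disk
# inscribed in an n x n square (effective Euclidean radius (n-1)/2), realised
# through EBImage's exact distance transform so that large adaptive elements
# cost O(MN). Outside the frame counts as background, so erosion insets
# border-touching regions at the image edge.

#' Structuring element descriptor
#'
#' @param kind "disk" or "square".
#' @param n size (diameter for disk, side for square), floored at 1.
#' @return list with \code{kind}, \code{n}.
#' @export
structElem <- function(kind = c("disk", "square"), n) {
  kind <- match.arg(kind)
  list(kind = kind, n = max(1L, as.integer(n)))
}

.diskRadius <- function(n) (n - 1) / 2

.pad <- function(mask, p, value = FALSE) {
  if (p <= 0) return(mask)
  M <- nrow(mask); N <- ncol(mask)
  out <- matrix(value, M + 2 * p, N + 2 * p)
  out[(p + 1):(p + M), (p + 1):(p + N)] <- mask
  out
}

.crop <- function(mask, p, M, N) mask[(p + 1):(p + M), (p + 1):(p + N)]

.distmap <- function(mask) {
  # Euclidean distance of TRUE pixels to the nearest FALSE pixel
  if (!any(mask)) return(matrix(0, nrow(mask), ncol(mask)))
  if (all(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  d <- EBImage::distmap(matrix(as.numeric(mask), nrow(mask)))
  matrix(as.numeric(d), nrow(mask))
}

.dilateDisk <- function(mask, n) {
  r <- .diskRadius(n)
  if (r <= 0 || !any(mask)) return(mask)
  d <- .distmap(!mask)
  mask | (d <= r)
}

.erodeDisk <- function(mask, n) {
  # outside the frame counts as background, so erosion insets at borders
  r <- .diskRadius(n)
  if (r <= 0 || !any(mask)) return(mask)
  p <- as.integer(ceiling(r)) + 1L
  pm <- .pad(mask, p, FALSE)
  d <- .distmap(pm)
  .crop(pm & (d > r), p, nrow(mask), ncol(mask))
}

.dilateSquare <- function(mask, n) {
  if (n <= 1 || !any(mask)) return(mask)
  lf <- floor((n - 1) / 2); rt <- n - 1 - lf
  out <- mask
  acc <- mask
  for (d in seq_len(rt)) { acc <- .shiftZero(acc, 1L, 0L) ; out <- out | acc }
  acc <- mask
  for (d in seq_len(lf)) { acc <- .shiftZero(acc, -1L, 0L); out <- out | acc }
  res <- out
  acc <- out
  for (d in seq_len(rt)) { acc <- .shiftZero(acc, 0L, 1L) ; res <- res | acc }
  acc <- out
  for (d in seq_len(lf)) { acc <- .shiftZero(acc, 0L, -1L); res <- res | acc }
  res
}

.erodeSquare <- function(mask, n) {
  if (n <= 1) return(mask)
  pm <- .pad(mask, n, FALSE)
  .crop(!.dilateSquare(!pm, n), n, nrow(mask), ncol(mask))
}

.applySe <- function(mask, se, what = c("dilate", "erode")) {
  what <- match.arg(what)
  if (se$kind == "disk") {
    if (what == "dilate") .dilateDisk(mask, se$n) else .erodeDisk(mask, se$n)
  } else {
    if (what == "dilate") .dilateSquare(mask, se$n) else .erodeSquare(mask, se$n)
  }
}

.closeMask <- function(mask, se) {
  if (!any(mask)) return(mask)
  p <- if (se$kind == "disk") as.integer(ceiling(.diskRadius(se$n))) + 1L else se$n
  pm <- .pad(mask, p, FALSE)
  pm <- .applySe(pm, se, "dilate")
  if (se$kind == "disk") {
    d <- .distmap(pm)
    pm <- pm & (d > .diskRadius(se$n))
  } else pm <- .erodeSquare(pm, se$n)
  .crop(pm, p, nrow(mask), ncol(mask))
}

.openMask <- function(mask, se) .applySe(.applySe(mask, se, "erode"), se, "dilate")

# ---- connected components ------------------------------------------------

#' Label connected components
#'
#' 4-connected labelling is delegated to \code{EBImage::bwlabel}; 8-connected
#' labels are obtained by merging diagonally adjacent 4-connected labels with
#' a union-find pass, so thin diagonal edge chains stay one component.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8, the foreground convention).
#' @return integer matrix of labels (0 = background).
#' @export
labelComponents <- function(mask, connectivity = 8L) {
  .checkMask(mask)
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  L <- matrix(as.integer(EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask)))),
    nrow(mask))
  if (connectivity == 4L) return(L)
  M <- nrow(L); N <- ncol(L)
  if (M < 2 || N < 2) return(L)
  # diagonal neighbour label pairs
  a1 <- L[-M, -N]; b1 <- L[-1, -1]   # (r,c) vs (r+1,c+1)
  a2 <- L[-1, -N]; b2 <- L[-M, -1]   # (r+1,c) vs (r,c+1)
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  if (nrow(pairs) == 0L) return(L)
  nlab <- max(L)
  parent <- seq_len(nlab)
  findRoot <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  for (i in seq_len(nrow(pairs))) {
    ra <- findRoot(pairs[i, 1]); rb <- findRoot(pairs[i, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nlab), findRoot, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- L
  out[L > 0L] <- dense[L[L > 0L]]
  out
}

#' Morphological reconstruction by component selection
#'
#' Returns the union of the 8-connected components of \code{mask} that
#' intersect \code{seed} -- equivalently, morphological reconstruction by
#' dilation with marker \code{mask & seed} inside \code{mask}. The result is
#' always a subset of \code{mask} and the operation is idempotent.
#'
#' @param mask,seed logical matrices of the same shape.
#' @return logical matrix.
#' @export
reconstructComponents <- function(mask, seed) {
  .checkMask(mask); .checkMask(seed, "seed")
  .sameShape(mask, seed)
  if (!any(mask) || !any(seed)) return(mask & FALSE)
  L <- labelComponents(mask, 8L)
  keep <- unique(L[seed & mask])
  keep <- keep[keep > 0L]
  if (length(keep) == 0L) return(mask & FALSE)
  matrix(L %in% keep, nrow(mask)) & mask
}

#' Fill interior holes of a binary mask
#'
#' Holes are 4-connected background regions that do not touch the image
#' border. Idempotent.
#'
#' @param mask logical matrix.
#' @return logical matrix with holes filled.
#' @export
fillHoles <- function(mask) {
  .checkMask(mask)
  if (!any(mask) || all(mask)) return(mask)
  Lbg <- labelComponents(!mask, 4L)
  border <- unique(c(Lbg[1, ], Lbg[nrow(Lbg), ], Lbg[, 1], Lbg[, ncol(Lbg)]))
  border <- border[border > 0L]
  mask | (Lbg > 0L & !(Lbg %in% border))
}

#' Keep the k largest components
#'
#' @param mask logical matrix.
#' @param k number of 8-connected components to keep (all, if fewer exist).
#' @return logical matrix.
#' @export
largestComponents <- function(mask, k = 1L) {
  .checkMask(mask)
  if (!any(mask)) return(mask)
  L <- labelComponents(mask, 8L)
  areas <- tabulate(L[L > 0L])
  keep <- order(areas, decreasing = TRUE)[seq_len(min(k, length(areas)))]
  matrix(L %in% keep, nrow(mask))
}

.neighborCount <- function(mask) {
  n <- matrix(0L, nrow(mask), ncol(mask))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    n <- n + .shiftZero(mask, dr, dc)
  }
  n
}

#' Remove spur (endpoint) pixels
#'
#' A spur is a foreground pixel with at most one 8-connected foreground
#' neighbour; each iteration removes the current endpoints, shortening open
#' strokes (text, thin artifacts) without touching closed contours.
#'
#' @param mask logical matrix.
#' @param iterations number of removal passes.
#' @return logical matrix.
#' @export
pruneSpurs <- function(mask, iterations = 1L) {
  .checkMask(mask)
  for (i in seq_len(iterations)) {
    if (!any(mask)) break
    nb <- .neighborCount(mask)
    spur <- mask & nb <= 1L
    if (!any(spur)) break
    mask <- mask & !spur
  }
  mask
}

#' Remove isolated single pixels
#' @param mask logical matrix.
#' @return logical matrix without 8-isolated foreground pixels.
#' @export
cleanIsolated <- function(mask) {
  .checkMask(mask)
  if (!any(mask)) return(mask)
  mask & .neighborCount(mask) > 0L
}

#' Filled convex hull of a binary mask
#'
#' Smallest convex region containing all foreground pixels, rasterised by an
#' inclusive point-in-polygon test over pixel centres (boundary pixels
#' count), then unioned with the mask itself. Idempotent.
#'
#' @param mask logical matrix.
#' @return logical matrix.
#' @export
convexHullMask <- function(mask) {
  .checkMask(mask)
  if (!any(mask)) return(mask)
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) <= 2L) return(mask)
  h <- grDevices::chull(pts[, 2], pts[, 1])
  vx <- pts[h, 2]; vy <- pts[h, 1]
  if (length(h) <= 2L) return(mask)
  out <- mask
  r1 <- min(vy); r2 <- max(vy); c1 <- min(vx); c2 <- max(vx)
  py <- rep(r1:r2, times = c2 - c1 + 1L)
  px <- rep(c1:c2, each = r2 - r1 + 1L)
  inside <- .pointInPoly(px, py, vx, vy)
  sub <- matrix(inside, nrow = r2 - r1 + 1L)
  out[r1:r2, c1:c2] <- out[r1:r2, c1:c2] | sub
  out
}

# inclusive even-odd point-in-polygon, vectorised over points
.pointInPoly <- function(px, py, vx, vy, tol = 1e-9) {
  n <- length(vx)
  inside <- logical(length(px))
  onEdge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
    # on-segment test
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- ((px - xi) * dx + (py - yi) * dy) / len2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (px - (xi + t * dx))^2 + (py - (yi + t * dy))^2
      onEdge <- onEdge | d2 <= tol
    } else {
      onEdge <- onEdge | (abs(px - xi) + abs(py - yi)) <= tol
    }
    j <- i
  }
  inside | onEdge
}

#' Skeletonize a binary mask
#'
#' Zhang-Suen thinning to a one-pixel-wide, topology-preserving medial
#' representation. Applying it to a skeleton returns the skeleton unchanged.
#'
#' @param mask logical matrix.
#' @return logical matrix (thin skeleton).
#' @export
skeletonize <- function(mask) {
  .checkMask(mask)
  if (!any(mask)) return(mask)
  m <- mask
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- .shiftZero(m,  1L,  0L)  # north neighbour value at each pixel
      p3 <- .shiftZero(m,  1L, -1L)
      p4 <- .shiftZero(m,  0L, -1L)
      p5 <- .shiftZero(m, -1L, -1L)
      p6 <- .shiftZero(m, -1L,  0L)
      p7 <- .shiftZero(m, -1L,  1L)
      p8 <- .shiftZero(m,  0L,  1L)
      p9 <- .shiftZero(m,  1L,  1L)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (sub == 1) {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) { m <- m & !cond; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

#' Binary morphology suite
#'
#' Dispatcher over the standard binary operations used by the heuristic
#' stage. \code{close}/\code{open}/\code{dilate}/\code{erode} require a
#' structuring element (\code{\link{structElem}}); \code{largest_k} requires
#' \code{k}. \code{prune} takes \code{iterations} removal passes.
#'
#' @param mask logical matrix.
#' @param op one of \code{"close"}, \code{"open"}, \code{"dilate"},
#'   \code{"erode"}, \code{"fill_holes"}, \code{"skeletonize"},
#'   \code{"convex_hull"}, \code{"largest_k"}, \code{"prune"},
#'   \code{"clean"}.
#' @param se structuring element from \code{\link{structElem}}.
#' @param k component count for \code{largest_k}.
#' @param iterations passes for \code{prune}.
#' @return logical matrix of unchanged shape.
#' @export
morphSuite <- function(mask, op, se = NULL, k = NULL, iterations = 1L) {
  .checkMask(mask)
  needSe <- c("close", "open", "dilate", "erode")
  if (op %in% needSe && is.null(se)) stop("op '", op, "' requires se")
  if (op == "largest_k" && is.null(k)) stop("op 'largest_k' requires k")
  switch(op,
    close = .closeMask(mask, se),
    open = .openMask(mask, se),
    dilate = .applySe(mask, se, "dilate"),
    erode = .applySe(mask, se, "erode"),
    fill_holes = fillHoles(mask),
    skeletonize = skeletonize(mask),
    convex_hull = convexHullMask(mask),
    largest_k = largestComponents(mask, k),
    prune = pruneSpurs(mask, iterations),
    clean = cleanIsolated(mask),
    stop("unknown op: ", op)
  )
}
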
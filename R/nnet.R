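# Minimal reverse-mode automatic differentiation for the segmentation
# harness: a tape of array-valued nodes with backward closures, im2col
# convolutions (BLAS matmuls), 2x2 max pooling, nearest upsampling, channel
# concatenation and a numerically stable logit binary cross-entropy.
# Feature arrays are laid out (H, W, C, B). Everything is plain R, so runs
# are bit-reproducible on CPU under a fixed seed.

tapeNew <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp$n <- 0L
  tp
}

.mkNode <- function(tape, value, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  tape$n <- tape$n + 1L
  nd$id <- tape$n
  nd$tape <- tape
  tape$nodes[[tape$n]] <- nd
  nd
}

tapeLeaf <- function(tape, value) .mkNode(tape, value)

.accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

tapeBackward <- function(loss) {
  tape <- loss$tape
  for (nd in tape$nodes) nd$grad <- NULL
  loss$grad <- 1
  for (id in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[id]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    for (j in seq_along(nd$parents)) {
      if (!is.null(gs[[j]])) .accum(nd$parents[[j]], gs[[j]])
    }
  }
  invisible(loss)
}

# ---- im2col machinery ----------------------------------------------------

.convCacheEnv <- new.env(parent = emptyenv())

# padded linear indices for a k x k same convolution over (H, W, C, B)
.convIndex <- function(H, W, C, B, k) {
  key <- paste(H, W, C, B, k, sep = "_")
  hit <- .convCacheEnv[[key]]
  if (!is.null(hit)) return(hit)
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p; Wp <- W + 2L * p
  rr <- rep(seq_len(H), times = W)           # output pixel rows
  cc <- rep(seq_len(W), each = H)
  base <- matrix(0L, H * W, k * k)
  i <- 1L
  for (dc in 0:(k - 1L)) for (dr in 0:(k - 1L)) {
    base[, i] <- (rr + dr) + (cc + dc - 1L) * Hp
    i <- i + 1L
  }
  chanStride <- Hp * Wp
  idx <- matrix(0L, H * W, k * k * C)
  for (ch in seq_len(C)) {
    idx[, ((ch - 1L) * k * k + 1L):(ch * k * k)] <- base + (ch - 1L) * chanStride
  }
  batchStride <- Hp * Wp * C
  full <- vector("list", B)
  for (b in seq_len(B)) full[[b]] <- idx + (b - 1L) * batchStride
  out <- list(idx = do.call(rbind, full), p = p, Hp = Hp, Wp = Wp)
  .convCacheEnv[[key]] <- out
  out
}

.padHW <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  out[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), , ] <- x
  out
}

# ---- layers --------------------------------------------------------------

#' @noRd
tConv <- function(x, w, b, k) {
  d <- dim(x$value)            # H W C B
  H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  Cout <- ncol(w$value)
  ci <- .convIndex(H, W, C, B, k)
  xp <- .padHW(x$value, ci$p)
  cols <- matrix(xp[as.vector(ci$idx)], nrow = H * W * B)      # (HWB) x (k2 C)
  y <- cols %*% w$value
  y <- sweep(y, 2L, b$value, "+")
  val <- array(0, dim = c(H, W, Cout, B))
  # y rows are ordered (H W) within each batch block
  for (bb in seq_len(B)) {
    val[, , , bb] <- array(y[((bb - 1L) * H * W + 1L):(bb * H * W), ],
      dim = c(H, W, Cout))
  }
  .mkNode(x$tape, val, list(x, w, b), function(g) {
    gf <- matrix(0, H * W * B, Cout)
    for (bb in seq_len(B)) {
      gf[((bb - 1L) * H * W + 1L):(bb * H * W), ] <-
        matrix(g[, , , bb], ncol = Cout)
    }
    dw <- crossprod(cols, gf)
    db <- colSums(gf)
    dcols <- gf %*% t(w$value)
    gpad <- array(0, dim = c(ci$Hp, ci$Wp, C, B))
    for (j in seq_len(ncol(dcols))) {
      ix <- ci$idx[, j]
      gpad[ix] <- gpad[ix] + dcols[, j]
    }
    p <- ci$p
    dx <- if (p > 0L) gpad[(p + 1L):(p + H), (p + 1L):(p + W), , , drop = FALSE]
      else gpad
    dim(dx) <- c(H, W, C, B)
    list(dx, dw, db)
  })
}

#' @noRd
tRelu <- function(x) {
  v <- pmax(x$value, 0)
  .mkNode(x$tape, v, list(x), function(g) list(g * (x$value > 0)))
}

#' @noRd
tSigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  .mkNode(x$tape, s, list(x), function(g) list(g * s * (1 - s)))
}

#' @noRd
tAdd <- function(a, b) {
  .mkNode(a$tape, a$value + b$value, list(a, b), function(g) list(g, g))
}

#' @noRd
tMul <- function(a, b) {
  .mkNode(a$tape, a$value * b$value, list(a, b),
    function(g) list(g * b$value, g * a$value))
}

#' @noRd
tMaxPool2 <- function(x) {
  d <- dim(x$value)
  H <- d[1]; W <- d[2]
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  i1 <- seq(1L, H, 2L); i2 <- seq(2L, H, 2L)
  j1 <- seq(1L, W, 2L); j2 <- seq(2L, W, 2L)
  cand <- list(
    x$value[i1, j1, , , drop = FALSE], x$value[i2, j1, , , drop = FALSE],
    x$value[i1, j2, , , drop = FALSE], x$value[i2, j2, , , drop = FALSE])
  v <- pmax(cand[[1]], cand[[2]], cand[[3]], cand[[4]])
  .mkNode(x$tape, v, list(x), function(g) {
    dx <- array(0, dim = d)
    taken <- array(FALSE, dim = dim(v))
    sub <- list(list(i1, j1), list(i2, j1), list(i1, j2), list(i2, j2))
    for (s in 1:4) {
      hit <- (cand[[s]] == v) & !taken     # first-candidate tie-break
      taken <- taken | hit
      tmp <- array(0, dim = dim(v))
      tmp[hit] <- g[hit]
      dx[sub[[s]][[1]], sub[[s]][[2]], , ] <-
        dx[sub[[s]][[1]], sub[[s]][[2]], , , drop = FALSE] + tmp
    }
    list(dx)
  })
}

#' @noRd
tUpsample2 <- function(x) {
  d <- dim(x$value)
  ri <- rep(seq_len(d[1]), each = 2L)
  ci <- rep(seq_len(d[2]), each = 2L)
  v <- x$value[ri, ci, , , drop = FALSE]
  .mkNode(x$tape, v, list(x), function(g) {
    i1 <- seq(1L, 2L * d[1], 2L); i2 <- i1 + 1L
    j1 <- seq(1L, 2L * d[2], 2L); j2 <- j1 + 1L
    dx <- g[i1, j1, , , drop = FALSE] + g[i2, j1, , , drop = FALSE] +
          g[i1, j2, , , drop = FALSE] + g[i2, j2, , , drop = FALSE]
    list(dx)
  })
}

#' @noRd
tConcatC <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  v <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  v[, , seq_len(da[3]), ] <- a$value
  v[, , da[3] + seq_len(db[3]), ] <- b$value
  .mkNode(a$tape, v, list(a, b), function(g) {
    list(g[, , seq_len(da[3]), , drop = FALSE],
         g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

#' @noRd
tBceWithLogits <- function(z, y) {
  zv <- z$value
  n <- length(zv)
  l <- mean(pmax(zv, 0) - zv * y + log1p(exp(-abs(zv))))
  .mkNode(z$tape, l, list(z), function(g) {
    list(g * (1 / (1 + exp(-zv)) - y) / n)
  })
}

#' @noRd
# batch normalisation over (H, W, B) per channel; returns the node plus
# updated running statistics (training mode) or uses the stored ones (eval)
tBatchNorm <- function(x, g, b, runMean, runVar, training = TRUE,
                       momentum = 0.1, eps = 1e-5) {
  d <- dim(x$value)
  C <- d[3]
  n <- d[1] * d[2] * d[4]
  xm <- matrix(aperm(x$value, c(1, 2, 4, 3)), ncol = C)
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm * xm) - mu^2
    runMean <- (1 - momentum) * runMean + momentum * mu
    runVar <- (1 - momentum) * runVar + momentum * va
  } else {
    mu <- runMean; va <- runVar
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2L, mu), 2L, istd, "*")
  ym <- sweep(sweep(xhat, 2L, g$value, "*"), 2L, b$value, "+")
  toArr <- function(m) aperm(array(m, dim = c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  nd <- .mkNode(x$tape, toArr(ym), list(x, g, b), function(gr) {
    dym <- matrix(aperm(gr, c(1, 2, 4, 3)), ncol = C)
    dg <- colSums(dym * xhat)
    db <- colSums(dym)
    if (training) {
      dxhat <- sweep(dym, 2L, g$value, "*")
      mdx <- colMeans(dxhat)
      mdxx <- colMeans(dxhat * xhat)
      dxm <- sweep(dxhat, 2L, mdx) - sweep(xhat, 2L, mdxx, "*")
      dxm <- sweep(dxm, 2L, istd, "*")
    } else {
      dxm <- sweep(sweep(dym, 2L, g$value, "*"), 2L, istd, "*")
    }
    list(toArr(dxm), dg, db)
  })
  list(node = nd, runMean = runMean, runVar = runVar)
}

# ---- optimiser -----------------------------------------------------------

adamInit <- function(paramArrays) {
  list(m = lapply(paramArrays, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(paramArrays, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adamStep <- function(paramArrays, grads, state, lr, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (i in seq_along(paramArrays)) {
    g <- grads[[i]]
    if (is.null(g)) next
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    mh <- state$m[[i]] / (1 - beta1^state$t)
    vh <- state$v[[i]] / (1 - beta2^state$t)
    paramArrays[[i]] <- paramArrays[[i]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = paramArrays, state = state)
}

# numeric gradient check helper used by the tests
.numGrad <- function(f, x, h = 1e-5) {
  g <- array(0, dim = dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}
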
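# Configurable encoder-decoder family for lung-field segmentation. The five
# families share one code path: plain double-conv blocks (unet), residual
# blocks (res_unet), attention gates on the skip connections
# (attention_unet), nested dense skip nodes in the U-Net++ style
# (nested_unet), and nested skips with attention gates
# (attention_dense_unet). All models take the 3-plane mixer output and emit
# a single logit plane at input resolution.

#' Segmentation model specification
#'
#' @param family one of \code{"unet"}, \code{"attention_unet"},
#'   \code{"nested_unet"}, \code{"res_unet"}, \code{"attention_dense_unet"}.
#' @param depth number of resolution levels (>= 2); each level halves H, W.
#' @param baseFilters filters at the top level, doubled per level.
#' @return list of class \code{ModelSpec}.
#' @export
modelSpec <- function(family = c("unet", "attention_unet", "nested_unet",
                                 "res_unet", "attention_dense_unet"),
                      depth = 3L, baseFilters = 8L) {
  family <- match.arg(family)
  stopifnot(depth >= 2L, baseFilters >= 1L)
  structure(list(family = family, depth = as.integer(depth),
    baseFilters = as.integer(baseFilters)), class = c("ModelSpec", "list"))
}

.heW <- function(k, cin, cout) {
  matrix(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
    k * k * cin, cout)
}

# parameter arrays for one conv: list(w, b); bn adds scale/shift
.mkConv <- function(params, name, k, cin, cout, bn = FALSE) {
  params[[paste0(name, ".w")]] <- .heW(k, cin, cout)
  params[[paste0(name, ".b")]] <- numeric(cout)
  if (bn) {
    params[[paste0(name, ".bn.g")]] <- rep(1, cout)
    params[[paste0(name, ".bn.b")]] <- numeric(cout)
  }
  params
}

#' Initialise model parameters
#'
#' He-normal initialisation, deterministic under the current RNG state.
#' The mixer parameters (names \code{mixer.w}, \code{mixer.b}) use the
#' identity-preserving initialisation of \code{\link{MixerParams}}.
#'
#' @param spec a \code{\link{modelSpec}}.
#' @return named list of parameter arrays (including the mixer).
#' @export
initModelParams <- function(spec) {
  d <- spec$depth; f <- spec$baseFilters
  att <- spec$family %in% c("attention_unet", "attention_dense_unet")
  nested <- spec$family %in% c("nested_unet", "attention_dense_unet")
  res <- spec$family == "res_unet"
  params <- list()
  params[["mixer.w"]] <- t(MixerParams()@weights)   # (5 x 3) conv layout
  params[["mixer.b"]] <- numeric(3)
  filt <- f * 2^(0:(d - 1))
  cin <- 3L
  for (l in seq_len(d)) {
    params <- .mkConv(params, sprintf("enc%d.c1", l), 3L, cin, filt[l], bn = TRUE)
    params <- .mkConv(params, sprintf("enc%d.c2", l), 3L, filt[l], filt[l], bn = TRUE)
    if (res) params <- .mkConv(params, sprintf("enc%d.sc", l), 1L, cin, filt[l])
    cin <- filt[l]
  }
  if (nested) {
    # nested skip nodes X[i, j]: level i, step j >= 1; single conv each
    for (j in seq_len(d - 1L)) {
      for (i in seq_len(d - j)) {
        cinN <- filt[i] * j + filt[i + 1L]   # j previous nodes + upsampled
        params <- .mkConv(params, sprintf("nest%d.%d", i, j), 3L, cinN, filt[i], bn = TRUE)
        if (att) {
          params <- .mkConv(params, sprintf("nest%d.%d.a.x", i, j), 1L,
            filt[i] * j, filt[i])
          params <- .mkConv(params, sprintf("nest%d.%d.a.g", i, j), 1L,
            filt[i + 1L], filt[i])
          params <- .mkConv(params, sprintf("nest%d.%d.a.o", i, j), 1L,
            filt[i], 1L)
        }
      }
    }
    params <- .mkConv(params, "out", 1L, filt[1], 1L)
  } else {
    for (l in seq_len(d - 1L)) {
      lev <- d - l            # decoder level producing filt[lev]
      cinD <- filt[lev] + filt[lev + 1L]
      params <- .mkConv(params, sprintf("dec%d.c1", lev), 3L, cinD, filt[lev], bn = TRUE)
      params <- .mkConv(params, sprintf("dec%d.c2", lev), 3L, filt[lev], filt[lev], bn = TRUE)
      if (res) params <- .mkConv(params, sprintf("dec%d.sc", lev), 1L, cinD, filt[lev])
      if (att) {
        params <- .mkConv(params, sprintf("att%d.x", lev), 1L, filt[lev], filt[lev])
        params <- .mkConv(params, sprintf("att%d.g", lev), 1L, filt[lev + 1L], filt[lev])
        params <- .mkConv(params, sprintf("att%d.o", lev), 1L, filt[lev], 1L)
      }
    }
    params <- .mkConv(params, "out", 1L, filt[1], 1L)
  }
  params
}

.convOf <- function(tape, nodes, params, name, x, k) {
  w <- nodes[[paste0(name, ".w")]]
  b <- nodes[[paste0(name, ".b")]]
  tConv(x, w, b, k)
}

# conv + batch norm, threading the running statistics through ctx
.convBn <- function(ctx, name, x, k) {
  h <- .convOf(ctx$tape, ctx$nodes, ctx$params, name, x, k)
  bn <- tBatchNorm(h, ctx$nodes[[paste0(name, ".bn.g")]],
    ctx$nodes[[paste0(name, ".bn.b")]],
    ctx$buffers[[paste0(name, ".rm")]] %||% numeric(dim(h$value)[3]),
    ctx$buffers[[paste0(name, ".rv")]] %||% rep(1, dim(h$value)[3]),
    training = ctx$training)
  ctx$buffers[[paste0(name, ".rm")]] <- bn$runMean
  ctx$buffers[[paste0(name, ".rv")]] <- bn$runVar
  bn$node
}

.block <- function(ctx, name, x, res) {
  h <- tRelu(.convBn(ctx, paste0(name, ".c1"), x, 3L))
  h <- .convBn(ctx, paste0(name, ".c2"), h, 3L)
  if (res) {
    sc <- .convOf(ctx$tape, ctx$nodes, ctx$params, paste0(name, ".sc"), x, 1L)
    h <- tAdd(h, sc)
  }
  tRelu(h)
}

.attGate <- function(ctx, prefix, x, g) {
  # additive attention: a = sigmoid(conv1(relu(conv1(x) + conv1(g)))), x * a
  tape <- ctx$tape
  ax <- .convOf(tape, ctx$nodes, ctx$params, paste0(prefix, ".x"), x, 1L)
  ag <- .convOf(tape, ctx$nodes, ctx$params, paste0(prefix, ".g"), g, 1L)
  a <- tSigmoid(.convOf(tape, ctx$nodes, ctx$params, paste0(prefix, ".o"),
    tRelu(tAdd(ax, ag)), 1L))
  # broadcast the 1-channel gate over x's channels
  dC <- dim(x$value)[3]
  aB <- .mkNode(tape, a$value[, , rep(1L, dC), , drop = FALSE], list(a),
    function(gr) {
      list(array(apply(gr, c(1, 2, 4), sum), dim = dim(a$value)))
    })
  tMul(x, aB)
}

#' Forward pass of the fusion front end and segmentation model
#'
#' Builds the graph: 1x1 mixer over the (already selection-masked) 5-plane
#' input, then the encoder-decoder of the requested family, ending in a
#' single-logit plane.
#'
#' @param tape autodiff tape.
#' @param x input node with value (H, W, 5, B).
#' @param params named list of parameter arrays.
#' @param spec \code{\link{modelSpec}}.
#' @param buffers named list of batch-norm running statistics (empty list at
#'   initialisation).
#' @param training logical; training mode uses batch statistics and updates
#'   the running ones, evaluation mode uses the stored statistics.
#' @return list with \code{logits} node, \code{paramNodes} (named list of
#'   leaf nodes aligned with \code{params}) and updated \code{buffers}.
#' @export
modelForward <- function(tape, x, params, spec, buffers = list(),
                         training = TRUE) {
  ctx <- new.env(parent = emptyenv())
  ctx$tape <- tape
  ctx$nodes <- lapply(params, function(p) tapeLeaf(tape, p))
  ctx$params <- params
  ctx$buffers <- buffers
  ctx$training <- training
  nodes <- ctx$nodes
  d <- spec$depth
  res <- spec$family == "res_unet"
  att <- spec$family %in% c("attention_unet", "attention_dense_unet")
  nested <- spec$family %in% c("nested_unet", "attention_dense_unet")
  h <- tConv(x, nodes[["mixer.w"]], nodes[["mixer.b"]], 1L)
  enc <- vector("list", d)
  for (l in seq_len(d)) {
    if (l > 1L) h <- tMaxPool2(h)
    h <- .block(ctx, sprintf("enc%d", l), h, res)
    enc[[l]] <- h
  }
  if (!nested) {
    h <- enc[[d]]
    for (lev in (d - 1L):1L) {
      up <- tUpsample2(h)
      skip <- enc[[lev]]
      if (att) skip <- .attGate(ctx, sprintf("att%d", lev), skip, up)
      h <- tConcatC(skip, up)
      h <- .block(ctx, sprintf("dec%d", lev), h, res)
    }
  } else {
    X <- vector("list", d)
    for (i in seq_len(d)) X[[i]] <- list(enc[[i]])   # X[i][1] = X_{i,0}
    for (j in seq_len(d - 1L)) {
      for (i in seq_len(d - j)) {
        up <- tUpsample2(X[[i + 1L]][[j]])
        prev <- X[[i]][[1L]]
        if (j > 1L) for (q in 2L:j) prev <- tConcatC(prev, X[[i]][[q]])
        if (att) prev <- .attGate(ctx, sprintf("nest%d.%d.a", i, j), prev, up)
        hN <- tConcatC(prev, up)
        hN <- tRelu(.convBn(ctx, sprintf("nest%d.%d", i, j), hN, 3L))
        X[[i]][[j + 1L]] <- hN
      }
    }
    h <- X[[1L]][[d]]
  }
  logits <- .convOf(tape, nodes, params, "out", h, 1L)
  list(logits = logits, paramNodes = nodes, buffers = ctx$buffers)
}
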
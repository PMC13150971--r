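# Training and evaluation harness: pixel metrics, data splits, the training
# loop over the selection + mixer + encoder-decoder pipeline, cross-dataset
# evaluation, and the 16-combination ablation sweep.

#' Pixelwise segmentation metrics
#'
#' Dice, Jaccard (IoU), accuracy, precision and recall from the pixel
#' confusion counts. When both masks are empty, dice, IoU, precision and
#' recall are 1 (nothing to find, nothing found); a prediction with no
#' positives against a nonempty reference scores precision 0.
#'
#' @param pred,ref logical matrices of the same shape.
#' @return one-row data.frame: \code{dice}, \code{iou}, \code{accuracy},
#'   \code{precision}, \code{recall}, \code{nImages}.
#' @export
pixelMetrics <- function(pred, ref) {
  .checkMask(pred, "pred"); .checkMask(ref, "ref"); .sameShape(pred, ref)
  tp <- sum(pred & ref); fp <- sum(pred & !ref)
  fn <- sum(!pred & ref); tn <- sum(!pred & !ref)
  dice <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  iou <- if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn)
  prec <- if (tp + fp == 0) as.numeric(fn == 0) else tp / (tp + fp)
  rec <- if (tp + fn == 0) as.numeric(fp == 0) else tp / (tp + fn)
  data.frame(dice = dice, iou = iou,
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    precision = prec, recall = rec, nImages = 1L)
}

.aggregateMetrics <- function(rows) {
  m <- do.call(rbind, rows)
  out <- as.data.frame(lapply(m[, 1:5], mean))
  out$nImages <- nrow(m)
  out
}

#' Seeded hold-out split
#'
#' @param ids character or integer ids (n >= 5).
#' @param fraction test fraction; test size is \code{round(fraction * n)}.
#' @param seed RNG seed.
#' @return list with \code{trainIds}, \code{testIds}, \code{fraction},
#'   \code{seed}.
#' @export
splitHoldout <- function(ids, fraction = 0.2, seed = 1L) {
  n <- length(ids)
  stopifnot(n >= 5L, fraction > 0, fraction < 1)
  perm <- .withSeed(seed, sample(ids))
  nTest <- round(fraction * n)
  list(trainIds = perm[-seq_len(nTest)], testIds = perm[seq_len(nTest)],
    fraction = fraction, seed = as.integer(seed))
}

#' Seeded k-fold partition
#'
#' Fold sizes differ by at most one; every id is in exactly one fold.
#'
#' @param trainIds ids to partition.
#' @param k number of folds (>= 2, <= length(trainIds)).
#' @param seed RNG seed.
#' @return list of k id vectors.
#' @export
kfold <- function(trainIds, k = 5L, seed = 1L) {
  n <- length(trainIds)
  stopifnot(k >= 2L, n >= k)
  perm <- .withSeed(seed + 1L, sample(trainIds))
  split(perm, rep_len(seq_len(k), n))
}

#' Training configuration
#'
#' @param learningRate Adam learning rate (default 1e-4).
#' @param epochs training epochs (default 50).
#' @param batchSize minibatch size (default 4).
#' @param inputSize square input resolution (default 256).
#' @param seed RNG seed governing fold assignment, batching and init.
#' @param model a \code{\link{modelSpec}}.
#' @param steps optional exact number of optimiser steps (overrides epochs).
#' @return list of class \code{TrainConfig}.
#' @export
trainConfig <- function(learningRate = 1e-4, epochs = 50L, batchSize = 4L,
                        inputSize = 256L, seed = 1L, model = modelSpec(),
                        steps = NULL) {
  stopifnot(learningRate > 0, epochs >= 1, batchSize >= 1, inputSize >= 8)
  structure(list(learningRate = learningRate, epochs = as.integer(epochs),
    batchSize = as.integer(batchSize), inputSize = as.integer(inputSize),
    seed = as.integer(seed), model = model, steps = steps),
    class = c("TrainConfig", "list"))
}

# data item -> (H, W, 5) array at the configured size
.itemStack <- function(item, size) {
  cs <- item$channels
  stopifnot(is(cs, "ChannelSet"))
  planes <- lapply(channelNames(cs), function(nm) {
    .resizePlane(channelPlane(cs, nm), size, nearest = nm != "Io")
  })
  array(unlist(planes), dim = c(size, size, 5L))
}

.itemMask <- function(item, size) {
  m <- .resizePlane(item$mask, size, nearest = TRUE)
  m >= 0.5
}

#' Train the fusion pipeline and segmentation model
#'
#' Pipeline: binary channel selection (fixed by \code{combo}), learnable
#' 1x1 mixer, encoder-decoder per \code{cfg$model}; optimised with Adam on
#' logit binary cross-entropy. Deterministic under \code{cfg$seed}. Aborts
#' with diagnostics if the loss becomes non-finite.
#'
#' @param cfg \code{\link{trainConfig}}.
#' @param data list of items, each \code{list(channels = ChannelSet,
#'   mask = logical matrix)}.
#' @param combo one row of \code{\link{enumerateCombinations}}.
#' @return object of class \code{lfModel}: parameters, spec, config, combo
#'   and the per-step loss trace.
#' @export
trainModel <- function(cfg, data, combo = enumerateCombinations()[16, ]) {
  stopifnot(inherits(cfg, "TrainConfig"), length(data) >= 1L)
  size <- cfg$inputSize
  sel <- .selectorVector(combo)
  xs <- lapply(data, function(it) {
    a <- .itemStack(it, size)
    for (c5 in 1:5) a[, , c5] <- a[, , c5] * sel[c5]
    a
  })
  ys <- lapply(data, function(it) .itemMask(it, size) * 1)
  n <- length(xs)
  nSteps <- if (!is.null(cfg$steps)) cfg$steps else
    cfg$epochs * max(1L, ceiling(n / cfg$batchSize))
  .withSeed(cfg$seed, {
    params <- initModelParams(cfg$model)
    opt <- adamInit(params)
    buffers <- list()
    losses <- numeric(nSteps)
    order <- integer(0)
    for (step in seq_len(nSteps)) {
      if (length(order) < cfg$batchSize) order <- c(order, sample(n))
      take <- order[seq_len(min(cfg$batchSize, n))]
      order <- order[-seq_len(min(cfg$batchSize, n))]
      B <- length(take)
      xb <- array(0, dim = c(size, size, 5L, B))
      yb <- array(0, dim = c(size, size, 1L, B))
      for (b in seq_len(B)) {
        xb[, , , b] <- xs[[take[b]]]
        yb[, , 1, b] <- ys[[take[b]]]
      }
      tape <- tapeNew()
      xN <- tapeLeaf(tape, xb)
      fw <- modelForward(tape, xN, params, cfg$model, buffers, training = TRUE)
      buffers <- fw$buffers
      loss <- tBceWithLogits(fw$logits, yb)
      if (!is.finite(loss$value)) {
        stop(sprintf("non-finite loss at step %d (last finite: %.6g)",
          step, if (step > 1) losses[step - 1] else NA_real_))
      }
      losses[step] <- loss$value
      tapeBackward(loss)
      grads <- lapply(fw$paramNodes, function(nd) nd$grad)
      upd <- adamStep(params, grads, opt, cfg$learningRate)
      params <- upd$params
      opt <- upd$state
    }
    structure(list(params = params, buffers = buffers, spec = cfg$model,
      cfg = cfg, combo = combo, losses = losses), class = "lfModel")
  })
}

#' Predict lung-field probabilities and masks
#'
#' @param model an \code{lfModel}.
#' @param data list of items with \code{channels}.
#' @param threshold probability threshold on the sigmoid output (0.5).
#' @return list per item: \code{prob} matrix and logical \code{mask}.
#' @export
predictModel <- function(model, data, threshold = 0.5) {
  size <- model$cfg$inputSize
  sel <- .selectorVector(model$combo)
  lapply(data, function(it) {
    a <- .itemStack(it, size)
    for (c5 in 1:5) a[, , c5] <- a[, , c5] * sel[c5]
    tape <- tapeNew()
    xN <- tapeLeaf(tape, array(a, dim = c(size, size, 5L, 1L)))
    fw <- modelForward(tape, xN, model$params, model$spec, model$buffers,
      training = FALSE)
    prob <- 1 / (1 + exp(-fw$logits$value[, , 1, 1]))
    list(prob = prob, mask = prob >= threshold)
  })
}

#' Evaluate a model on one labelled set
#'
#' @param model an \code{lfModel}.
#' @param data labelled items (\code{channels} + \code{mask}).
#' @return aggregated \code{\link{pixelMetrics}} row.
#' @export
evaluateModel <- function(model, data) {
  stopifnot(length(data) >= 1L)
  preds <- predictModel(model, data)
  rows <- lapply(seq_along(data), function(i) {
    ref <- .itemMask(data[[i]], model$cfg$inputSize)
    pixelMetrics(preds[[i]]$mask, ref)
  })
  .aggregateMetrics(rows)
}

#' Cross-dataset evaluation
#'
#' Evaluates a model trained on one source on each named held-out target
#' set, without fine-tuning; rows are tagged "SOURCE -> TARGET".
#'
#' @param model an \code{lfModel} (its \code{cfg$sourceName} or "source"
#'   tags the rows).
#' @param testSets named list of labelled data sets.
#' @return data.frame with a \code{pair} column and the five metrics.
#' @export
crossDatasetEval <- function(model, testSets) {
  stopifnot(length(testSets) >= 1L, !is.null(names(testSets)))
  src <- model$cfg$sourceName %||% "source"
  rows <- lapply(names(testSets), function(nm) {
    if (length(testSets[[nm]]) == 0L) stop("empty target set: ", nm)
    cbind(pair = paste(src, "->", nm), evaluateModel(model, testSets[[nm]]))
  })
  do.call(rbind, rows)
}

#' Ablation sweep over the 16 channel combinations
#'
#' Trains and evaluates every channel combination under an identical
#' configuration and seed, and reports the five metrics plus delta columns
#' against the grayscale-only baseline row.
#'
#' @param cfg \code{\link{trainConfig}}.
#' @param data training items.
#' @param evalData items to evaluate on (defaults to \code{data}).
#' @return 16-row data.frame: \code{label}, metrics, \code{deltaDice},
#'   \code{deltaIou}.
#' @export
ablationSweep <- function(cfg, data, evalData = data) {
  combos <- enumerateCombinations()
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    model <- trainModel(cfg, data, combos[i, ])
    cbind(label = combos$label[i], evaluateModel(model, evalData))
  })
  out <- do.call(rbind, rows)
  base <- out[out$label == "Io", ]
  out$deltaDice <- out$dice - base$dice
  out$deltaIou <- out$iou - base$iou
  rownames(out) <- NULL
  out
}
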
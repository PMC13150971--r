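test_that("autodiff gradients match central finite differences", {
  set.seed(7)
  H <- 8; W <- 8; C <- 2; B <- 2
  x <- array(runif(H * W * C * B), c(H, W, C, B))
  y <- array(rbinom(H * W * B, 1, 0.4), c(H, W, 1, B))
  w1 <- matrix(rnorm(9 * C * 3, 0, 0.3), 9 * C, 3); b1 <- rnorm(3)
  w2 <- matrix(rnorm(3), 3, 1); b2 <- rnorm(1)
  g1 <- c(1.1, 0.9, 1.0); be1 <- c(0.05, -0.1, 0)
  build <- function(w1v) {
    tape <- tapeNew()
    xn <- tapeLeaf(tape, x)
    w1n <- tapeLeaf(tape, w1v); b1n <- tapeLeaf(tape, b1)
    gn <- tapeLeaf(tape, g1); ben <- tapeLeaf(tape, be1)
    bnr <- lungfuse:::tBatchNorm(lungfuse:::tConv(xn, w1n, b1n, 3L), gn, ben,
      numeric(3), rep(1, 3), training = TRUE)
    h <- lungfuse:::tMaxPool2(lungfuse:::tRelu(bnr$node))
    h <- lungfuse:::tUpsample2(h)
    z <- lungfuse:::tConv(h, tapeLeaf(tape, w2), tapeLeaf(tape, b2), 1L)
    list(loss = lungfuse:::tBceWithLogits(z, y), w1n = w1n, gn = gn, xn = xn)
  }
  r <- build(w1)
  lungfuse:::tapeBackward(r$loss)
  num <- lungfuse:::.numGrad(function(v) build(matrix(v, nrow(w1)))$loss$value, w1)
  expect_lt(max(abs(r$w1n$grad - num)), 1e-8)
  expect_false(is.null(r$gn$grad))
})

test_that("adam descends a quadratic and training reduces the loss", {
  p <- list(theta = c(5, -3))
  st <- lungfuse:::adamInit(p)
  for (i in 1:400) {
    g <- list(theta = 2 * p$theta)
    up <- lungfuse:::adamStep(p, g, st, lr = 0.05)
    p <- up$params; st <- up$state
  }
  expect_lt(sum(p$theta^2), 0.1)
  items <- randomItems(4, seed = 2)
  cfg <- trainConfig(learningRate = 1e-4, batchSize = 4L, inputSize = 16L,
    seed = 5L, model = modelSpec("unet", 2, 2), steps = 3L)
  m <- trainModel(cfg, items)
  expect_lt(m$losses[2], m$losses[1])   # one full-batch update helps
})

test_that("training is reproducible under a fixed seed and aborts on blow-up", {
  items <- randomItems(3, seed = 3)
  cfg <- trainConfig(inputSize = 16L, seed = 11L,
    model = modelSpec("unet", 2, 2), steps = 3L)
  m1 <- trainModel(cfg, items)
  m2 <- trainModel(cfg, items)
  expect_identical(m1$losses, m2$losses)
  expect_identical(m1$params, m2$params)
  bad <- trainConfig(learningRate = Inf, inputSize = 16L, seed = 1L,
    model = modelSpec("unet", 2, 2), steps = 5L)
  expect_error(trainModel(bad, items), "non-finite")
})

test_that("every model family trains a step and predicts in-range probabilities", {
  items <- randomItems(2, seed = 6)
  for (fam in c("unet", "attention_unet", "nested_unet", "res_unet",
                "attention_dense_unet")) {
    cfg <- trainConfig(inputSize = 16L, seed = 2L,
      model = modelSpec(fam, 2, 2), steps = 2L)
    m <- trainModel(cfg, items)
    pr <- predictModel(m, items)
    expect_true(all(vapply(pr, function(p) all(p$prob >= 0 & p$prob <= 1),
      logical(1))), info = fam)
    expect_identical(dim(pr[[1]]$prob), c(16L, 16L))
  }
})
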
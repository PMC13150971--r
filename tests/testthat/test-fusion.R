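test_that("channel set assembly resizes and binarises correctly", {
  Io <- matrix(runif(512 * 512), 512, 512)
  e <- matrix(FALSE, 512, 512); e[100:300, 100:300] <- TRUE
  cs <- buildChannelSet(Io, e, e & FALSE, e, e)
  expect_s4_class(cs, "ChannelSet")
  expect_identical(dim(cs@planes), c(256L, 256L, 5L))
  expect_true(all(channelPlane(cs, "cn1") %in% c(0, 1)))
  expect_identical(sum(channelPlane(cs, "cn2")), 0)
  # nearest-resized mask overlaps an independently resized mask well
  ref <- matrix(FALSE, 256, 256); ref[50:150, 50:150] <- TRUE
  pm <- channelPlane(cs, "pm") > 0.5
  inter <- sum(pm & ref); uni <- sum(pm | ref)
  expect_gte(inter / uni, 0.95)
  expect_error(buildChannelSet(Io, e, e), "missing stage-1 artifact")
})

test_that("the sixteen combinations are exhaustive, distinct and Io-anchored", {
  comb <- enumerateCombinations()
  expect_identical(nrow(comb), 16L)
  expect_identical(comb$label[1], "Io")
  expect_true(all(grepl("^Io", comb$label)))
  expect_identical(anyDuplicated(comb$label), 0L)
  sel <- as.matrix(comb[, c("cn1", "cn2", "log", "pm")])
  expect_identical(nrow(unique(sel)), 16L)
  expect_identical(comb$label[16], "Io_cn1_cn2_log_pm")
})

test_that("binary selection zeroes deselected planes and is idempotent", {
  set.seed(4)
  X <- array(runif(5 * 4 * 4), c(5, 4, 4))
  comb <- enumerateCombinations()
  allOn <- applySelection(X, comb[16, ])
  expect_identical(allOn, X)
  onlyIo <- applySelection(X, comb[1, ])
  expect_identical(onlyIo[1, , ], X[1, , ])
  expect_true(all(onlyIo[2:5, , ] == 0))
  # elementwise against a loop oracle
  m <- lungfuse:::.selectorVector(comb[7, ])
  want <- X
  for (c5 in 1:5) for (i in 1:4) for (j in 1:4) want[c5, i, j] <- X[c5, i, j] * m[c5]
  expect_identical(applySelection(X, comb[7, ]), want)
  expect_identical(applySelection(applySelection(X, comb[7, ]), comb[7, ]),
    applySelection(X, comb[7, ]))
})

test_that("the 1x1 mixer is exact at init, matches a loop oracle, is linear", {
  set.seed(9)
  X <- array(runif(5 * 8 * 8), c(5, 8, 8))
  out <- channelMixer(X, MixerParams())
  expect_identical(dim(out), c(3L, 8L, 8L))
  for (c3 in 1:3) expect_equal(out[c3, , ], X[1, , ])
  pb <- MixerParams(matrix(0, 3, 5), c(0.2, 0.4, 0.6))
  ob <- channelMixer(X, pb)
  expect_true(all(ob[1, , ] == 0.2) && all(ob[3, , ] == 0.6))
  W <- matrix(rnorm(15), 3, 5); b <- rnorm(3)
  p <- MixerParams(W, b)
  Y <- array(runif(5 * 2 * 2), c(5, 2, 2))
  got <- channelMixer(Y, p)
  for (c3 in 1:3) for (i in 1:2) for (j in 1:2)
    expect_equal(got[c3, i, j], sum(W[c3, ] * Y[, i, j]) + b[c3], tolerance = 1e-6)
  # linearity with zero bias
  p0 <- MixerParams(W, numeric(3))
  Z <- array(runif(5 * 2 * 2), c(5, 2, 2))
  expect_equal(channelMixer(2 * Y + 3 * Z, p0),
    2 * channelMixer(Y, p0) + 3 * channelMixer(Z, p0), tolerance = 1e-12)
  expect_error(channelMixer(array(0, c(4, 2, 2)), p0), "stack")
})
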
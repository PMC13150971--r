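test_that("pixel metrics match hand counts and conventions", {
  a <- matrix(FALSE, 10, 10); a[1:3, 1:10] <- TRUE          # 30 px
  b <- matrix(FALSE, 10, 10); b[2:6, 1:10] <- TRUE          # 50 px, overlap 20
  m <- pixelMetrics(a, b)
  expect_equal(m$dice, 40 / 80)
  expect_equal(m$iou, 20 / 60)
  expect_equal(m$precision, 20 / 30)
  expect_equal(m$recall, 20 / 50)
  full <- matrix(TRUE, 5, 5)
  expect_equal(pixelMetrics(full, full)$dice, 1)
  expect_equal(pixelMetrics(full & FALSE, full & FALSE)$dice, 1)
  expect_equal(pixelMetrics(full & FALSE, full & FALSE)$precision, 1)
  d1 <- matrix(FALSE, 5, 5); d1[1, 1] <- TRUE
  d2 <- matrix(FALSE, 5, 5); d2[5, 5] <- TRUE
  expect_equal(pixelMetrics(d1, d2)$dice, 0)
  expect_error(pixelMetrics(d1, matrix(FALSE, 4, 4)), "shape")
})

test_that("hold-out split sizes, determinism and seed sensitivity", {
  ids <- sprintf("img%03d", 1:100)
  sp <- splitHoldout(ids, 0.2, seed = 3)
  expect_length(sp$testIds, 20L)
  expect_length(sp$trainIds, 80L)
  expect_length(intersect(sp$trainIds, sp$testIds), 0L)
  expect_identical(splitHoldout(ids, 0.2, seed = 3), sp)
  others <- vapply(4:8, function(s)
    identical(splitHoldout(ids, 0.2, seed = s)$testIds, sp$testIds), logical(1))
  expect_false(all(others))
})

test_that("k-fold partitions are balanced, exhaustive and leak-free", {
  ids <- letters[1:10]
  f <- kfold(ids, 5, seed = 1)
  expect_identical(unname(lengths(f)), rep(2L, 5))
  expect_setequal(unlist(f), ids)
  f11 <- kfold(letters[1:11], 5, seed = 1)
  expect_identical(sort(unname(lengths(f11)), decreasing = TRUE), c(3L, 2L, 2L, 2L, 2L))
  sp <- splitHoldout(letters[1:20], 0.2, seed = 2)
  folds <- kfold(sp$trainIds, 4, seed = 2)
  expect_length(intersect(unlist(folds), sp$testIds), 0L)
})

test_that("channel selection zeroes planes end to end in the training stack", {
  items <- randomItems(1, seed = 9)
  comb <- enumerateCombinations()
  a <- lungfuse:::.itemStack(items[[1]], 16L)
  onlyIo <- a
  for (c5 in 2:5) onlyIo[, , c5] <- 0
  selA <- lungfuse:::.selectorVector(comb[1, ])
  got <- a
  for (c5 in 1:5) got[, , c5] <- got[, , c5] * selA[c5]
  expect_identical(got, onlyIo)
})

test_that("cross-dataset evaluation plumbs named pairs and rejects empties", {
  items <- randomItems(3, seed = 12)
  cfg <- trainConfig(inputSize = 16L, seed = 4L,
    model = modelSpec("unet", 2, 2), steps = 2L)
  cfg$sourceName <- "A"
  m <- trainModel(cfg, items)
  rep <- crossDatasetEval(m, list(B = randomItems(2, seed = 13),
                                  C = randomItems(2, seed = 14)))
  expect_identical(nrow(rep), 2L)
  expect_identical(rep$pair, c("A -> B", "A -> C"))
  expect_true(all(is.finite(as.matrix(rep[, 2:6]))))
  expect_error(crossDatasetEval(m, list(B = list())), "empty target")
})
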
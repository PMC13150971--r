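test_that("preconditioning removes impulses and respects the min-filter order", {
  cst <- matrix(0.5, 32, 32)
  expect_equal(preconditionLog(cst), cst)
  img <- matrix(0.5, 32, 32); img[16, 16] <- 1
  out <- preconditionLog(img)
  expect_lt(out[16, 16], 0.9)
  ph <- generatePhantom(phantomSpec(seed = 5, size = c(128L, 128L)))
  p <- imgPixels(ph$image)
  cl <- claheEnhance(p, c(5, 5), 0.001, "uniform", 256L)
  med <- lungfuse:::.median3x3(cl)
  expect_true(all(preconditionLog(p) <= med + 1e-12))
})

test_that("boundary subtraction is pixelwise and disconnects contours", {
  IL <- matrix(FALSE, 20, 20); IL[10, 2:18] <- TRUE
  Mb <- matrix(FALSE, 20, 20); Mb[, 9:11] <- TRUE
  L1 <- subtractBoundary(IL, Mb)
  expect_identical(L1, IL & !Mb)
  expect_identical(max(labelComponents(L1)), 2L)   # split into two parts
  expect_identical(subtractBoundary(IL, matrix(FALSE, 20, 20)), IL)
  expect_identical(sum(subtractBoundary(IL, IL | TRUE)), 0L)
})

test_that("region masks: ribcage inset and upper-half shoulder construction", {
  Ib <- matrix(TRUE, 64, 64)
  rm1 <- buildRegionMasks(Ib, 0.02, heuristicParams(inputWidth = 64L))
  expect_true(sum(rm1$MR) > 0 && sum(rm1$MR) < 64 * 64)   # margin inset
  # before dilation the shoulder mask lives in the upper half only;
  # the dilation element here is 1 px, so the property holds exactly
  expect_false(any(rm1$MS[33:64, ]))
  expect_warning(buildRegionMasks(matrix(FALSE, 16, 16), 0.02), "empty")
  # MR stays inside the closing of Ib
  cl <- morphSuite(Ib, "close", structElem("disk", as.integer(round(64 * 0.7))))
  expect_true(all(!rm1$MR | cl))
})

test_that("lung LoG extraction composes subtraction and reconstruction", {
  L1 <- matrix(FALSE, 30, 30)
  L1[5:8, 5:8] <- TRUE          # shoulder-ish component
  L1[20:24, 20:24] <- TRUE      # lung-ish component
  MS <- matrix(FALSE, 30, 30); MS[6, 6] <- TRUE
  MR <- matrix(FALSE, 30, 30); MR[22, 22] <- TRUE
  r <- extractLungLog(L1, MR, MS)
  expect_false(any(r$IR[5:8, 5:8]))
  expect_identical(sum(r$LF0), 25L)
  expect_true(all(!r$LF0 | r$IR)); expect_true(all(!r$IR | L1))
  r2 <- extractLungLog(L1, MR, matrix(FALSE, 30, 30))
  expect_identical(r2$IR, L1)
})

test_that("ROI refinement keeps the subset chain and hull convexity", {
  s1 <- stage1Cached(1)
  a <- s1$artifacts
  expect_true(all(!a$S2 | a$S1))
  expect_true(all(!a$IF | a$LF0))
  expect_identical(convexHullMask(a$hullC1), a$hullC1)
  expect_warning(
    refineRoi(matrix(FALSE, 16, 16), matrix(FALSE, 16, 16),
      matrix(FALSE, 16, 16), 0.02, heuristicParams(inputWidth = 16L)),
    "empty")
})

test_that("the refined hull covers both true lung fields on the suite", {
  suite <- phantomSuiteCached(20)
  for (i in seq_len(20)) {
    a <- stage1Cached(i)$artifacts
    truth <- suite[[i]]$mask
    lab <- labelComponents(truth)
    for (k in seq_len(max(lab))) {
      lung <- lab == k
      expect_gte(sum(a$hullC1 & lung) / sum(lung), 0.90)
    }
  }
})
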
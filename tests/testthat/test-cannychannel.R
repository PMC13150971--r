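test_that("dual Canny variants share the stretch and scale their variances", {
  ph <- generatePhantom(phantomSpec(seed = 6, size = c(256L, 256L)))
  Id <- enhanceRayleigh(preconditionLog(imgPixels(ph$image)))
  epsD <- localStdEpsilon(Id, c(3, 3))$epsilon
  cp <- cannyPair(Id, epsD)
  expect_identical(dim(cp$canny1), dim(Id))
  expect_gt(sum(cp$canny1), 0); expect_gt(sum(cp$canny2), 0)
  cst <- cannyPair(matrix(0.5, 64, 64), 0.01)
  expect_identical(sum(cst$canny1) + sum(cst$canny2), 0L)
})

test_that("lung Canny extraction uses the hull as a component gate", {
  c1 <- matrix(FALSE, 30, 30); c1[5:9, 5:9] <- TRUE
  c2 <- matrix(FALSE, 30, 30); c2[22:26, 22:26] <- TRUE
  ILX <- matrix(FALSE, 30, 30); ILX[4:10, 4:10] <- TRUE
  r <- extractLungCanny(c1, c2, ILX)
  expect_true(all(!r$CF | (c1 | c2)))
  expect_true(any(r$CF[5:9, 5:9]))
  expect_false(any(r$CF[22:26, 22:26]))   # outside the hull
  expect_warning(e <- extractLungCanny(c1, c2, matrix(FALSE, 30, 30)), "empty")
  expect_identical(sum(e$CF), 0L)
})

test_that("spine and saturation pruning preserve the subset chain", {
  s1 <- stage1Cached(2)
  a <- s1$artifacts
  expect_true(all(!a$ICN | a$CP))
  expect_true(all(!a$CP | a$CF))
  expect_false(any(a$CP & reconstructComponents(a$CF, a$Xm)))
  # no spine/saturation masks: identity
  CF <- matrix(FALSE, 20, 20); CF[3:6, 3:6] <- TRUE
  r <- pruneSpineAndSaturation(CF, matrix(FALSE, 20, 20), matrix(0.2, 20, 20))
  expect_identical(r$CP, CF)
})

test_that("lung separation produces two balanced components on phantoms", {
  s1 <- stage1Cached(1)
  a <- s1$artifacts
  lab <- labelComponents(a$CM)
  expect_gte(max(lab), 2L)
  areas <- sort(tabulate(lab[lab > 0]), decreasing = TRUE)[1:2]
  expect_gte(areas[2] / areas[1], 0.5)
  # arithmetic of the height-adaptive elements
  expect_identical(as.integer(round(800 * 0.006)), 5L)
  expect_identical(as.integer(round(800 * 0.005)), 4L)
  expect_identical(as.integer(round(800 * 0.03)), 24L)
})

test_that("ROI combination builds the abdominal polygon from the box corners", {
  CM <- matrix(FALSE, 100, 100)
  CM[20:70, 10:40] <- TRUE    # left lung box: rows 20-70, cols 10-40
  CM[25:80, 60:95] <- TRUE    # right lung box: rows 25-80, cols 60-95
  ILX <- CM
  r <- combineRois(ILX, CM)
  v <- r$T1poly
  expect_identical(nrow(v), 4L)
  expect_equal(v[1, ], c(x = 95, y = 25 + (80 - 25) / 2))
  expect_equal(v[2, ], c(x = 10, y = 20 + (70 - 20) / 2))
  expect_equal(v[3, ], c(x = 40, y = 70))
  expect_equal(v[4, ], c(x = 60, y = 80))
  expect_true(all(!CM | r$LFfinal))              # CM subset of final
  expect_identical(fillHoles(r$P1 | CM), r$LFfinal)
  # empty CM falls back, recording the degenerate-input warning
  fb <- combineRois(ILX, CM & FALSE, XL = CM, MR = CM)
  expect_match(fb$warnings, "fallback")
  expect_identical(fb$LFfinal, CM)
  z <- combineRois(ILX & FALSE, CM & FALSE)
  expect_match(z$warnings, "fallback")
  expect_identical(sum(z$LFfinal), 0L)
})
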
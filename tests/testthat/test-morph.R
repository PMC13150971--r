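test_that("component reconstruction matches the flood-fill oracle", {
  set.seed(21)
  for (i in 1:25) {
    m <- randomMask(32, 32, 0.35)
    s <- randomMask(32, 32, 0.05)
    got <- reconstructComponents(m, s)
    expect_identical(got, oracleReconstruct(m, s))
    expect_identical(reconstructComponents(got, s), got)  # idempotent
    expect_true(all(!got | m))                            # subset of mask
  }
  m <- matrix(FALSE, 10, 10); m[2:4, 2:4] <- TRUE; m[7:9, 7:9] <- TRUE
  s <- matrix(FALSE, 10, 10); s[3, 3] <- TRUE
  expect_identical(sum(reconstructComponents(m, s)), 9L)
  expect_identical(sum(reconstructComponents(m, matrix(FALSE, 10, 10))), 0L)
  expect_identical(reconstructComponents(m, m | TRUE), m)
  expect_error(reconstructComponents(m, matrix(FALSE, 5, 5)), "shape")
})

test_that("labelling is 8-connected for foreground", {
  z <- matrix(FALSE, 6, 6); z[2, 2] <- TRUE; z[3, 3] <- TRUE; z[5, 5] <- TRUE
  expect_identical(max(labelComponents(z, 8L)), 2L)
  expect_identical(max(labelComponents(z, 4L)), 3L)
})

test_that("hole filling fills 4-connected interior regions and is idempotent", {
  ring <- matrix(FALSE, 20, 20)
  ring[5, 5:15] <- TRUE; ring[15, 5:15] <- TRUE
  ring[5:15, 5] <- TRUE; ring[5:15, 15] <- TRUE
  filled <- fillHoles(ring)
  expect_identical(sum(filled), 11L * 11L)
  expect_identical(fillHoles(filled), filled)
  # border-touching background is not a hole
  open <- ring; open[5, 10] <- FALSE
  expect_identical(fillHoles(open), open)
})

test_that("largest-k keeps components by area", {
  m <- matrix(FALSE, 40, 40)
  m[1:25, 1:20] <- TRUE     # 500
  m[30:34, 30:39] <- TRUE   # 50
  expect_identical(sum(largestComponents(m, 1L)), 500L)
  expect_identical(sum(largestComponents(m, 2L)), 550L)
  expect_identical(sum(largestComponents(m, 5L)), 550L)  # fewer than k exist
})

test_that("convex hull is filled, contains the mask, and is idempotent", {
  rect <- matrix(FALSE, 15, 15); rect[4:10, 5:12] <- TRUE
  expect_identical(convexHullMask(rect), rect)
  tri <- matrix(FALSE, 20, 20)
  tri[cbind(c(3, 17, 17), c(10, 3, 18))] <- TRUE
  h <- convexHullMask(tri)
  expect_true(all(h[tri]))
  expect_gt(sum(h), 100)
  expect_identical(convexHullMask(h), h)
})

test_that("skeletonization thins to one pixel and is stable", {
  blob <- matrix(FALSE, 20, 30); blob[8:12, 4:26] <- TRUE
  sk <- skeletonize(blob)
  expect_true(sum(sk) < sum(blob) / 3)
  # no 2x2 all-true block
  two <- sk[-1, -1] & sk[-nrow(sk), -1] & sk[-1, -ncol(sk)] & sk[-nrow(sk), -ncol(sk)]
  expect_false(any(two))
  expect_identical(skeletonize(sk), sk)
})

test_that("disk morphology via distance transform behaves like its element", {
  m <- matrix(FALSE, 30, 30); m[15, 15] <- TRUE
  d <- morphSuite(m, "dilate", structElem("disk", 11L))
  idx <- which(d, arr.ind = TRUE)
  rad <- sqrt((idx[, 1] - 15)^2 + (idx[, 2] - 15)^2)
  expect_lte(max(rad), 5)
  expect_identical(sum(d), sum(rad <= 5))
  sq <- matrix(FALSE, 30, 30); sq[10:20, 10:20] <- TRUE
  expect_identical(morphSuite(sq, "close", structElem("disk", 7L)), sq)  # convex
  er <- morphSuite(sq, "erode", structElem("square", 3L))
  expect_identical(sum(er), 81L)
  expect_error(morphSuite(sq, "close"), "requires se")
  expect_error(morphSuite(sq, "largest_k"), "requires k")
})

test_that("spur pruning and isolated-pixel cleaning target the right pixels", {
  m <- matrix(FALSE, 12, 12)
  m[6, 3:9] <- TRUE      # line with two endpoints
  m[2, 2] <- TRUE        # isolated
  pr <- pruneSpurs(m, 1L)
  expect_identical(sum(pr), sum(m) - 3L)  # two endpoints + isolated removed
  cl <- cleanIsolated(m)
  expect_false(cl[2, 2]); expect_identical(sum(cl), sum(m) - 1L)
})
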
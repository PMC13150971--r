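test_that("spine band geometry follows the hull centroid arithmetic", {
  hull <- matrix(FALSE, 700, 1024)
  hull[100:600, 213:812] <- TRUE   # width 600, centroid col 512.5
  b <- spineBand(hull)
  cols <- range(which(apply(b, 2, any)))
  expect_equal(diff(cols) + 1L, as.integer(round(2 * 0.15 * 600)))
  expect_lt(abs(mean(cols) - 512.5), 2)
  expect_true(all(b[, cols[1]]))   # spans all rows
  expect_warning(empty <- spineBand(matrix(FALSE, 20, 20)), "empty")
  expect_identical(sum(empty), 0L)
})

test_that("spine skeleton is confined to band and hull", {
  X1 <- randomMask(40, 40, 0.2)
  B1 <- matrix(FALSE, 40, 40); B1[, 15:25] <- TRUE
  hull <- matrix(FALSE, 40, 40); hull[5:35, 5:35] <- TRUE
  X2 <- spineSkeleton(X1, B1, hull)
  expect_true(all(!X2 | (B1 & hull)))
  expect_identical(sum(spineSkeleton(X1, matrix(FALSE, 40, 40), hull)), 0L)
})

test_that("spline fit: exact line, jittered line, sparse fallback", {
  M <- 100; N <- 200
  B1 <- matrix(FALSE, M, N); B1[, 81:120] <- TRUE   # band width 40
  X2 <- matrix(FALSE, M, N); X2[10:90, 100] <- TRUE
  f <- fitSpineSpline(X2, B1)
  expect_true(all(which(f$X3, arr.ind = TRUE)[, 2] == 100))
  xmCols <- range(which(apply(f$Xm, 2, any)))
  expect_lt(diff(xmCols) + 1, 40)                    # narrower than the band
  expect_true(all(f$X3[f$X3] | TRUE))
  # jitter within 3 px: fitted curve stays within 3 px of the centre
  set.seed(8)
  X2j <- matrix(FALSE, M, N)
  X2j[cbind(10:90, 100 + sample(-3:3, 81, TRUE))] <- TRUE
  fj <- fitSpineSpline(X2j, B1)
  expect_true(all(abs(which(fj$X3, arr.ind = TRUE)[, 2] - 100) <= 3))
  # sparse: centreline fallback at half width
  fs <- fitSpineSpline(matrix(FALSE, M, N), B1)
  expect_true(all(fs$X3[, 100]))
  expect_lte(diff(range(which(apply(fs$Xm, 2, any)))) + 1, 21)
})

test_that("spine removal deletes touching components whole and only those", {
  IF <- matrix(FALSE, 30, 30)
  IF[5:10, 5] <- TRUE          # off-spine component
  IF[5:25, 15] <- TRUE         # component crossing the spine model
  Xm <- matrix(FALSE, 30, 30); Xm[14:16, 12:18] <- TRUE
  out <- removeSpine(IF, Xm)
  expect_identical(sum(out), 6L)
  expect_false(any(out & reconstructComponents(IF, Xm)))
  expect_identical(removeSpine(IF, matrix(FALSE, 30, 30)), IF)
})

test_that("spine removal barely touches edge pixels inside the true lungs", {
  suite <- phantomSuiteCached(20)
  for (i in seq_len(20)) {
    a <- stage1Cached(i)$artifacts
    truth <- suite[[i]]$mask
    removed <- reconstructComponents(a$IF, a$Xm)
    inLung <- sum(a$IF & truth)
    if (inLung > 0) expect_lte(sum(removed & truth) / inLung, 0.02)
    # no surviving component intersects the spine model
    expect_false(any(a$ILX & reconstructComponents(a$IF, a$Xm)))
  }
})
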
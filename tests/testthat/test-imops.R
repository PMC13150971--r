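test_that("contrast stretch follows the clamped linear map", {
  x <- matrix(c(0, 0.5, 1, 0.05, 0.5, 0.95, 0.3, 0.3, 0.3), 3, 3)
  expect_equal(contrastStretch(x, 0, 1), x)
  y <- contrastStretch(matrix(c(0.05, 0.5, 0.95), 1, 3)[rep(1, 8), rep(1:3, 3)[1:8]], 0.05, 0.95)
  expect_equal(unique(round(as.numeric(y), 10)), c(0, 0.5, 1))
  expect_true(all(contrastStretch(matrix(0.3, 8, 8), 0.4, 1) == 0))
  expect_error(contrastStretch(matrix(0.3, 8, 8), 0.5, 0.5), "lo < hi")
  # monotone non-decreasing
  v <- sort(runif(50))
  sv <- contrastStretch(matrix(v, 5, 10), 0.2, 0.8)
  expect_true(all(diff(as.numeric(sv)[order(v)]) >= 0))
})

test_that("local std statistic matches the exhaustive window oracle", {
  set.seed(11)
  chk <- matrix(rep(c(0, 1), 8), 4, 4)
  expect_equal(localStdEpsilon(chk)$epsilon, oracleEpsilon(chk), tolerance = 1e-12)
  for (i in 1:5) {
    img <- matrix(runif(16 * 16), 16, 16)
    got <- localStdEpsilon(img)
    expect_equal(got$epsilon, oracleEpsilon(img), tolerance = 1e-12)
    expect_equal(got$m, 8L)
    # scale invariance: std and max both scale
    expect_equal(localStdEpsilon(img * 0.5)$epsilon, got$epsilon, tolerance = 1e-12)
  }
  expect_identical(localStdEpsilon(matrix(0.7, 12, 12))$epsilon, 0)
  # explicit small-window form matches too
  img <- matrix(runif(100), 10, 10)
  expect_equal(localStdEpsilon(img, c(3, 3))$epsilon,
    oracleEpsilon(img, c(3, 3)), tolerance = 1e-12)
})

test_that("histogram valley threshold finds engineered valleys", {
  set.seed(3)
  v <- c(rnorm(4000, 100 / 255, 0.02), rnorm(4000, 200 / 255, 0.02))
  img <- matrix(pmin(pmax(v[1:6400], 0), 1), 80, 80)
  thr <- histogramValleyThreshold(img, c(130, 170))
  expect_gte(thr, 130 / 255); expect_lte(thr, 170 / 255)
  # engineered exact valley: empty bins except a dip at 150
  px <- c(rep(140, 50), rep(150, 5), rep(160, 50), rep(155, 20)) / 255
  img2 <- matrix(rep_len(px, 144), 12, 12)
  expect_equal(histogramValleyThreshold(img2, c(130, 170)) * 255,
    which.min(sapply(0:255, function(b) {
      h <- tabulate(floor(rep_len(px, 144) * 255 + 0.5) + 1, 256)
      hs <- sapply(1:256, function(i) mean(h[max(1, i - 2):min(256, i + 2)]))
      hs[b + 1]
    })[131:171]) + 129)
  expect_equal(histogramValleyThreshold(matrix(0.5, 8, 8), c(130, 170)), 150 / 255)
  expect_error(histogramValleyThreshold(matrix(0.5, 8, 8), c(170, 130)))
})

test_that("adaptive element size follows round(min(M,N) * eps * c) with floor 1", {
  expect_identical(adaptiveSeSize(1024, 1024, 0.01, 6), 61L)
  expect_identical(adaptiveSeSize(512, 900, 0, 3), 1L)
  expect_identical(adaptiveSeSize(1024, 800, 0.02, 0.05), 1L)
  expect_error(adaptiveSeSize(100, 100, -1, 2))
})

test_that("CLAHE honours its degenerate and range contracts", {
  cst <- matrix(0.3, 16, 16)
  expect_identical(claheEnhance(cst, c(5, 5), 0.01, "uniform", 256L), cst)
  ramp <- matrix(seq(0, 1, length.out = 64 * 64), 64, 64)
  eq <- claheEnhance(ramp, c(1, 1), 1, "uniform", 256L)
  expect_lt(max(abs(eq - ramp)), 0.01)   # global equalisation of a uniform ramp
  set.seed(5)
  for (i in 1:10) {
    img <- matrix(runif(32 * 32), 32, 32)
    out <- claheEnhance(img, c(4, 4), 0.01, "rayleigh", 64L, alpha = 0.4)
    expect_true(all(out >= 0 & out <= 1))
  }
  expect_error(claheEnhance(cst, c(5, 5), 0.01, "rayleigh", 256L), "alpha")
})
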
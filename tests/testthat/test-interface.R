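test_that("heuristic parameters validate overrides", {
  p <- heuristicParams(inputWidth = 512L, cLog = 0.5)
  expect_identical(p$inputWidth, 512L)
  expect_identical(p$cLog, 0.5)
  expect_error(heuristicParams(nosuch = 1), "unknown parameters")
  expect_error(heuristicParams(cLog = -1))
})

test_that("PNG image IO round-trips grayscale and rejects colour", {
  d <- withr::local_tempdir()
  img <- matrix(runif(64 * 48), 64, 48)
  f <- file.path(d, "x.png")
  writeGrayPng(img, f)
  back <- readGrayImage(f)
  expect_s4_class(back, "GrayImage")
  expect_lt(max(abs(imgPixels(back) - img)), 1 / 255)
  rgb <- array(runif(32 * 32 * 3), c(32, 32, 3))
  png::writePNG(rgb, file.path(d, "c.png"))
  expect_error(readGrayImage(file.path(d, "c.png")), "colour")
  expect_error(readGrayImage(file.path(d, "missing.png")), "cannot read")
})

test_that("the stage-1 driver degrades gracefully on pathological content", {
  res <- suppressWarnings(
    runStage1(GrayImage(matrix(0, 64, 64)), heuristicParams(inputWidth = 64L)))
  expect_s4_class(res$channels, "ChannelSet")
  expect_identical(sum(channelPlane(res$channels, "pm")), 0)
  expect_gt(length(res$warnings), 0L)
  expect_true(all(dim(res$artifacts$LFfinal) == c(64L, 64L)))
})

test_that("the CLI handles phantom generation, extraction and bad usage", {
  d <- withr::local_tempdir()
  expect_identical(lungfuseCli(character()), 1L)
  expect_identical(lungfuseCli("nonsense"), 1L)
  expect_identical(suppressMessages(lungfuseCli(c("extract"))), 2L)
  pd <- file.path(d, "ph")
  expect_identical(suppressMessages(lungfuseCli(
    c("phantom", "--n", "1", "--seed", "5", "--family", "A", "--outdir", pd))), 0L)
  expect_true(file.exists(file.path(pd, "images", "A001.png")))
  expect_true(file.exists(file.path(pd, "masks", "A001.png")))
  cfgFile <- file.path(d, "cfg.json")
  jsonlite::write_json(list(inputWidth = 256L), cfgFile, auto_unbox = TRUE)
  od <- file.path(d, "chan")
  expect_identical(suppressMessages(lungfuseCli(
    c("extract", "--input", file.path(pd, "images"), "--outdir", od,
      "--config", cfgFile))), 0L)
  expect_true(file.exists(file.path(od, "A001", "pm.png")))
  expect_true(file.exists(file.path(od, "A001", "manifest.json")))
})
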
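# Session-level cache of stage-1 runs on the seeded phantom suites, shared
# across test files so the heavy pipeline runs once per phantom.
.stage1Cache <- new.env(parent = emptyenv())

phantomSuiteCached <- function(n, family = "A") {
  key <- paste0("suite_", family, "_", n)
  if (is.null(.stage1Cache[[key]]))
    .stage1Cache[[key]] <- generateSuite(n, baseSeed = 1, family = family)
  .stage1Cache[[key]]
}

stage1Cached <- function(i, family = "A", n = 20) {
  key <- paste0("s1_", family, "_", i)
  if (is.null(.stage1Cache[[key]])) {
    ph <- phantomSuiteCached(n, family)[[i]]
    .stage1Cache[[key]] <- runStage1(ph$image, heuristicParams(inputWidth = 512L))
  }
  .stage1Cache[[key]]
}

# small random ChannelSet + mask items for harness plumbing tests
randomItems <- function(k, seed = 1) {
  lungfuse:::.withSeed(seed, lapply(seq_len(k), function(i) {
    pl <- function() matrix(stats::runif(256 * 256), 256, 256)
    mask <- matrix(FALSE, 256, 256)
    r0 <- sample(40:160, 1)
    mask[r0:(r0 + 60), 60:200] <- TRUE
    list(channels = ChannelSet(pl(), pl() > 0.5, pl() > 0.5, pl() > 0.5,
      mask * 1), mask = mask)
  }))
}
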
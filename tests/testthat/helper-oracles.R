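# Independent brute-force oracles. These deliberately avoid the package's
# own implementations: components are found by queue-based flood fill,
# local statistics by explicit double loops.

# 8-connected components by BFS flood fill; returns integer label matrix
oracleLabel8 <- function(mask) {
  M <- nrow(mask); N <- ncol(mask)
  lab <- matrix(0L, M, N)
  cur <- 0L
  for (r0 in seq_len(M)) for (c0 in seq_len(N)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    cur <- cur + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= M && c >= 1 && c <= N &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# union of mask components touching seed (the reconstruction contract)
oracleReconstruct <- function(mask, seed) {
  lab <- oracleLabel8(mask)
  keep <- unique(lab[seed & mask])
  keep <- keep[keep > 0L]
  matrix(lab %in% keep, nrow(mask))
}

# exhaustive windowed population-std statistic
oracleEpsilon <- function(img, window = NULL) {
  M <- nrow(img); N <- ncol(img)
  if (is.null(window)) window <- c(round(0.5 * M), round(0.5 * N))
  m <- max(1L, window[1]); n <- max(1L, window[2])
  if (max(img) == 0) return(0)
  up <- floor((m - 1) / 2); dn <- m - 1 - up
  lf <- floor((n - 1) / 2); rt <- n - 1 - lf
  acc <- 0
  for (x in seq_len(M)) for (y in seq_len(N)) {
    w <- img[max(1, x - up):min(M, x + dn), max(1, y - lf):min(N, y + rt)]
    mu <- mean(w)
    acc <- acc + sqrt(mean((w - mu)^2))
  }
  acc / (M * N) / max(img)
}

randomMask <- function(M, N, p = 0.4) matrix(stats::runif(M * N) < p, M, N)
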
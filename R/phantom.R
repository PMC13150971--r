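# Seeded synthetic posteroanterior chest-radiograph phantom. The phantom
# carries the anatomical structure the heuristic stage exploits -- a bright
# body blob on dark background, two dark elliptical lung fields, a bright
# central spine band, rib arcs, clavicles and an optional corner label --
# together with the paired ground-truth lung mask (the union of the two lung
# ellipses, recorded before noise is added).

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Phantom specification
#'
#' Geometry and intensity parameters of the synthetic chest radiograph. All
#' intensities are in \[0, 1\]; geometry is in fractions of the image size so
#' a spec renders consistently at any resolution. Defaults emulate a typical
#' adult PA film: a bright body (about 0.75) on a dark background, lung
#' fields around 0.25, a spine band around 0.9, rib arcs around 0.65 and
#' additive Gaussian noise with sigma 0.02.
#'
#' @param size integer pair (rows, cols).
#' @param bodyIntensity,lungIntensity,spineIntensity,ribIntensity intensities.
#' @param spineWidthFrac spine band width as a fraction of image width.
#' @param spineBow lateral sinusoidal bow amplitude (fraction of width).
#' @param nRibs rib arcs per side.
#' @param ribThickness rib stroke thickness in pixels (at 512 width).
#' @param label logical, render a bright corner text-label artifact.
#' @param noiseSigma additive Gaussian noise standard deviation.
#' @param gain,offset global contrast jitter applied after rendering.
#' @param jitter relative geometry jitter applied per seed.
#' @param seed integer RNG seed.
#' @return object of class \code{PhantomSpec} (named list).
#' @export
phantomSpec <- function(size = c(512L, 512L), bodyIntensity = 0.75,
                        lungIntensity = 0.25, spineIntensity = 0.9,
                        ribIntensity = 0.65, spineWidthFrac = 0.12,
                        spineBow = 0.01, nRibs = 7L, ribThickness = 3,
                        label = TRUE, noiseSigma = 0.02, gain = 1,
                        offset = 0, jitter = 0.03, seed = 1L) {
  spec <- list(size = as.integer(size), bodyIntensity = bodyIntensity,
    lungIntensity = lungIntensity, spineIntensity = spineIntensity,
    ribIntensity = ribIntensity, spineWidthFrac = spineWidthFrac,
    spineBow = spineBow, nRibs = as.integer(nRibs),
    ribThickness = ribThickness, label = isTRUE(label),
    noiseSigma = noiseSigma, gain = gain, offset = offset,
    jitter = jitter, seed = as.integer(seed))
  class(spec) <- "PhantomSpec"
  spec
}

.ellipseMask <- function(M, N, cy, cx, a, b, theta = 0) {
  # cy, cx in rows/cols; a = row semi-axis, b = col semi-axis
  Y <- matrix(seq_len(M), M, N)
  X <- matrix(seq_len(N), M, N, byrow = TRUE)
  dy <- Y - cy; dx <- X - cx
  u <- dy * cos(theta) + dx * sin(theta)
  v <- -dy * sin(theta) + dx * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Render a phantom chest radiograph with ground truth
#'
#' Renders background, body, lungs, spine, ribs, clavicles and the optional
#' corner label in that order, applies the global contrast jitter, adds
#' Gaussian noise and clamps to \[0, 1\]. The ground-truth lung mask is the
#' union of the two (pre-noise) lung ellipses. Deterministic under a fixed
#' \code{spec$seed}.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return list with \code{image} (\linkS4class{GrayImage}), \code{mask}
#'   (logical lung-field ground truth) and \code{body} (logical body-ellipse
#'   mask, useful for coverage checks).
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  .withSeed(spec$seed, {
    M <- spec$size[1]; N <- spec$size[2]
    jit <- function(x) x * (1 + stats::runif(1, -spec$jitter, spec$jitter))
    img <- matrix(0.08, M, N)

    bodyCy <- jit(0.53) * M; bodyCx <- jit(0.50) * N
    bodyA <- jit(0.47) * M; bodyB <- jit(0.42) * N
    body <- .ellipseMask(M, N, bodyCy, bodyCx, bodyA, bodyB)
    img[body] <- spec$bodyIntensity

    lungA <- jit(0.25) * M; lungB <- jit(0.115) * N
    lungCy <- jit(0.46) * M
    tilt <- jit(7) * pi / 180
    lungR <- .ellipseMask(M, N, lungCy, bodyCx - jit(0.205) * N, lungA, lungB, -tilt)
    lungL <- .ellipseMask(M, N, lungCy, bodyCx + jit(0.205) * N, lungA, lungB, tilt)
    if (any(lungR & !body) || any(lungL & !body))
      stop("invalid geometry: lung ellipse extends outside the body")
    truth <- lungR | lungL
    img[truth] <- spec$lungIntensity

    halfW <- spec$spineWidthFrac * N / 2
    bow <- spec$spineBow * N * sin(seq_len(M) / M * pi + stats::runif(1, 0, pi))
    colIdx <- matrix(seq_len(N), M, N, byrow = TRUE)
    ctr <- matrix(bodyCx + bow, M, N)
    spine <- abs(colIdx - ctr) <= halfW & body
    img[spine] <- spec$spineIntensity

    # rib arcs: parabolic stripes curving downward away from the spine
    rowIdx <- matrix(seq_len(M), M, N)
    ribs <- matrix(FALSE, M, N)
    tk <- spec$ribThickness * N / 512
    for (side in c(-1, 1)) {
      lung <- if (side < 0) lungR else lungL
      span <- range(which(apply(lung, 1, any)))
      for (k in seq_len(spec$nRibs)) {
        r0 <- span[1] + (k - 0.5) * diff(span) / spec$nRibs
        dcol <- (colIdx - bodyCx) * side
        line <- r0 + 0.0022 * 512 / M * dcol^2 - 0.06 * dcol
        hit <- abs(rowIdx - line) <= tk / 2 & dcol > halfW * 0.5 &
          dcol < 0.36 * N & body
        ribs <- ribs | hit
      }
    }
    img[ribs] <- pmax(img[ribs], spec$ribIntensity)

    # clavicles: slanted bright strokes across the apices
    for (side in c(-1, 1)) {
      dcol <- (colIdx - bodyCx) * side
      line <- (lungCy - lungA) + 0.10 * dcol
      hit <- abs(rowIdx - line) <= tk & dcol > 0 & dcol < 0.30 * N & body
      img[hit] <- pmax(img[hit], 0.8)
    }

    if (spec$label) {
      r0 <- round(0.03 * M); c0 <- round(0.86 * N)
      for (g in 0:2) {
        rr <- (r0 + 1):(r0 + round(0.045 * M))
        cc <- (c0 + g * round(0.035 * N) + 1):(c0 + g * round(0.035 * N) + round(0.02 * N))
        cc <- cc[cc <= N]
        img[rr, cc] <- 1.0
      }
    }

    img <- img * spec$gain + spec$offset
    img <- img + stats::rnorm(M * N, 0, spec$noiseSigma)
    img <- clamp01(img)
    list(image = GrayImage(img, 8L), mask = truth, body = body)
  })
}

#' Generate a phantom suite
#'
#' \code{n} phantoms with per-seed geometry and contrast jitter. Families A
#' and B differ in contrast, noise level and rib prominence, emulating two
#' imaging protocols for cross-dataset experiments: family B is flatter
#' (lower gain, positive offset), noisier and has brighter ribs.
#'
#' @param n number of phantoms (>= 1).
#' @param baseSeed integer; phantom i uses seed \code{baseSeed * 1000 + i}.
#' @param family "A" or "B".
#' @return list of \code{list(image, mask, id)}.
#' @export
generateSuite <- function(n, baseSeed = 1L, family = c("A", "B")) {
  family <- match.arg(family)
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    seed <- as.integer(baseSeed) * 1000L + i +
      if (family == "B") 500000L else 0L
    spec <- if (family == "A") {
      phantomSpec(seed = seed)
    } else {
      phantomSpec(seed = seed, gain = 0.8, offset = 0.12,
        noiseSigma = 0.035, ribIntensity = 0.75)
    }
    ph <- generatePhantom(spec)
    ph$id <- sprintf("%s%03d", family, i)
    ph
  })
}
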
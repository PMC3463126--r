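flatTrack <- function(values, contig = "chr1", reads = NULL) {
  pos <- seq_along(values) - 1
  keep <- values != 0
  sv <- sparseVector0(pos[keep], values[keep])
  new("CoverageTrack", contigLengths = stats::setNames(length(values), contig),
      forward = stats::setNames(list(sv), contig),
      reverse = stats::setNames(list(sparseVector0()), contig),
      total = stats::setNames(list(sv), contig),
      mismatch = stats::setNames(list(sparseVector0()), contig),
      readsCounted = if (is.null(reads)) max(1, round(sum(values))) else reads,
      normalized = FALSE)
}

test_that("signal preparation cancels a matched control and conserves mass", {
  set.seed(71)
  v <- stats::rpois(500, 3)
  tr <- flatTrack(v)
  sameSig <- prepareSignal(tr, control = tr, binSize = 5)[["chr1"]]
  expect_true(all(sameSig@values == 0))      # exact cancellation

  ident <- prepareSignal(tr, binSize = 1, kernel = "none",
                         normalize = FALSE)[["chr1"]]
  expect_equal(ident@values, as.numeric(v))  # identity path

  imp <- numeric(401); imp[201] <- 1
  sm <- prepareSignal(flatTrack(imp, reads = 1), binSize = 1,
                      kernel = "gaussian", bandwidth = 4,
                      normalize = FALSE)[["chr1"]]
  expect_equal(sum(sm@values), 1, tolerance = 1e-9)   # kernel mass 1
  expect_equal(sm@values[201 + 1:10], sm@values[201 - 1:10])  # symmetry
  expect_equal(which.max(sm@values), 201)

  empty <- flatTrack(numeric(10), reads = 0)
  empty@readsCounted <- 0
  expect_error(prepareSignal(empty), "zero reads")
})

test_that("the transform is translation invariant with zero preserved", {
  zero <- new("SmoothedTrack", contig = "c", binSize = 1,
              values = numeric(300), raw = numeric(0), kernel = "none")
  cw0 <- suppressWarnings(cwtScales(zero, scales = c(4, 16)))
  expect_true(all(vapply(cw0$coefficients, function(x) all(x == 0), TRUE)))

  set.seed(72)
  base <- pmax(stats::rnorm(600, 5), 0)
  k <- 23
  shifted <- c(base[(k + 1):600], base[1:k])   # cyclic shift by -k
  s1 <- new("SmoothedTrack", contig = "c", binSize = 1, values = base,
            raw = numeric(0), kernel = "none")
  s2 <- new("SmoothedTrack", contig = "c", binSize = 1, values = shifted,
            raw = numeric(0), kernel = "none")
  c1 <- cwtScales(s1, scales = c(4, 8, 16))
  c2 <- cwtScales(s2, scales = c(4, 8, 16))
  interior <- 150:350                          # away from both boundaries
  for (j in 1:3) {
    expect_equal(c2$coefficients[[j]][interior],
                 c1$coefficients[[j]][interior + k], tolerance = 1e-10)
  }
  expect_warning(cwtScales(s1, scales = c(4, 1000)), "exceeding")
})

test_that("scale response to a Gaussian bump peaks where theory says", {
  sigma <- 20
  x <- exp(-((1:4000) - 2000)^2 / (2 * sigma^2))
  sig <- new("SmoothedTrack", contig = "c", binSize = 1, values = x,
             raw = numeric(0), kernel = "none")
  scales <- 2^(1:10)
  cw <- cwtScales(sig, scales = scales)
  got <- vapply(cw$coefficients, function(co) co[2000], 0)
  # closed-form response of the normalized Ricker to a Gaussian bump
  theory <- vapply(scales, function(s) {
    a2 <- s^2 * sigma^2 / (s^2 + sigma^2)
    sqrt(2 * pi) * sqrt(a2) * (1 - a2 / s^2) / s
  }, 0)
  expect_identical(which.max(got), which.max(theory))
  expect_equal(scales[which.max(got)], 32)     # nearest to sqrt(2)*sigma
  # matched coefficient is scale independent: compare two matched pairs
  for (sigma2 in c(40, 80)) {
    x2 <- exp(-((1:4000) - 2000)^2 / (2 * sigma2^2))
    sig2 <- new("SmoothedTrack", contig = "c", binSize = 1, values = x2,
                raw = numeric(0), kernel = "none")
    cwm <- cwtScales(sig2, scales = sqrt(2) * sigma2)
    cwm1 <- cwtScales(sig, scales = sqrt(2) * sigma)
    expect_equal(cwm$coefficients[[1]][2000], cwm1$coefficients[[1]][2000],
                 tolerance = 1e-3)
  }
})

test_that("per-scale maxima match a brute-force windowed argmax oracle", {
  mono <- new("SmoothedTrack", contig = "c", binSize = 1,
              values = as.numeric(1:50), raw = numeric(0), kernel = "none")
  cwMono <- list(scalesBases = 4, scalesBins = 4,
                 coefficients = list(as.numeric(1:50)), binSize = 1, n = 50)
  expect_length(findScaleMaxima(cwMono)[[1]]$positions, 0)

  imp <- numeric(50); imp[25] <- 3
  cwImp <- list(scalesBases = 4, scalesBins = 4, coefficients = list(imp),
                binSize = 1, n = 50)
  expect_identical(findScaleMaxima(cwImp)[[1]]$positions, 25L)

  set.seed(73)
  for (trial in 1:15) {
    x <- round(stats::rnorm(120), 1)            # ties likely at 1 decimal
    s <- sample(c(2, 5, 9), 1)
    cw <- list(scalesBases = s, scalesBins = s, coefficients = list(x),
               binSize = 1, n = length(x))
    got <- findScaleMaxima(cw, minSeparationFactor = 1)[[1]]$positions
    w <- max(3, round(s)); half <- w %/% 2
    want <- integer(0)
    for (i in (half + 1):(length(x) - half)) {
      left <- x[(i - half):(i - 1)]; right <- x[(i + 1):(i + half)]
      if (all(x[i] > left) && all(x[i] >= right)) want <- c(want, i)
    }
    expect_identical(got, want)
  }
})

test_that("ridge linking chains constant positions and seeds singletons", {
  lvl <- function(s, pos, coef = rep(1, length(pos)))
    list(scaleBases = s, scaleBins = s, positions = pos,
         coefficients = coef, noise = 1)
  allScales <- lapply(c(32, 16, 8, 4), function(s) lvl(s, 100L))
  r <- linkRidges(allScales)
  expect_length(r, 1)
  expect_identical(r[[1]]$length, 4L)
  expect_identical(r[[1]]$summit, 100)

  oneScale <- list(lvl(16, c(10L, 40L)), lvl(8, integer(0)))
  r2 <- linkRidges(oneScale)
  expect_identical(sort(vapply(r2, `[[`, 0L, "length")), c(1L, 1L))
})

test_that("greedy linking equals the exhaustive-assignment oracle", {
  set.seed(74)
  for (trial in 1:60) {
    inst <- randomMaximaInstance(sample(2:4, 1))
    got <- ridgeSignatures(linkRidges(inst, gapTolerance = 1,
                                      positionToleranceFactor = 1.5))
    want <- oracleLinkRidges(inst, gapTolerance = 1, posTolFactor = 1.5)
    expect_identical(got, want)
  }
})

test_that("planted peaks are called with accurate summits and bounds", {
  expect_identical(nrow(callPeaks(
    new("SmoothedTrack", contig = "c", binSize = 10, values = numeric(100),
        raw = numeric(100), kernel = "none"), list())), 0L)

  pt <- makePeakTrack(60000, data.frame(center = 30000, width = 100,
                                        amplitude = 50),
                      noiseRate = 0, seed = 75)
  peaks <- suppressWarnings(waveletPeakCall(pt$track, minSignal = 5))
  expect_identical(nrow(peaks), 1L)
  expect_lt(abs(peaks$summit - 30000), 50)     # within sigma/2
  expect_true(peaks$start <= 30000 && peaks$end > 30000)
})

test_that("the spike filter removes single-bin spikes and only those", {
  sp <- makePeakTrack(20000, data.frame(center = 10000, width = 0.5,
                                        amplitude = 1000),
                      noiseRate = 0.5, seed = 76)
  on <- suppressWarnings(waveletPeakCall(sp$track))
  off <- suppressWarnings(waveletPeakCall(sp$track, maxSpikeSharpness = 0))
  expect_identical(nrow(on), 0L)
  expect_identical(nrow(off), 1L)
  expect_identical(off$filteredReason, "none")
  expect_lt(abs(off$summit - 10000), 20)

  wide <- makePeakTrack(20000, data.frame(center = 10000, width = 150,
                                          amplitude = 20),
                        noiseRate = 0.5, seed = 77)
  expect_identical(nrow(suppressWarnings(waveletPeakCall(wide$track))), 1L)
})

test_that("peak calls are invariant to translation and amplitude", {
  lay <- data.frame(center = c(30000, 70000), width = c(100, 300),
                    amplitude = c(10, 8))
  a <- makePeakTrack(150000, lay, noiseRate = 1, seed = 78)$track
  k <- 37                                       # whole bins at binSize 10
  sv <- a@total[["chr1"]]
  b <- a
  b@total[["chr1"]] <- sparseVector0(sv@pos + k * 10, sv@val)
  b@forward[["chr1"]] <- b@total[["chr1"]]
  b@contigLengths[["chr1"]] <- a@contigLengths[["chr1"]] + k * 10
  pa <- suppressWarnings(waveletPeakCall(a))
  pb <- suppressWarnings(waveletPeakCall(b))
  expect_identical(sort(pa$summit) + k * 10, sort(pb$summit))

  scaled <- scaleTrack(a, 7)
  scaled@readsCounted <- a@readsCounted
  p1 <- suppressWarnings(waveletPeakCall(a, normalize = FALSE))
  p7 <- suppressWarnings(waveletPeakCall(scaled, normalize = FALSE))
  expect_identical(p1$summit, p7$summit)        # same order, same summits
  expect_identical(p1$ridgeLength, p7$ridgeLength)
})

test_that("isolation lengthens ridges relative to a crowded twin", {
  iso <- makePeakTrack(60000, data.frame(center = 30000, width = 200,
                                         amplitude = 10),
                       noiseRate = 0, seed = 1)$track
  fwhm <- 2 * sqrt(2 * log(2)) * 200
  crw <- makePeakTrack(60000,
                       data.frame(center = c(30000 - 1.5 * fwhm, 30000),
                                  width = 200, amplitude = 10),
                       noiseRate = 0, seed = 1)$track
  pi <- suppressWarnings(waveletPeakCall(iso, minSignal = 1))
  pc <- suppressWarnings(waveletPeakCall(crw, minSignal = 1))
  ri <- pi$ridgeLength[which.min(abs(pi$summit - 30000))]
  rc <- pc$ridgeLength[which.min(abs(pc$summit - 30000))]
  expect_gt(ri, rc)
})

test_that("the Gaussian single-scale caller resolves by bandwidth", {
  flat <- new("SmoothedTrack", contig = "c", binSize = 10,
              values = rep(2, 500), raw = rep(2, 500), kernel = "none")
  expect_identical(nrow(gaussianSmoothPeaks(flat, 50, minSignal = 5)), 0L)

  one <- makePeakTrack(30000, data.frame(center = 15000, width = 150,
                                         amplitude = 20),
                       noiseRate = 0, seed = 79)
  sig <- prepareSignal(one$track, kernel = "none")[["chr1"]]
  p1 <- gaussianSmoothPeaks(sig, 100, minSignal = 1)
  expect_identical(nrow(p1), 1L)
  expect_lt(abs(p1$summit - 15000), 100)

  two <- makePeakTrack(30000,
                       data.frame(center = c(10000, 20000), width = 150,
                                  amplitude = 20), noiseRate = 0, seed = 80)
  sig2 <- prepareSignal(two$track, kernel = "none")[["chr1"]]
  expect_identical(nrow(gaussianSmoothPeaks(sig2, 100, minSignal = 1)), 2L)
  # bandwidth far above the separation merges the pair
  close2 <- makePeakTrack(30000,
                          data.frame(center = c(14800, 15200), width = 150,
                                     amplitude = 20), noiseRate = 0, seed = 81)
  sig3 <- prepareSignal(close2$track, kernel = "none")[["chr1"]]
  expect_identical(nrow(gaussianSmoothPeaks(sig3, 2000, minSignal = 0.01)), 1L)
})
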
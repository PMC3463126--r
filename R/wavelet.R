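# Multiscale wavelet peak calling for ChIP-seq style coverage:
# kernel-smoothed sample/control signal, dense (undecimated, hence
# translation-invariant) Ricker wavelet transform over a dyadic scale
# grid, per-scale local maxima, greedy ridge-line linking across scales,
# and ranking by ridge length.  Peaks persisting over many scales are
# well-formed and isolated; low-signal and spike filters are optional.

# symmetric convolution with reflective boundary handling
.convReflect <- function(x, kernel) {
  n <- length(x)
  h <- (length(kernel) - 1L) %/% 2L
  if (h == 0) return(x * kernel)
  idx <- c(rev(seq_len(min(h, n))), seq_len(n), n + 1L - rev(seq_len(min(h, n))))
  while (length(idx) < n + 2L * h) {        # tiny signals: repeat reflection
    idx <- c(idx[1], idx, idx[length(idx)])
  }
  xp <- x[idx]
  out <- stats::filter(xp, kernel, method = "convolution", sides = 2)
  as.numeric(out[(h + 1L):(h + n)])
}

.gaussKernel <- function(sigmaBins) {
  half <- max(1L, ceiling(4 * sigmaBins))
  t <- seq(-half, half)
  k <- exp(-t^2 / (2 * sigmaBins^2))
  k / sum(k)
}

.boxKernel <- function(widthBins) {
  w <- max(1L, 2L * floor(widthBins / 2) + 1L)   # odd-ified
  rep(1 / w, w)
}

#' Ricker (Mexican-hat) wavelet sampled at integer offsets
#' @param sigmaBins wavelet scale in bins.
#' @return numeric kernel over offsets -ceil(5*sigma)..ceil(5*sigma).
#' @export
rickerKernel <- function(sigmaBins) {
  half <- max(1L, ceiling(5 * sigmaBins))
  t <- seq(-half, half)
  (1 - (t / sigmaBins)^2) * exp(-t^2 / (2 * sigmaBins^2))
}

.binTrack <- function(track, contig, binSize) {
  len <- track@contigLengths[[contig]]
  nBins <- ceiling(len / binSize)
  sv <- track@total[[contig]]
  out <- numeric(nBins)
  if (length(sv@pos)) {
    w <- floor(sv@pos / binSize)
    keep <- w < nBins
    agg <- rowsum(sv@val[keep], group = w[keep])
    out[as.numeric(rownames(agg)) + 1] <- agg[, 1]
  }
  out
}

#' Binned, normalized, background-corrected, kernel-smoothed signal
#'
#' Coverage is summed within bins of \code{binSize} bases, each track is
#' normalized to reads per million, the control (when given) is
#' subtracted from the sample and negatives floored at 0, and the result
#' is kernel smoothed.  The pre-kernel values are kept in the
#' \code{raw} slot for the spike filter.
#'
#' @param sample a \linkS4class{CoverageTrack}.
#' @param control optional background \linkS4class{CoverageTrack}.
#' @param binSize bases per bin, >= 1.
#' @param kernel "gaussian", "box" or "none".
#' @param bandwidth kernel width in bases: the Gaussian sigma or the box
#'   width.
#' @param normalize reads-per-million normalize before combining
#'   (requires \code{readsCounted > 0} in each track).
#' @return named list of \linkS4class{SmoothedTrack}, one per contig of
#'   \code{sample}.
#' @export
prepareSignal <- function(sample, control = NULL, binSize = 10,
                          kernel = c("gaussian", "box", "none"),
                          bandwidth = 40, normalize = TRUE) {
  kernel <- match.arg(kernel)
  stopifnot(binSize >= 1)
  if (normalize && sample@readsCounted == 0) {
    stop("sample track has zero reads; cannot normalize")
  }
  if (normalize && !is.null(control) && control@readsCounted == 0) {
    stop("control track has zero reads; cannot normalize")
  }
  k <- switch(kernel,
              gaussian = .gaussKernel(bandwidth / binSize),
              box = .boxKernel(bandwidth / binSize),
              none = NULL)
  desc <- switch(kernel, gaussian = sprintf("gaussian(%g)", bandwidth),
                 box = sprintf("box(%g)", bandwidth), none = "none")
  out <- lapply(names(sample@contigLengths), function(contig) {
    x <- .binTrack(sample, contig, binSize)
    if (normalize) x <- x * 1e6 / sample@readsCounted
    if (!is.null(control) && contig %in% names(control@contigLengths)) {
      y <- .binTrack(control, contig, binSize)
      if (normalize) y <- y * 1e6 / control@readsCounted
      length(y) <- length(x); y[is.na(y)] <- 0
      x <- pmax(x - y, 0)
    }
    raw <- x
    if (!is.null(k) && length(x)) x <- pmax(.convReflect(x, k), 0)
    new("SmoothedTrack", contig = contig, binSize = binSize, values = x,
        raw = raw, kernel = desc)
  })
  names(out) <- names(sample@contigLengths)
  out
}

#' Dense continuous wavelet transform over a scale grid
#'
#' Convolves the signal with a Ricker wavelet at every scale, dividing
#' by the scale so that a Gaussian bump of matched width (sigma =
#' scale/sqrt(2) bins) yields a scale-independent coefficient.  The
#' transform is evaluated at every bin (undecimated), so shifting the
#' input by k bins shifts every coefficient array by k bins; boundaries
#' are handled by reflection.  Scales wider than the signal are skipped
#' with a warning.
#'
#' @param signal a \linkS4class{SmoothedTrack}.
#' @param scales scale grid in bases; default dyadic 2,4,...,1024.
#'   Scales below one bin are dropped.
#' @return list with \code{scalesBases}, \code{scalesBins} and
#'   \code{coefficients} (one array per scale, same length as the
#'   signal).
#' @export
cwtScales <- function(signal, scales = NULL) {
  if (is.null(scales)) scales <- 2^(1:10)
  stopifnot(all(scales > 0), !is.unsorted(scales))
  sBins <- scales / signal@binSize
  keep <- sBins >= 1
  if (any(!keep)) {
    warning(sum(!keep), " scale(s) below one bin dropped")
  }
  n <- length(signal@values)
  usable <- keep & sBins <= n
  if (any(keep & !usable)) {
    warning(sum(keep & !usable), " scale(s) exceeding signal length skipped")
  }
  coefs <- lapply(which(usable), function(i) {
    .convReflect(signal@values, rickerKernel(sBins[i])) / sBins[i]
  })
  list(scalesBases = scales[usable], scalesBins = sBins[usable],
       coefficients = coefs, binSize = signal@binSize, n = n)
}

#' Per-scale local maxima of the wavelet coefficients
#'
#' At scale s, a position is reported when it is the strict maximum of a
#' sliding window of \code{max(3, round(minSeparationFactor * s))} bins
#' (strictly greater than everything left of it in the window,
#' greater-or-equal to everything right: plateau ties go to the leftmost
#' bin).  Positions whose window would run off either edge are not
#' eligible.
#'
#' @param cwt output of \code{\link{cwtScales}}.
#' @param minSeparationFactor window width as a multiple of the scale in
#'   bins.
#' @return list of per-scale records (scaleBases, scaleBins, positions
#'   as 1-based bin indices, coefficients), ordered by descending scale.
#' @export
findScaleMaxima <- function(cwt, minSeparationFactor = 1) {
  out <- lapply(rev(seq_along(cwt$scalesBins)), function(k) {
    s <- cwt$scalesBins[k]
    x <- cwt$coefficients[[k]]
    n <- length(x)
    w <- max(3, round(minSeparationFactor * s))
    half <- w %/% 2
    pos <- integer(0)
    if (n >= 3) {
      cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
      cand <- cand[cand > half & cand <= n - half]
      for (i in cand) {
        left <- x[(i - half):(i - 1)]
        right <- x[(i + 1):(i + half)]
        if (all(x[i] > left) && all(x[i] >= right)) pos <- c(pos, i)
      }
    }
    list(scaleBases = cwt$scalesBases[k], scaleBins = s, positions = pos,
         coefficients = x[pos], noise = stats::mad(x))
  })
  out
}

#' Link per-scale maxima into ridge lines
#'
#' Greedy linking from the largest scale down.  At each scale, active
#' ridges (ordered by current coefficient desc, then current length
#' desc, then position asc) each claim the nearest unclaimed maximum
#' within \code{positionToleranceFactor * currentScaleBins} bins
#' (distance ties to the smaller position).  A ridge failing to extend
#' accrues a gap; more than \code{gapTolerance} consecutive gaps
#' terminates it (a successful link resets the counter).  Maxima left
#' unclaimed seed new ridges, so every maximum belongs to exactly one
#' ridge.
#'
#' @param maxima output of \code{\link{findScaleMaxima}} (descending
#'   scale order).
#' @param gapTolerance maximum consecutive scales a ridge may skip.
#' @param positionToleranceFactor link radius as a multiple of the
#'   ridge's current scale (bins).
#' @return list of ridge lines; each has \code{points} (data.frame
#'   scaleBases/scaleBins/pos/coef from largest to smallest scale),
#'   \code{length}, \code{summit} (bin at the smallest scale),
#'   \code{bestScale} (bases, at the maximal coefficient) and
#'   \code{maxCoef}.
#' @export
linkRidges <- function(maxima, gapTolerance = 2, positionToleranceFactor = 1) {
  active <- list()
  done <- list()
  for (lvl in maxima) {
    avail <- rep(TRUE, length(lvl$positions))
    if (length(active)) {
      ord <- order(-vapply(active, `[[`, 0, "lastCoef"),
                   -vapply(active, `[[`, 0L, "len"),
                   vapply(active, `[[`, 0, "lastPos"), method = "radix")
      surviving <- list()
      for (r in active[ord]) {
        tol <- positionToleranceFactor * r$lastScaleBins
        cand <- which(avail & abs(lvl$positions - r$lastPos) <= tol)
        if (length(cand)) {
          d <- abs(lvl$positions[cand] - r$lastPos)
          pick <- cand[order(d, lvl$positions[cand], method = "radix")[1]]
          avail[pick] <- FALSE
          r$points[[length(r$points) + 1L]] <-
            c(scaleBases = lvl$scaleBases, scaleBins = lvl$scaleBins,
              pos = lvl$positions[pick], coef = lvl$coefficients[pick],
              noise = lvl$noise)
          r$lastPos <- lvl$positions[pick]
          r$lastCoef <- lvl$coefficients[pick]
          r$lastScaleBins <- lvl$scaleBins
          r$len <- r$len + 1L
          r$gaps <- 0L
          surviving[[length(surviving) + 1L]] <- r
        } else {
          r$gaps <- r$gaps + 1L
          if (r$gaps > gapTolerance) done[[length(done) + 1L]] <- r
          else surviving[[length(surviving) + 1L]] <- r
        }
      }
      active <- surviving
    }
    for (j in which(avail)) {            # unclaimed maxima seed new ridges
      active[[length(active) + 1L]] <- list(
        points = list(c(scaleBases = lvl$scaleBases,
                        scaleBins = lvl$scaleBins,
                        pos = lvl$positions[j], coef = lvl$coefficients[j],
                        noise = lvl$noise)),
        lastPos = lvl$positions[j], lastCoef = lvl$coefficients[j],
        lastScaleBins = lvl$scaleBins, len = 1L, gaps = 0L)
    }
  }
  done <- c(done, active)
  lapply(done, function(r) {
    pts <- as.data.frame(do.call(rbind, r$points))
    best <- which.max(pts$coef)
    list(points = pts, length = nrow(pts), summit = pts$pos[nrow(pts)],
         bestScale = pts$scaleBases[best], bestScaleBins = pts$scaleBins[best],
         maxCoef = pts$coef[best],
         bestNoise = if ("noise" %in% names(pts)) pts$noise[best] else NA_real_)
  })
}

.halfMaxBounds <- function(values, summit, minSignal, capBins) {
  height <- values[summit]
  half <- height / 2
  n <- length(values)
  left <- summit
  while (left > 1 && summit - (left - 1) <= capBins) {
    v <- values[left - 1]
    if (v < half) break
    if (v < minSignal && left - 2 >= 1 && values[left - 2] > v) break
    left <- left - 1
  }
  right <- summit
  while (right < n && (right + 1) - summit <= capBins) {
    v <- values[right + 1]
    if (v < half) break
    if (v < minSignal && right + 2 <= n && values[right + 2] > v) break
    right <- right + 1
  }
  c(left, right)
}

.autoMinSignal <- function(values) {
  stats::median(values) + 5 * stats::mad(values)
}

.widthAtHalfMax <- function(raw, summitBin) {
  # local apex on the raw (pre-kernel) signal near the summit
  n <- length(raw)
  apex <- summitBin
  win <- max(1, apex - 2):min(n, apex + 2)
  apex <- win[which.max(raw[win])]
  half <- raw[apex] / 2
  l <- apex
  while (l > 1 && raw[l - 1] >= half) l <- l - 1
  r <- apex
  while (r < n && raw[r + 1] >= half) r <- r + 1
  r - l + 1
}

#' Turn ridge lines into ranked, filtered peaks
#'
#' Each ridge at least \code{minRidgeLength} scales long becomes a peak:
#' the summit is the ridge position at its smallest scale; boundaries
#' extend from the summit to the nearest bin where the smoothed signal
#' falls below half the summit height (or a local minimum below
#' \code{minSignal}), capped at 2 x bestScale bins each side.  The
#' low-signal filter drops peaks whose summit signal is below
#' \code{minSignal}; the spike filter drops peaks whose width at half
#' maximum on the raw binned signal is below \code{maxSpikeSharpness}
#' bins.  Peaks are scored by ridge length (coefficient as tiebreak) and
#' returned in descending score order.
#'
#' @param signal the \linkS4class{SmoothedTrack} the transform ran on.
#' @param ridges output of \code{\link{linkRidges}}.
#' @param minRidgeLength minimum scales a ridge must span.
#' @param minSignal low-signal threshold in signal units; \code{NULL}
#'   selects median + 5 * MAD of the smoothed signal, which keeps peak
#'   calls invariant under rescaling of the input.
#' @param maxSpikeSharpness spike threshold in bins (0 disables the
#'   spike filter).
#' @param minSnr minimum ridge coefficient as a multiple of the
#'   coefficient noise level (the median over scales of each scale's
#'   coefficient MAD — the per-scale normalization makes a matched
#'   peak's coefficient scale-independent, so one global level
#'   applies); 0 disables.  Noise-relative, so calls are invariant
#'   under rescaling of the input.
#' @param keepFiltered also return filtered peaks, tagged by
#'   \code{filteredReason}.
#' @return data.frame of peaks: chrom, start, end (bases, half-open),
#'   summit (base), score, ridgeLength, bestScale (bases), maxHeight,
#'   filteredReason.
#' @export
callPeaks <- function(signal, ridges, minRidgeLength = 3, minSignal = NULL,
                      maxSpikeSharpness = 2, minSnr = 5,
                      keepFiltered = FALSE) {
  if (is.null(minSignal)) minSignal <- .autoMinSignal(signal@values)
  bs <- signal@binSize
  raw <- if (length(signal@raw)) signal@raw else signal@values
  perScaleNoise <- unlist(lapply(ridges, function(r)
    if ("noise" %in% names(r$points)) {
      stats::setNames(r$points$noise, r$points$scaleBases)
    } else NULL))
  coefNoise <- if (length(perScaleNoise)) {
    stats::median(perScaleNoise[!duplicated(names(perScaleNoise))])
  } else NA_real_
  rows <- lapply(ridges, function(r) {
    if (r$length < minRidgeLength) return(NULL)
    s <- r$summit
    height <- signal@values[s]
    reason <- "none"
    if (height < minSignal ||
        (minSnr > 0 && is.finite(coefNoise) &&
         r$maxCoef < minSnr * coefNoise)) {
      reason <- "low_signal"
    } else if (maxSpikeSharpness > 0 &&
               .widthAtHalfMax(raw, s) < maxSpikeSharpness) {
      reason <- "spike"
    }
    cap <- max(1, 2 * r$bestScaleBins)
    b <- .halfMaxBounds(signal@values, s, minSignal, cap)
    data.frame(chrom = signal@contig, start = (b[1] - 1) * bs, end = b[2] * bs,
               summit = (s - 1) * bs + floor(bs / 2), score = r$length,
               ridgeLength = r$length, bestScale = r$bestScale,
               maxHeight = height, maxCoef = r$maxCoef,
               filteredReason = reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), summit = numeric(0),
                      score = numeric(0), ridgeLength = integer(0),
                      bestScale = numeric(0), maxHeight = numeric(0),
                      maxCoef = numeric(0), filteredReason = character(0),
                      stringsAsFactors = FALSE)
  }
  if (!keepFiltered) out <- out[out$filteredReason == "none", , drop = FALSE]
  ord <- order(-out$score, -out$maxCoef, out$summit, method = "radix")
  out <- out[ord, , drop = FALSE]
  # non-maximum suppression: a summit inside a better-ranked surviving
  # peak's interval is a shoulder of that peak, not a second peak
  n <- nrow(out)
  keep <- rep(TRUE, n)
  for (j in seq_len(n)) {
    if (out$filteredReason[j] != "none") next
    prior <- which(keep[seq_len(j - 1L)] &
                   out$filteredReason[seq_len(j - 1L)] == "none")
    if (any(out$summit[j] >= out$start[prior] &
            out$summit[j] < out$end[prior])) {
      keep[j] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Single-scale Gaussian-smoothing peak caller
#'
#' The comparison pipeline: Gaussian smoothing at one bandwidth, strict
#' local maxima above \code{minSignal}, half-maximum boundaries.  Same
#' peak contract as \code{\link{callPeaks}} with ridge length 1 and
#' score = summit height.
#'
#' @param signal a \linkS4class{SmoothedTrack}.
#' @param bandwidth Gaussian sigma in bases.
#' @param minSignal threshold; \code{NULL} selects median + 5 * MAD.
#' @return peaks data.frame as in \code{\link{callPeaks}}.
#' @export
gaussianSmoothPeaks <- function(signal, bandwidth, minSignal = NULL) {
  stopifnot(bandwidth > 0)
  bs <- signal@binSize
  sm <- pmax(.convReflect(signal@values, .gaussKernel(bandwidth / bs)), 0)
  if (is.null(minSignal)) minSignal <- .autoMinSignal(sm)
  n <- length(sm)
  if (n < 3) return(callPeaks(signal, list()))
  cand <- which(sm[2:(n - 1)] > sm[1:(n - 2)] & sm[2:(n - 1)] >= sm[3:n]) + 1L
  cand <- cand[sm[cand] >= minSignal & sm[cand] > 0]
  cap <- max(1, 4 * bandwidth / bs)
  rows <- lapply(cand, function(s) {
    b <- .halfMaxBounds(sm, s, minSignal, cap)
    data.frame(chrom = signal@contig, start = (b[1] - 1) * bs, end = b[2] * bs,
               summit = (s - 1) * bs + floor(bs / 2), score = sm[s],
               ridgeLength = 1L, bestScale = bandwidth, maxHeight = sm[s],
               maxCoef = sm[s], filteredReason = "none",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(callPeaks(signal, list()))
  out <- out[order(-out$score, out$summit), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full wavelet peak-calling pipeline over all contigs
#'
#' \code{\link{prepareSignal}} -> \code{\link{cwtScales}} ->
#' \code{\link{findScaleMaxima}} -> \code{\link{linkRidges}} ->
#' \code{\link{callPeaks}}, per contig, concatenated and sorted by
#' descending score.
#'
#' @inheritParams prepareSignal
#' @inheritParams cwtScales
#' @inheritParams findScaleMaxima
#' @inheritParams linkRidges
#' @inheritParams callPeaks
#' @return peaks data.frame (see \code{\link{callPeaks}}).
#' @export
waveletPeakCall <- function(sample, control = NULL, binSize = 10,
                            kernel = "gaussian", bandwidth = 40,
                            normalize = TRUE, scales = NULL,
                            minSeparationFactor = 1, gapTolerance = 2,
                            positionToleranceFactor = 1, minRidgeLength = 3,
                            minSignal = NULL, maxSpikeSharpness = 2,
                            minSnr = 5, keepFiltered = FALSE) {
  signals <- prepareSignal(sample, control, binSize = binSize,
                           kernel = kernel, bandwidth = bandwidth,
                           normalize = normalize)
  pieces <- lapply(signals, function(sig) {
    cw <- cwtScales(sig, scales = scales)
    mx <- findScaleMaxima(cw, minSeparationFactor = minSeparationFactor)
    rl <- linkRidges(mx, gapTolerance = gapTolerance,
                     positionToleranceFactor = positionToleranceFactor)
    callPeaks(sig, rl, minRidgeLength = minRidgeLength,
              minSignal = minSignal, maxSpikeSharpness = maxSpikeSharpness,
              minSnr = minSnr, keepFiltered = keepFiltered)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(-out$score, -out$maxCoef, out$chrom, out$summit,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write peaks as BED6
#' @param peaks peaks data.frame from \code{\link{callPeaks}}.
#' @param path output path.
#' @param provenance optional '#' header lines.
#' @export
writePeaksBed <- function(peaks, path, provenance = NULL) {
  body <- sprintf("%s\t%d\t%d\tpeak_%d\t%g\t.", peaks$chrom,
                  as.integer(peaks$start), as.integer(peaks$end),
                  seq_len(nrow(peaks)), peaks$score)
  writeLines(c(provenance, body), path)
  invisible(path)
}

#' Write the peak detail table (summit, ridge length, scale, height)
#' @inheritParams writePeaksBed
#' @export
writePeakDetails <- function(peaks, path, provenance = NULL) {
  hdr <- "chrom\tsummit\tridge_length\tbest_scale\theight\tfilter_reason"
  body <- sprintf("%s\t%d\t%d\t%g\t%.10g\t%s", peaks$chrom,
                  as.integer(peaks$summit), peaks$ridgeLength,
                  peaks$bestScale, peaks$maxHeight, peaks$filteredReason)
  writeLines(c(provenance, hdr, body), path)
  invisible(path)
}
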
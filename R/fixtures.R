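# Deterministic synthetic data: genomes, SAM alignments with planted
# mismatches and indels (with correct CIGAR/MD/NM), feature sets, and
# coverage tracks with planted Gaussian peaks on Poisson background.
# Every generator is a pure function of its arguments including the
# seed, and each records the ground truth alongside its artifact.

.BASES <- c("A", "C", "G", "T")

.complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement a DNA string
#' @param s DNA string over ACGTN.
#' @export
reverseComplement <- function(s) {
  paste(rev(.complement[strsplit(s, "")[[1]]]), collapse = "")
}

#' Generate a random genome
#'
#' @param contigSpecs named numeric vector: contig name -> length.
#' @param seed integer seed; the same seed reproduces the genome
#'   exactly.
#' @return list with \code{contigs} (named character vector of
#'   sequences) and \code{seed}.
#' @export
makeGenome <- function(contigSpecs, seed) {
  rng <- seededRng(seed)
  contigs <- vapply(contigSpecs, function(len) {
    paste(rngDraw(rng, sample(.BASES, len, replace = TRUE)), collapse = "")
  }, "")
  names(contigs) <- names(contigSpecs)
  list(contigs = contigs, seed = seed)
}

#' Write a genome as wrapped FASTA
#' @param genome from \code{\link{makeGenome}}.
#' @param path output path.
#' @param width wrap width.
#' @export
writeGenomeFasta <- function(genome, path, width = 60) {
  recs <- lapply(names(genome$contigs), function(cn) {
    list(name = cn, sequence = genome$contigs[[cn]])
  })
  writeFasta(recs, path, width = width)
}

# mutate one aligned segment; returns list(seq, mdParts, mmPos)
.mutateSegment <- function(refSeg, refStart, mismatchAt) {
  chars <- strsplit(refSeg, "")[[1]]
  mdParts <- character(0)
  run <- 0L
  mm <- numeric(0)
  for (j in seq_along(chars)) {
    if (mismatchAt[j]) {
      mdParts <- c(mdParts, as.character(run), chars[j])
      run <- 0L
      mm <- c(mm, refStart + j - 1)
      chars[j] <- sample(setdiff(.BASES, chars[j]), 1)
    } else run <- run + 1L
  }
  mdParts <- c(mdParts, as.character(run))
  list(seq = paste(chars, collapse = ""), mdParts = mdParts, mmPos = mm)
}

#' Generate a SAM file with planted mismatches and indels
#'
#' Reads are placed uniformly (contig by length, position uniform,
#' strand fair coin).  Mismatches are planted per aligned base at
#' \code{mismatchRate} and reflected in the MD and NM tags; with
#' probability \code{indelRate} a read carries one short (1-2 bp)
#' insertion or deletion, reflected in CIGAR, MD and NM.  \code{@SQ}
#' headers carry the contig lengths.  The returned truth records where
#' every read really aligns and where every mismatch was planted.
#'
#' @param genome from \code{\link{makeGenome}}.
#' @param nReads number of reads.
#' @param readLength aligned read length in reference bases.
#' @param mismatchRate per-base mismatch probability.
#' @param indelRate per-read probability of one short indel.
#' @param seed integer seed.
#' @param path output SAM path.
#' @return invisibly, list(path, truth) where truth is a data.frame
#'   with name, contig, start (0-based), strand, cigar, spanEnd and a
#'   list-column mmPos of planted mismatch reference positions.
#' @export
makeSam <- function(genome, nReads, readLength = 50, mismatchRate = 0.01,
                    indelRate = 0, seed = 1, path) {
  rng <- seededRng(seed)
  lens <- nchar(genome$contigs)
  stopifnot(readLength + 4 <= min(lens))
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens))
  rows <- character(nReads)
  truth <- vector("list", nReads)
  rngDraw(rng, {
    for (i in seq_len(nReads)) {
      cn <- if (length(lens) == 1) names(lens) else
        sample(names(lens), 1, prob = lens)
      L <- lens[[cn]]
      maxSpan <- readLength + 4            # room for a small deletion
      start0 <- sample.int(L - maxSpan + 1, 1) - 1
      strand <- sample(c("+", "-"), 1)
      flag <- if (strand == "-") 16L else 0L

      hasIndel <- runif(1) < indelRate
      indelType <- if (hasIndel) sample(c("I", "D"), 1) else ""
      indelLen <- if (hasIndel) sample(1:2, 1) else 0L
      # split the aligned bases into two M runs around the indel
      m1 <- if (hasIndel) sample(seq(5, readLength - 5), 1) else readLength
      m2 <- readLength - m1

      refSeq <- genome$contigs[[cn]]
      seg1 <- substr(refSeq, start0 + 1, start0 + m1)
      mut1 <- .mutateSegment(seg1, start0, runif(m1) < mismatchRate)
      if (!hasIndel) {
        cigar <- sprintf("%dM", readLength)
        md <- paste(mut1$mdParts, collapse = "")
        seqOut <- mut1$seq
        mm <- mut1$mmPos
        nmv <- length(mm)
        spanEnd <- start0 + readLength
      } else if (indelType == "I") {
        ins <- paste(sample(.BASES, indelLen, replace = TRUE), collapse = "")
        seg2 <- substr(refSeq, start0 + m1 + 1, start0 + m1 + m2)
        mut2 <- .mutateSegment(seg2, start0 + m1, runif(m2) < mismatchRate)
        cigar <- sprintf("%dM%dI%dM", m1, indelLen, m2)
        # MD ignores insertions: adjacent match runs merge across the I
        md <- paste(c(utils::head(mut1$mdParts, -1),
                      as.character(as.integer(utils::tail(mut1$mdParts, 1)) +
                                   as.integer(mut2$mdParts[1])),
                      utils::tail(mut2$mdParts, -1)), collapse = "")
        seqOut <- paste0(mut1$seq, ins, mut2$seq)
        mm <- c(mut1$mmPos, mut2$mmPos)
        nmv <- length(mm) + indelLen
        spanEnd <- start0 + readLength
      } else {
        delStart <- start0 + m1
        delSeq <- substr(refSeq, delStart + 1, delStart + indelLen)
        seg2 <- substr(refSeq, delStart + indelLen + 1,
                       delStart + indelLen + m2)
        mut2 <- .mutateSegment(seg2, delStart + indelLen,
                               runif(m2) < mismatchRate)
        cigar <- sprintf("%dM%dD%dM", m1, indelLen, m2)
        md <- paste(c(mut1$mdParts, paste0("^", delSeq), mut2$mdParts),
                    collapse = "")
        seqOut <- paste0(mut1$seq, mut2$seq)
        mm <- c(mut1$mmPos, mut2$mmPos)
        nmv <- length(mm) + indelLen
        spanEnd <- start0 + readLength + indelLen
      }
      qname <- sprintf("r%06d", i)
      rows[i] <- paste(qname, flag, cn, start0 + 1, 60L, cigar, "*", 0, 0,
                       seqOut, strrep("I", nchar(seqOut)),
                       sprintf("NM:i:%d", nmv), sprintf("MD:Z:%s", md),
                       "NH:i:1", sep = "\t")
      truth[[i]] <- list(name = qname, contig = cn, start = start0,
                         strand = strand, cigar = cigar, mmPos = mm,
                         spanEnd = spanEnd)
    }
  })
  writeLines(c(header, rows), path)
  tr <- data.frame(name = vapply(truth, `[[`, "", "name"),
                   contig = vapply(truth, `[[`, "", "contig"),
                   start = vapply(truth, `[[`, 0, "start"),
                   strand = vapply(truth, `[[`, "", "strand"),
                   cigar = vapply(truth, `[[`, "", "cigar"),
                   spanEnd = vapply(truth, `[[`, 0, "spanEnd"),
                   stringsAsFactors = FALSE)
  tr$mmPos <- lapply(truth, `[[`, "mmPos")
  invisible(list(path = path, truth = tr))
}

#' Generate a coverage track with planted Gaussian peaks
#'
#' Per-base values are Poisson(\code{noiseRate}) background plus
#' Gaussian-profile bumps \code{amplitude * exp(-d^2 / (2 width^2))}
#' around each planted center.  The full signal lands on the forward
#' and total arrays of the returned track.
#'
#' @param contigLength contig length in bases.
#' @param peaks data.frame with columns center, width (Gaussian sigma,
#'   bases) and amplitude (reads per base at the center); overlapping
#'   peaks are allowed.
#' @param noiseRate Poisson background rate per base.
#' @param seed integer seed.
#' @param contig contig name.
#' @return list(track = \linkS4class{CoverageTrack}, truth = peaks).
#' @export
makePeakTrack <- function(contigLength, peaks, noiseRate = 1, seed = 1,
                          contig = "chr1") {
  rng <- seededRng(seed)
  vals <- rngDraw(rng, rpois(contigLength, noiseRate))
  vals <- as.numeric(vals)
  pos <- seq(0, contigLength - 1)
  for (i in seq_len(nrow(peaks))) {
    d <- pos - peaks$center[i]
    vals <- vals + peaks$amplitude[i] * exp(-d^2 / (2 * peaks$width[i]^2))
  }
  sv <- sparseVector0(pos[vals != 0], vals[vals != 0])
  empty <- sparseVector0()
  lens <- stats::setNames(contigLength, contig)
  track <- new("CoverageTrack", contigLengths = lens,
               forward = stats::setNames(list(sv), contig),
               reverse = stats::setNames(list(empty), contig),
               total = stats::setNames(list(sv), contig),
               mismatch = stats::setNames(list(empty), contig),
               readsCounted = max(1, round(sum(vals))), normalized = FALSE)
  list(track = track, truth = peaks)
}

#' Random peak layout for recovery experiments
#'
#' Places \code{n} peaks on a rough grid with jitter so neighbours stay
#' separated; widths are log-uniform in [widthRange], amplitudes
#' uniform in [amplitudeRange].
#'
#' @param contigLength contig length in bases.
#' @param n number of peaks.
#' @param widthRange Gaussian sigma range in bases.
#' @param amplitudeRange reads-per-base amplitude range.
#' @param seed integer seed.
#' @return peaks data.frame (center, width, amplitude).
#' @export
makePeakLayout <- function(contigLength, n = 20, widthRange = c(50, 1000),
                           amplitudeRange = c(5, 20), seed = 1) {
  rng <- seededRng(seed)
  rngDraw(rng, {
    slot <- contigLength / n
    center <- (seq_len(n) - 0.5) * slot + runif(n, -0.15, 0.15) * slot
    width <- exp(runif(n, log(widthRange[1]), log(widthRange[2])))
    amplitude <- runif(n, amplitudeRange[1], amplitudeRange[2])
    data.frame(center = round(center), width = width, amplitude = amplitude)
  })
}

#' Random synthetic feature set
#'
#' @param contigLengths named numeric vector of contig lengths.
#' @param n number of features.
#' @param seed integer seed.
#' @param withBlocks give each feature 1-3 exon-like sub-blocks.
#' @param maxLen maximum feature length.
#' @return feature data.frame as from \code{\link{readFeatures}}.
#' @export
makeFeatures <- function(contigLengths, n, seed = 1, withBlocks = FALSE,
                         maxLen = 500) {
  rng <- seededRng(seed)
  rngDraw(rng, {
    cn <- sample(names(contigLengths), n, replace = TRUE,
                 prob = contigLengths)
    len <- sample.int(maxLen, n, replace = TRUE)
    start <- vapply(seq_len(n), function(i) {
      sample.int(max(1, contigLengths[[cn[i]]] - len[i]), 1) - 1
    }, 0)
    strand <- sample(c("+", "-", "."), n, replace = TRUE, prob = c(.45, .45, .1))
    f <- .makeFeatureFrame(id = sprintf("F%04d", seq_len(n)),
                           name = sprintf("gene%04d", seq_len(n)),
                           chrom = cn, start = start, end = start + len,
                           strand = strand)
    if (withBlocks) {
      for (i in seq_len(n)) {
        k <- sample(1:3, 1)
        if (f$end[i] - f$start[i] + 1 < 2 * k) next
        cuts <- sort(sample(seq(f$start[i], f$end[i]), 2 * k))
        bs <- cuts[seq(1, 2 * k, by = 2)]
        be <- cuts[seq(2, 2 * k, by = 2)]
        keep <- be > bs
        if (any(keep)) {
          bs <- bs[keep]; be <- be[keep]
          bs[1] <- f$start[i]; be[length(be)] <- f$end[i]
          f$blockStarts[[i]] <- bs
          f$blockEnds[[i]] <- be
        }
      }
    }
    f
  })
}
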
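# Strand-specific per-base coverage and mismatch counting from parsed
# SAM records, with midpoint mode, unique-read filtering, region
# restriction, per-million normalization, windowing and scaling.

#' Construct a SparseVector
#' @param pos 0-based positions (need not be sorted; duplicates summed).
#' @param val values parallel to \code{pos}.
#' @return a \linkS4class{SparseVector}; zero entries are pruned.
#' @export
sparseVector0 <- function(pos = numeric(0), val = numeric(0)) {
  if (length(pos)) {
    agg <- rowsum(as.numeric(val), group = as.numeric(pos))
    pos <- as.numeric(rownames(agg)); val <- agg[, 1]
    keep <- val != 0
    pos <- pos[keep]; val <- unname(val[keep])
    o <- order(pos); pos <- pos[o]; val <- val[o]
  }
  new("SparseVector", pos = pos, val = val)
}

#' Read values of a SparseVector at arbitrary positions
#' @param sv a \linkS4class{SparseVector}.
#' @param positions 0-based positions.
#' @return numeric values (0 for unpopulated positions).
#' @export
svGet <- function(sv, positions) {
  i <- match(positions, sv@pos)
  out <- numeric(length(positions))
  hit <- !is.na(i)
  out[hit] <- sv@val[i[hit]]
  out
}

#' Expand a SparseVector to a dense vector of length n (positions 0..n-1)
#' @param sv a \linkS4class{SparseVector}.
#' @param n dense length.
#' @export
svDense <- function(sv, n) {
  out <- numeric(n)
  keep <- sv@pos < n
  out[sv@pos[keep] + 1] <- sv@val[keep]
  out
}

#' Sum of all stored values of a SparseVector
#' @param sv a \linkS4class{SparseVector}.
#' @export
svSum <- function(sv) sum(sv@val)

.svScale <- function(sv, factor) {
  val <- sv@val * factor
  keep <- val != 0
  new("SparseVector", pos = sv@pos[keep], val = val[keep])
}

.emptyTrack <- function(contigLengths) {
  mk <- function() {
    l <- lapply(names(contigLengths), function(cn) sparseVector0())
    names(l) <- names(contigLengths)
    l
  }
  new("CoverageTrack", contigLengths = contigLengths, forward = mk(),
      reverse = mk(), total = mk(), mismatch = mk(), readsCounted = 0,
      normalized = FALSE)
}

.alignmentFilter <- function(aln, uniqueOnly = FALSE, maxErrors = NULL,
                             keepDuplicates = TRUE) {
  keep <- aln$mapped & !aln$secondary
  if (uniqueOnly) {
    keep <- keep & ifelse(is.na(aln$nh), aln$mapq > 0, aln$nh == 1)
  }
  if (!is.null(maxErrors)) {
    keep <- keep & (is.na(aln$nm) | aln$nm <= maxErrors)  # absent NM: assume 0
  }
  if (!keepDuplicates) keep <- keep & !aln$duplicate
  keep
}

#' Strand-specific coverage from alignments
#'
#' Each mapped primary record passing the filters increments depth at
#' every reference base its M/=/X blocks cover (deletion/skip gaps are
#' not covered), on the strand given by SAM flag 0x10.  In midpoint
#' mode only \code{floor((spanStart + spanEnd)/2)} of the outer
#' reference span is incremented.  "Uniquely aligning" means NH == 1
#' when the NH tag is present, else mapq > 0.  Records without an NM
#' tag are treated as error-free by the \code{maxErrors} filter.
#'
#' @param aln parsed alignments from \code{\link{parseSam}}.
#' @param contigLengths named lengths; defaults to the SAM \code{@SQ}
#'   headers, else the maximum end seen per contig.
#' @param midpoint increment only the span midpoint.
#' @param uniqueOnly keep uniquely aligning records only.
#' @param regions optional interval data.frame; only bases inside are
#'   counted (records still count toward \code{readsCounted}).
#' @param normalizePerMillion scale depths by 1e6 / readsCounted
#'   (mismatch counts are never normalized).
#' @param maxErrors optional maximum NM value.
#' @param keepDuplicates count flag-0x400 duplicates (default yes).
#' @return a \linkS4class{CoverageTrack}.
#' @export
computeCoverage <- function(aln, contigLengths = NULL, midpoint = FALSE,
                            uniqueOnly = FALSE, regions = NULL,
                            normalizePerMillion = FALSE, maxErrors = NULL,
                            keepDuplicates = TRUE) {
  keep <- .alignmentFilter(aln, uniqueOnly, maxErrors, keepDuplicates)
  used <- aln[keep, , drop = FALSE]
  if (is.null(contigLengths)) contigLengths <- attr(aln, "contigLengths")
  if (is.null(contigLengths) || !length(contigLengths)) {
    contigLengths <- vapply(split(used$spanEnd, used$chrom),
                            function(x) max(x, 0, na.rm = TRUE), 0)
  }
  track <- .emptyTrack(contigLengths)
  track@readsCounted <- nrow(used)
  inRegion <- function(contig, p) {
    if (is.null(regions)) return(rep(TRUE, length(p)))
    r <- regions[regions$chrom == contig, , drop = FALSE]
    if (!nrow(r)) return(rep(FALSE, length(p)))
    out <- rep(FALSE, length(p))
    for (k in seq_len(nrow(r))) out <- out | (p >= r$start[k] & p < r$end[k])
    out
  }
  for (contig in names(contigLengths)) {
    sel <- which(used$chrom == contig)
    if (!length(sel)) next
    posByStrand <- list(`+` = numeric(0), `-` = numeric(0))
    for (i in sel) {
      p <- if (midpoint) {
        floor((used$spanStart[i] + used$spanEnd[i]) / 2)
      } else {
        b <- used$blocks[[i]]
        if (!nrow(b)) next
        unlist(lapply(seq_len(nrow(b)), function(k) seq(b[k, 1], b[k, 2] - 1)))
      }
      p <- p[inRegion(contig, p)]
      s <- used$strand[i]
      posByStrand[[s]] <- c(posByStrand[[s]], p)
    }
    fwd <- sparseVector0(posByStrand[["+"]], rep(1, length(posByStrand[["+"]])))
    rev <- sparseVector0(posByStrand[["-"]], rep(1, length(posByStrand[["-"]])))
    track@forward[[contig]] <- fwd
    track@reverse[[contig]] <- rev
    track@total[[contig]] <- sparseVector0(c(fwd@pos, rev@pos), c(fwd@val, rev@val))
  }
  if (normalizePerMillion) {
    if (track@readsCounted == 0) stop("cannot normalize: no reads passed filters")
    f <- 1e6 / track@readsCounted
    for (contig in names(contigLengths)) {
      track@forward[[contig]] <- .svScale(track@forward[[contig]], f)
      track@reverse[[contig]] <- .svScale(track@reverse[[contig]], f)
      track@total[[contig]] <- .svScale(track@total[[contig]], f)
    }
    track@normalized <- TRUE
  }
  track
}

#' Reference positions of MD-tag mismatches
#'
#' Walks the MD tag jointly with the CIGAR so insertions and soft clips
#' do not shift reference positions: match counts advance over aligned
#' (M/=/X) reference bases, letters mark a mismatch at the current
#' aligned base, and ^-prefixed runs advance over deleted reference
#' bases.
#'
#' @param pos0 0-based leftmost mapped position.
#' @param cigar CIGAR string.
#' @param md MD tag value.
#' @return numeric vector of 0-based mismatch reference positions.
#' @export
mdMismatchPositions <- function(pos0, cigar, md) {
  ops <- parseCigar(cigar)
  refpos <- numeric(0)   # reference position of every aligned (M/=/X) base
  delpos <- numeric(0)   # reference positions of deleted bases, in order
  cur <- pos0
  aligned <- character(0)
  for (k in seq_len(nrow(ops))) {
    op <- ops$op[k]; len <- ops$len[k]
    if (op %in% c("M", "=", "X")) {
      refpos <- c(refpos, seq(cur, length.out = len)); cur <- cur + len
      aligned <- c(aligned, rep("M", len))
    } else if (op == "D") {
      delpos <- c(delpos, seq(cur, length.out = len)); cur <- cur + len
      aligned <- c(aligned, rep("D", len))
    } else if (op == "N") {
      cur <- cur + len
    }
  }
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Za-z]+|[A-Za-z]", md))[[1]]
  if (paste(toks, collapse = "") != md) stop("malformed MD tag: ", md)
  # pointer over the concatenated aligned+deleted reference walk
  walkOps <- aligned
  walkPos <- numeric(length(walkOps))
  walkPos[walkOps == "M"] <- refpos
  walkPos[walkOps == "D"] <- delpos
  ptr <- 1L
  mm <- numeric(0)
  for (tok in toks) {
    if (grepl("^[0-9]+$", tok)) {
      nadv <- as.integer(tok)
      if (nadv > 0) {
        idx <- seq(ptr, length.out = nadv)
        if (max(idx) > length(walkOps) || any(walkOps[idx] != "M")) {
          stop("MD tag inconsistent with CIGAR: ", md, " / ", cigar)
        }
        ptr <- ptr + nadv
      }
    } else if (startsWith(tok, "^")) {
      nadv <- nchar(tok) - 1L
      idx <- seq(ptr, length.out = nadv)
      if (max(idx) > length(walkOps) || any(walkOps[idx] != "D")) {
        stop("MD tag inconsistent with CIGAR: ", md, " / ", cigar)
      }
      ptr <- ptr + nadv
    } else {
      if (ptr > length(walkOps) || walkOps[ptr] != "M") {
        stop("MD tag inconsistent with CIGAR: ", md, " / ", cigar)
      }
      mm <- c(mm, walkPos[ptr])
      ptr <- ptr + 1L
    }
  }
  if (ptr != length(walkOps) + 1L) {
    stop("MD tag does not span the CIGAR reference footprint: ", md, " / ", cigar)
  }
  mm
}

#' Count mismatched bases per reference position
#'
#' For every record carrying an MD tag, mismatch positions are located
#' by the joint MD/CIGAR walk and tallied into the track's mismatch
#' array.  Records without MD, and records whose MD contradicts their
#' CIGAR, are skipped; a warning reports the counts.
#'
#' @param aln parsed alignments from \code{\link{parseSam}}.
#' @param track a \linkS4class{CoverageTrack} to fill (its filters are
#'   not re-applied; pass the same filtered set used to build it).
#' @return the track with mismatch counts filled in.
#' @export
countMismatches <- function(aln, track) {
  skippedNoMd <- 0L; skippedBad <- 0L
  posByContig <- list()
  for (i in seq_len(nrow(aln))) {
    if (!aln$mapped[i]) next
    if (is.na(aln$md[i])) { skippedNoMd <- skippedNoMd + 1L; next }
    mm <- tryCatch(mdMismatchPositions(aln$pos0[i], aln$cigar[i], aln$md[i]),
                   error = function(e) NULL)
    if (is.null(mm)) { skippedBad <- skippedBad + 1L; next }
    if (length(mm)) {
      cn <- aln$chrom[i]
      posByContig[[cn]] <- c(posByContig[[cn]], mm)
    }
  }
  for (cn in names(posByContig)) {
    if (!cn %in% names(track@contigLengths)) next
    track@mismatch[[cn]] <- sparseVector0(posByContig[[cn]],
                                          rep(1, length(posByContig[[cn]])))
  }
  if (skippedNoMd + skippedBad > 0) {
    warning(skippedNoMd, " record(s) without MD and ", skippedBad,
            " with inconsistent MD were skipped")
  }
  track
}

#' Reduce a track over non-overlapping windows
#'
#' Window k covers bases [k*w, (k+1)*w); the result stores one value per
#' window index (position k).  The mean of a final partial window uses
#' the actual number of bases it contains.
#'
#' @param track a \linkS4class{CoverageTrack}.
#' @param window window width in bases, >= 1.
#' @param stat "mean" or "sum".
#' @return a windowed \linkS4class{CoverageTrack} (positions are window
#'   indices; contig lengths become window counts).
#' @export
windowTrack <- function(track, window, stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  stopifnot(window >= 1)
  nWin <- ceiling(track@contigLengths / window)
  out <- .emptyTrack(stats::setNames(nWin, names(track@contigLengths)))
  out@readsCounted <- track@readsCounted
  out@normalized <- track@normalized
  for (cn in names(track@contigLengths)) {
    len <- track@contigLengths[[cn]]
    for (s in c("forward", "reverse", "total", "mismatch")) {
      sv <- slot(track, s)[[cn]]
      if (!length(sv@pos)) next
      w <- floor(sv@pos / window)
      agg <- rowsum(sv@val, group = w)
      wi <- as.numeric(rownames(agg)); v <- agg[, 1]
      if (stat == "mean") {
        size <- pmin(window, len - wi * window)
        v <- v / size
      }
      slot(out, s)[[cn]] <- sparseVector0(wi, unname(v))
    }
  }
  out
}

#' Scale the depth arrays of a track
#'
#' Multiplies forward, reverse and total depths by a constant, globally
#' or per contig.  Mismatch counts are integer evidence tallies and are
#' left untouched.
#'
#' @param track a \linkS4class{CoverageTrack}.
#' @param factor a single number or a named per-contig vector.
#' @return the scaled track.
#' @export
scaleTrack <- function(track, factor) {
  for (cn in names(track@contigLengths)) {
    f <- if (length(factor) == 1 && is.null(names(factor))) factor
         else if (cn %in% names(factor)) factor[[cn]] else 1
    if (!is.finite(f)) stop("non-finite scale factor for ", cn)
    track@forward[[cn]] <- .svScale(track@forward[[cn]], f)
    track@reverse[[cn]] <- .svScale(track@reverse[[cn]], f)
    track@total[[cn]] <- .svScale(track@total[[cn]], f)
  }
  track
}

#' Write a coverage track as TSV
#'
#' One row per populated position: contig, 1-based position, forward,
#' reverse and total depth, mismatch count.
#'
#' @param track a \linkS4class{CoverageTrack}.
#' @param path output path.
#' @param provenance optional '#' header lines.
#' @export
writeCoverageTsv <- function(track, path, provenance = NULL) {
  rows <- character(0)
  for (cn in names(track@contigLengths)) {
    p <- sort(unique(c(track@forward[[cn]]@pos, track@reverse[[cn]]@pos,
                       track@total[[cn]]@pos, track@mismatch[[cn]]@pos)))
    if (!length(p)) next
    rows <- c(rows, sprintf("%s\t%d\t%.10g\t%.10g\t%.10g\t%.10g", cn,
                            as.integer(p) + 1L, svGet(track@forward[[cn]], p),
                            svGet(track@reverse[[cn]], p),
                            svGet(track@total[[cn]], p),
                            svGet(track@mismatch[[cn]], p)))
  }
  writeLines(c(provenance, "contig\tposition\tforward\treverse\ttotal\tmismatches",
               rows), path)
  invisible(path)
}
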
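# Annotate interval-bearing TSV rows with intersecting features, and
# count alignments per feature with shifting, filtering and RPKM.

#' Shift features toward their 5' end
#'
#' A positive shift moves each feature upstream in its own orientation:
#' toward lower coordinates on '+' (and unstranded) features, toward
#' higher coordinates on '-'.  Starts are clamped at 0, preserving the
#' end so a clamped feature shrinks rather than wraps.
#'
#' @param features feature data.frame.
#' @param shift signed shift in bases (positive = upstream).
#' @return the shifted features.
#' @export
shiftFeatures <- function(features, shift) {
  if (shift == 0) return(features)
  minus <- features$strand == "-"
  d <- ifelse(minus, shift, -shift)
  features$start <- pmax(0, features$start + d)
  features$end <- pmax(features$start, features$end + d)
  features
}

.featureLength <- function(features) {
  vapply(seq_len(nrow(features)), function(i) {
    bs <- features$blockStarts[[i]]
    if (!is.null(bs) && length(bs)) sum(features$blockEnds[[i]] - bs)
    else features$end[i] - features$start[i]
  }, 0)
}

#' Annotate a TSV of genomic intervals with intersecting features
#'
#' Every input row reappears: in \code{all_matches_one_row} mode exactly
#' once, with all matching feature ids/names joined by ';' in two
#' appended columns; in \code{one_match_per_row} mode once per match
#' (unmatched rows once, annotated empty).  Matches are ordered by
#' (start, end, id); the empty marker is ".".  Unknown chromosomes
#' annotate empty, they are not an error.
#'
#' @param inputPath TSV whose rows carry a genomic interval ('#' lines
#'   are passed over).
#' @param features feature data.frame (see \code{\link{readFeatures}}).
#' @param chromCol,startCol,endCol,strandCol 1-based column indices of
#'   the interval fields (\code{strandCol} optional).
#' @param oneBased input coordinates are 1-based inclusive.
#' @param requireStrand only match features with compatible strand
#'   ('.' matches any).
#' @param mode "all_matches_one_row" or "one_match_per_row".
#' @param outputPath optional path; when given the annotated rows are
#'   written as TSV (with optional provenance) and the path returned
#'   invisibly.
#' @param provenance optional '#' header lines for the output.
#' @return data.frame of output rows: original fields (as strings) plus
#'   \code{feature_ids} and \code{feature_names}.
#' @export
annotateTsv <- function(inputPath, features, chromCol, startCol, endCol,
                        strandCol = NULL, oneBased = FALSE,
                        requireStrand = FALSE,
                        mode = c("all_matches_one_row", "one_match_per_row"),
                        outputPath = NULL, provenance = NULL) {
  mode <- match.arg(mode)
  lines <- streamLines(inputPath)
  lines <- lines[!startsWith(lines, "#")]
  idx <- buildIntervalIndex(features)
  outRows <- list()
  for (k in seq_along(lines)) {
    f <- splitTsvLine(lines[k])
    start <- suppressWarnings(as.numeric(f[startCol]))
    end <- suppressWarnings(as.numeric(f[endCol]))
    if (is.na(start) || is.na(end)) {
      stop("unparseable coordinates at row ", k, ": ",
           f[startCol], "..", f[endCol])
    }
    if (oneBased) start <- start - 1
    strand <- if (!is.null(strandCol) && length(f) >= strandCol &&
                  f[strandCol] %in% c("+", "-")) f[strandCol] else "."
    q <- list(chrom = f[chromCol], start = start, end = end, strand = strand)
    hits <- queryOverlapping(idx, q, requireStrand = requireStrand)
    if (length(hits)) {
      ids <- ifelse(nzchar(features$id[hits]), features$id[hits], ".")
      nms <- ifelse(nzchar(features$name[hits]), features$name[hits], ".")
    } else { ids <- character(0); nms <- character(0) }
    if (mode == "all_matches_one_row" || !length(hits)) {
      outRows[[length(outRows) + 1L]] <-
        c(f, if (length(ids)) paste(ids, collapse = ";") else ".",
          if (length(nms)) paste(nms, collapse = ";") else ".")
    } else {
      for (h in seq_along(hits)) {
        outRows[[length(outRows) + 1L]] <- c(f, ids[h], nms[h])
      }
    }
  }
  nc <- if (length(outRows)) max(lengths(outRows)) else 2L
  mat <- do.call(rbind, lapply(outRows, function(r) { length(r) <- nc; r }))
  out <- as.data.frame(mat, stringsAsFactors = FALSE, optional = TRUE)
  if (nrow(out)) {
    names(out) <- c(paste0("V", seq_len(nc - 2L)), "feature_ids", "feature_names")
  }
  if (!is.null(outputPath)) {
    body <- if (nrow(out)) do.call(paste, c(out, sep = "\t")) else character(0)
    writeLines(c(provenance, body), outputPath)
    return(invisible(outputPath))
  }
  out
}

#' Count alignments per feature, with RPKM
#'
#' Each alignment passing the filters increments every feature whose
#' (shifted) interval it overlaps — a read overlapping N features
#' counts N times, with no fractional assignment.  Overlap uses the
#' record's reference blocks when \code{useBlocks}, else its outer
#' span.  RPKM = 1e9 * C / (N * L), where C is the feature's count,
#' N the number of records passing filters (whether or not they hit any
#' feature) and L the feature length (sum of sub-block lengths when
#' present, else the interval length).  Zero-length features get RPKM 0
#' with a warning.
#'
#' @param aln parsed alignments from \code{\link{parseSam}}.
#' @param features feature data.frame; input order is preserved in the
#'   output.
#' @param shift signed upstream shift applied to features before
#'   counting (see \code{\link{shiftFeatures}}).
#' @param readWhitelist optional character vector of qnames to keep.
#' @param maxErrors optional maximum NM.
#' @param uniqueOnly keep uniquely aligning records only.
#' @param rpkm compute the rpkm column (error if no read passes
#'   filters).
#' @param useBlocks overlap by reference blocks rather than outer span.
#' @param requireStrand only count reads whose strand matches the
#'   feature's ('.' matches any).
#' @return the features with \code{rawCount} (and \code{rpkm}) columns
#'   appended.
#' @export
countHitsPerFeature <- function(aln, features, shift = 0,
                                readWhitelist = NULL, maxErrors = NULL,
                                uniqueOnly = FALSE, rpkm = FALSE,
                                useBlocks = TRUE, requireStrand = FALSE) {
  if (!nrow(features)) stop("features must be non-empty")
  keep <- .alignmentFilter(aln, uniqueOnly, maxErrors)
  if (!is.null(readWhitelist)) keep <- keep & aln$qname %in% readWhitelist
  used <- aln[keep, , drop = FALSE]
  nCounted <- nrow(used)
  shifted <- shiftFeatures(features, shift)
  idx <- buildIntervalIndex(shifted)
  counts <- numeric(nrow(features))
  for (i in seq_len(nCounted)) {
    pieces <- if (useBlocks) {
      b <- used$blocks[[i]]
      if (!nrow(b)) next
      b
    } else {
      cbind(start = used$spanStart[i], end = used$spanEnd[i])
    }
    hits <- integer(0)
    for (k in seq_len(nrow(pieces))) {
      q <- list(chrom = used$chrom[i], start = pieces[k, 1],
                end = pieces[k, 2], strand = used$strand[i])
      hits <- c(hits, queryOverlapping(idx, q, requireStrand = requireStrand))
    }
    hits <- unique(hits)
    counts[hits] <- counts[hits] + 1
  }
  features$rawCount <- as.integer(counts)
  if (rpkm) {
    if (nCounted == 0) stop("RPKM requested but no read passed the filters")
    len <- .featureLength(features)
    zero <- len == 0
    if (any(zero)) warning(sum(zero), " zero-length feature(s): RPKM set to 0")
    r <- numeric(nrow(features))
    r[!zero] <- 1e9 * counts[!zero] / (nCounted * len[!zero])
    features$rpkm <- r
  }
  attr(features, "readsCounted") <- nCounted
  features
}

#' Write per-feature counts as TSV
#' @param counted output of \code{\link{countHitsPerFeature}}.
#' @param path output path.
#' @param provenance optional '#' header lines.
#' @export
writeFeatureCounts <- function(counted, path, provenance = NULL) {
  hasRpkm <- "rpkm" %in% names(counted)
  hdr <- paste(c("id", "name", "chrom", "start", "end", "strand", "rawCount",
                 if (hasRpkm) "rpkm"), collapse = "\t")
  body <- vapply(seq_len(nrow(counted)), function(i) {
    paste(c(counted$id[i], counted$name[i], counted$chrom[i],
            as.integer(counted$start[i]), as.integer(counted$end[i]),
            counted$strand[i], counted$rawCount[i],
            if (hasRpkm) sprintf("%.10g", counted$rpkm[i])), collapse = "\t")
  }, "")
  writeLines(c(provenance, hdr, body), path)
  invisible(path)
}
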
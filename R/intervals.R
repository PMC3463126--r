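# Strand-aware genomic intervals.  All internal coordinates are 0-based
# half-open [start, end); format readers convert at the boundary.
# Set operations and the overlap index delegate to IRanges; strand logic
# and the coordinate convention live here.

#' @importFrom IRanges IRanges reduce findOverlaps start end width
#' @importFrom S4Vectors subjectHits
NULL

#' Construct a set of genomic intervals
#'
#' @param chrom chromosome names.
#' @param start 0-based inclusive starts.
#' @param end exclusive ends (\code{start == end} is an empty interval).
#' @param strand "+", "-" or "." (unstranded); recycled.
#' @return data.frame with columns chrom/start/end/strand.
#' @export
genomicIntervals <- function(chrom, start, end, strand = ".") {
  n <- max(length(start), length(end))
  out <- data.frame(chrom = rep_len(as.character(chrom), n),
                    start = rep_len(as.numeric(start), n),
                    end = rep_len(as.numeric(end), n),
                    strand = rep_len(as.character(strand), n),
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$chrom))) stop("empty chromosome name")
  if (any(out$start < 0)) stop("negative start")
  if (any(out$end < out$start)) stop("end < start")
  if (any(!out$strand %in% c("+", "-", "."))) stop("strand must be +, - or .")
  out
}

.strandCompatible <- function(a, b) a == "." | b == "." | a == b

#' Pairwise interval overlap test
#'
#' Two intervals overlap iff they share a chromosome and
#' \code{max(starts) < min(ends)} (half-open convention: abutting
#' intervals do not overlap).  With \code{requireStrand}, strands must
#' also be equal, except that '.' matches any strand.
#'
#' @param a,b interval data.frames (rows recycled to equal length).
#' @param requireStrand demand strand compatibility.
#' @return logical vector.
#' @export
intervalsOverlap <- function(a, b, requireStrand = FALSE) {
  n <- max(nrow(a), nrow(b))
  ia <- rep_len(seq_len(nrow(a)), n); ib <- rep_len(seq_len(nrow(b)), n)
  ok <- a$chrom[ia] == b$chrom[ib] &
    pmax(a$start[ia], b$start[ib]) < pmin(a$end[ia], b$end[ib])
  if (requireStrand) ok <- ok & .strandCompatible(a$strand[ia], b$strand[ib])
  ok
}

.toIRanges <- function(df) IRanges(start = df$start + 1, end = df$end)

.fromIRanges <- function(ir, chrom) {
  genomicIntervals(chrom = rep(chrom, length(ir)), start = start(ir) - 1,
                   end = end(ir), strand = ".")
}

#' Set operations on interval lists
#'
#' Computes the union, intersection or subtraction (\code{xs \\ ys}) of
#' the base sets covered by two interval lists, per chromosome, ignoring
#' strand.  The result is the minimal sorted list of disjoint intervals
#' covering exactly the resulting base set (adjacent intervals are
#' merged).
#'
#' @param xs,ys interval data.frames from \code{\link{genomicIntervals}}.
#' @param op one of "union", "intersection", "subtraction".
#' @return an interval data.frame, strand '.'.
#' @export
intervalSetOp <- function(xs, ys, op = c("union", "intersection", "subtraction")) {
  op <- match.arg(op)
  chroms <- sort(unique(c(xs$chrom, ys$chrom)))
  pieces <- lapply(chroms, function(cn) {
    x <- reduce(.toIRanges(xs[xs$chrom == cn & xs$end > xs$start, , drop = FALSE]))
    y <- reduce(.toIRanges(ys[ys$chrom == cn & ys$end > ys$start, , drop = FALSE]))
    r <- switch(op,
                union = reduce(c(x, y)),
                intersection = IRanges::intersect(x, y),
                subtraction = IRanges::setdiff(x, y))
    .fromIRanges(r, cn)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) genomicIntervals(character(0), numeric(0), numeric(0)) else out
}

#' Build an overlap-query index over intervals
#'
#' @param intervals interval data.frame.
#' @param payload values attached to each interval (default row numbers).
#' @return an opaque index for \code{\link{queryOverlapping}}; results do
#'   not depend on insertion order.
#' @export
buildIntervalIndex <- function(intervals, payload = seq_len(nrow(intervals))) {
  stopifnot(length(payload) == nrow(intervals))
  byChrom <- split(seq_len(nrow(intervals)), intervals$chrom)
  idx <- lapply(byChrom, function(rows) {
    df <- intervals[rows, , drop = FALSE]
    list(ir = .toIRanges(df), start = df$start, end = df$end,
         strand = df$strand, payload = payload[rows])
  })
  structure(list(chroms = idx, empty = payload[0]), class = "IntervalIndex")
}

#' Query an interval index for overlapping features
#'
#' @param index from \code{\link{buildIntervalIndex}}.
#' @param q a one-row interval data.frame (or list with chrom/start/end/strand).
#' @param requireStrand demand strand compatibility ('.' matches any).
#' @return payloads of overlapping intervals, ordered by
#'   (start, end, payload); empty for an unknown chromosome.
#' @export
queryOverlapping <- function(index, q, requireStrand = FALSE) {
  node <- index$chroms[[as.character(q$chrom[1])]]
  if (is.null(node)) return(index$empty)
  qs <- as.numeric(q$start[1]); qe <- as.numeric(q$end[1])
  if (qe <= qs) return(node$payload[0])
  hits <- findOverlaps(IRanges(qs + 1, qe), node$ir)
  j <- S4Vectors::subjectHits(hits)
  if (requireStrand) {
    j <- j[.strandCompatible(as.character(q$strand[1]), node$strand[j])]
  }
  j <- j[node$end[j] > node$start[j]]  # empty intervals never overlap
  ord <- order(node$start[j], node$end[j], node$payload[j], method = "radix")
  node$payload[j[ord]]
}
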
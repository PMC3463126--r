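# Small-application layer: summary statistics, histograms, text-file set
# operations, FASTA/FASTQ subset/trim/dedupe, and a seeded RNG whose
# draws and permutations are bit-reproducible for a fixed seed.

#' Summary statistics of a numeric vector
#'
#' Sample variance uses the n-1 denominator (0 for n == 1); quartiles
#' are linearly interpolated.
#'
#' @param values numeric vector, length >= 1.
#' @return list: n, mean, median, sampleVariance, sd, min, max, q1, q3,
#'   sum.
#' @export
summarizeNumbers <- function(values) {
  if (!length(values)) stop("cannot summarize an empty list")
  v <- if (length(values) > 1) stats::var(values) else 0
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE)
  list(n = length(values), mean = mean(values),
       median = stats::median(values), sampleVariance = v, sd = sqrt(v),
       min = min(values), max = max(values), q1 = q[1], q3 = q[2],
       sum = sum(values))
}

#' Histogram of numeric or string values
#'
#' Numeric mode bins values into half-open intervals [lo, lo + width)
#' starting at \code{origin} (default: the minimum), with the final bin
#' closed so the maximum is counted.  String mode counts exact values,
#' sorted by descending count then label.  Counts always sum to the
#' input length.
#'
#' @param values numeric or character vector.
#' @param binWidth numeric mode: bin width (> 0).
#' @param binCount numeric mode alternative: number of equal bins over
#'   the data range.
#' @param origin numeric mode: left edge of the first bin.
#' @return data.frame with columns \code{label} and \code{count}.
#' @export
makeHistogram <- function(values, binWidth = NULL, binCount = NULL,
                          origin = NULL) {
  if (is.character(values)) {
    tab <- table(values)
    df <- data.frame(label = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
    return(df[order(-df$count, df$label, method = "radix"), ,
              drop = FALSE] |> (\(d) { rownames(d) <- NULL; d })())
  }
  if (is.null(binWidth)) {
    if (is.null(binCount)) stop("numeric mode needs binWidth or binCount")
    binWidth <- (max(values) - min(values)) / binCount
    if (binWidth == 0) binWidth <- 1
  }
  if (binWidth <= 0) stop("bin width must be positive")
  if (is.null(origin)) origin <- min(values)
  k <- floor((values - origin) / binWidth)
  if (!is.null(binCount)) k <- pmin(k, binCount - 1)  # closed final bin
  kAll <- seq(0, max(k))
  counts <- vapply(kAll, function(b) sum(k == b), 0L)
  lab <- sprintf("[%.10g,%.10g%s", origin + kAll * binWidth,
                 origin + (kAll + 1) * binWidth,
                 c(rep(")", length(kAll) - 1L), "]"))
  data.frame(label = lab, count = counts, stringsAsFactors = FALSE)
}

#' Set operations on the lines of two text files
#'
#' Lines are set elements compared exactly (no whitespace
#' normalization); duplicates within a file collapse to one.  The
#' result preserves first-occurrence order from \code{a}; union appends
#' \code{b}'s novel lines in their order.
#'
#' @param a,b paths to text files.
#' @param op "intersection", "subtraction" (a minus b) or "union".
#' @return character vector of result lines.
#' @export
textSetOp <- function(a, b, op = c("intersection", "subtraction", "union")) {
  op <- match.arg(op)
  la <- unique(streamLines(a))
  lb <- unique(streamLines(b))
  switch(op,
         intersection = la[la %in% lb],
         subtraction = la[!la %in% lb],
         union = c(la, lb[!lb %in% la]))
}

# ---- seeded RNG ------------------------------------------------------------

#' A self-contained seeded random number generator
#'
#' Carries its own generator state, so draws are bit-reproducible for a
#' fixed seed and independent of (and invisible to) the global RNG
#' stream.
#'
#' @param seed integer seed.
#' @return an object usable with \code{\link{rngDraw}} and
#'   \code{\link{rngPermutation}}.
#' @export
seededRng <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$seed <- seed
  e$state <- NULL
  class(e) <- "SeededRng"
  e
}

#' Evaluate a random expression under a SeededRng's stream
#' @param rng a \code{\link{seededRng}}.
#' @param expr expression drawing from the RNG (e.g. \code{runif(3)}).
#' @return the expression's value; the rng state advances.
#' @export
rngDraw <- function(rng, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  if (is.null(rng$state)) set.seed(rng$seed)
  else assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Uniform random permutation of 0..n-1
#' @param rng a \code{\link{seededRng}}.
#' @param n permutation size (>= 0).
#' @return integer vector, a uniform permutation of \code{0:(n-1)}.
#' @export
rngPermutation <- function(rng, n) {
  if (n == 0) return(integer(0))
  rngDraw(rng, sample.int(n)) - 1L
}

# ---- FASTA/FASTQ operations ------------------------------------------------

.asRecords <- function(x) if (is.character(x)) readSequenceRecords(x) else x

#' Write sequence records as FASTA
#' @param records list of records (name/sequence).
#' @param path output path.
#' @param width wrap width for sequence lines (0 = no wrapping).
#' @export
writeFasta <- function(records, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(paste0(">", r$name), con)
    s <- r$sequence
    if (width > 0 && nchar(s) > width) {
      starts <- seq(1, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
    } else writeLines(s, con)
  }
  invisible(path)
}

#' Write sequence records as FASTQ (4-line records)
#' @param records list of records (name/sequence/quality; a missing
#'   quality becomes "I" per base).
#' @param path output path.
#' @export
writeFastq <- function(records, path) {
  lines <- unlist(lapply(records, function(r) {
    q <- r$quality
    if (is.null(q)) q <- strrep("I", nchar(r$sequence))
    c(paste0("@", r$name), r$sequence, "+", q)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Subset sequence records by name or random fraction
#'
#' Name subsets keep the file order; fraction subsets keep each record
#' independently with probability \code{fraction} under the given
#' seeded RNG, so the same seed reproduces the same subset exactly.
#'
#' @param x records list or FASTA/FASTQ path.
#' @param names optional character vector of record names to keep.
#' @param fraction optional keep probability in [0, 1].
#' @param rng a \code{\link{seededRng}} (required with
#'   \code{fraction}).
#' @return list of records.
#' @export
fastxSubset <- function(x, names = NULL, fraction = NULL, rng = NULL) {
  recs <- .asRecords(x)
  if (!is.null(names)) {
    return(recs[vapply(recs, function(r) r$name %in% names, TRUE)])
  }
  if (!is.null(fraction)) {
    if (is.null(rng)) stop("fraction subsetting needs a seeded rng")
    keep <- rngDraw(rng, stats::runif(length(recs))) < fraction
    return(recs[keep])
  }
  recs
}

#' Trim sequence records to a window
#'
#' Keeps \code{length} bases starting at 0-based \code{start}; quality
#' is trimmed in lockstep.  Records shorter than the window are emitted
#' at their available length; their number is reported in a warning.
#'
#' @param x records list or path.
#' @param start 0-based start of the kept window.
#' @param length window length.
#' @return list of trimmed records.
#' @export
fastxTrim <- function(x, start, length) {
  recs <- .asRecords(x)
  short <- 0L
  out <- lapply(recs, function(r) {
    n <- nchar(r$sequence)
    if (start + length > n) short <<- short + 1L
    from <- min(start + 1, n + 1)
    to <- min(start + length, n)
    r$sequence <- substr(r$sequence, from, to)
    if (!is.null(r$quality)) r$quality <- substr(r$quality, from, to)
    r
  })
  if (short > 0) warning(short, " record(s) shorter than the trim window")
  out
}

#' Remove duplicate reads, keyed on sequence only
#'
#' Keeps the first record for each exact sequence; names and qualities
#' do not participate in the key.  Idempotent.
#'
#' @param x records list or path.
#' @return deduplicated records list.
#' @export
fastxDedupe <- function(x) {
  recs <- .asRecords(x)
  seqs <- vapply(recs, `[[`, "", "sequence")
  recs[!duplicated(seqs)]
}
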
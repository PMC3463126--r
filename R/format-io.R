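# Readers and writers for the standard text formats the tools touch:
# SAM, BED, GFF, UCSC refGene.txt, Biomart/generic TSV, wiggle fixedStep.
# Everything is converted to 0-based half-open coordinates on ingest.

.CIGAR_OPS <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")

#' Parse a CIGAR string into (length, op) runs
#' @param cigar CIGAR string, e.g. "5M2D3M".
#' @return data.frame with columns \code{len} (integer), \code{op}.
#' @export
parseCigar <- function(cigar) {
  if (cigar == "*") return(data.frame(len = integer(0), op = character(0)))
  toks <- regmatches(cigar, gregexpr("[0-9]+[A-Z=]", cigar))[[1]]
  if (!length(toks) || sum(nchar(toks)) != nchar(cigar)) {
    stop("malformed CIGAR: ", cigar)
  }
  op <- substring(toks, nchar(toks))
  if (any(!op %in% .CIGAR_OPS)) {
    stop("unknown CIGAR operation '", setdiff(op, .CIGAR_OPS)[1], "' in ", cigar)
  }
  data.frame(len = as.integer(substring(toks, 1, nchar(toks) - 1L)), op = op,
             stringsAsFactors = FALSE)
}

#' Reference-space blocks covered by an alignment
#'
#' Walks the CIGAR from a 0-based leftmost position: M/=/X consume
#' reference and query (covered), D/N consume reference only (gap, not
#' covered), I/S consume query only, H/P consume neither.  Adjacent
#' covered runs are merged.
#'
#' @param pos0 0-based leftmost mapped position.
#' @param cigar CIGAR string.
#' @return two-column matrix of 0-based half-open (start, end) blocks.
#' @export
cigarRefBlocks <- function(pos0, cigar) {
  ops <- parseCigar(cigar)
  cur <- pos0
  starts <- numeric(0); ends <- numeric(0)
  for (k in seq_len(nrow(ops))) {
    op <- ops$op[k]; len <- ops$len[k]
    if (op %in% c("M", "=", "X")) {
      if (length(ends) && ends[length(ends)] == cur) {
        ends[length(ends)] <- cur + len
      } else {
        starts <- c(starts, cur); ends <- c(ends, cur + len)
      }
      cur <- cur + len
    } else if (op %in% c("D", "N")) {
      cur <- cur + len
    }                                   # I/S/H/P: no reference consumed
  }
  cbind(start = starts, end = ends)
}

.samTag <- function(fields, tag, conv = identity) {
  hit <- fields[startsWith(fields, tag)]
  if (!length(hit)) return(NA)
  conv(sub("^..:.:", "", hit[1]))
}

#' Parse a text SAM file into alignment records
#'
#' Mandatory fields are parsed for every record (mapped and unmapped);
#' positions are converted to the internal 0-based half-open convention
#' and reference-covered blocks are derived from the CIGAR.  The NM, MD
#' and NH tags are recognized.  Contig lengths from \code{@SQ} header
#' lines are attached as \code{attr(, "contigLengths")}.
#'
#' @param path text SAM file.
#' @return data.frame with columns qname, flag, chrom, pos0, mapq,
#'   cigar, seq, nm, md, nh, mapped, secondary, duplicate, strand,
#'   spanStart, spanEnd and a list-column \code{blocks} of (start, end)
#'   matrices.
#' @export
parseSam <- function(path) {
  lines <- streamLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  contigLengths <- numeric(0)
  sq <- hdr[startsWith(hdr, "@SQ")]
  for (h in sq) {
    f <- splitTsvLine(h)
    sn <- sub("^SN:", "", f[startsWith(f, "SN:")][1])
    ln <- as.numeric(sub("^LN:", "", f[startsWith(f, "LN:")][1]))
    contigLengths[sn] <- ln
  }
  n <- length(body)
  qname <- character(n); flag <- integer(n); chrom <- character(n)
  pos0 <- numeric(n); mapq <- integer(n); cigar <- character(n)
  seqs <- character(n); nm <- rep(NA_integer_, n); md <- rep(NA_character_, n)
  nh <- rep(NA_integer_, n); blocks <- vector("list", n)
  spanStart <- rep(NA_real_, n); spanEnd <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    f <- splitTsvLine(body[i])
    if (length(f) < 11) stop("malformed SAM record at line ", i, ": ",
                             length(f), " fields")
    fl <- suppressWarnings(as.integer(f[2]))
    p1 <- suppressWarnings(as.numeric(f[4]))
    mq <- suppressWarnings(as.integer(f[5]))
    if (is.na(fl) || is.na(p1) || is.na(mq)) {
      stop("malformed SAM mandatory field at record ", i)
    }
    qname[i] <- f[1]; flag[i] <- fl; chrom[i] <- f[3]
    pos0[i] <- p1 - 1; mapq[i] <- mq; cigar[i] <- f[6]; seqs[i] <- f[10]
    if (length(f) > 11) {
      tags <- f[12:length(f)]
      nm[i] <- .samTag(tags, "NM", as.integer)
      md[i] <- .samTag(tags, "MD", as.character)
      nh[i] <- .samTag(tags, "NH", as.integer)
    }
    mapped <- bitwAnd(fl, 4L) == 0L
    if (mapped && f[6] != "*") {
      b <- cigarRefBlocks(pos0[i], f[6])
      blocks[[i]] <- b
      if (nrow(b)) { spanStart[i] <- b[1, 1]; spanEnd[i] <- b[nrow(b), 2] }
    } else {
      blocks[[i]] <- cbind(start = numeric(0), end = numeric(0))
    }
  }
  out <- data.frame(qname = qname, flag = flag, chrom = chrom, pos0 = pos0,
                    mapq = mapq, cigar = cigar, seq = seqs, nm = nm, md = md,
                    nh = nh, stringsAsFactors = FALSE)
  out$mapped <- bitwAnd(out$flag, 4L) == 0L
  out$secondary <- bitwAnd(out$flag, 256L) != 0L
  out$duplicate <- bitwAnd(out$flag, 1024L) != 0L
  out$strand <- ifelse(bitwAnd(out$flag, 16L) != 0L, "-", "+")
  out$spanStart <- spanStart
  out$spanEnd <- spanEnd
  out$blocks <- blocks
  attr(out, "contigLengths") <- contigLengths
  out
}

# ---- feature tables --------------------------------------------------------

.emptyFeatures <- function() {
  data.frame(id = character(0), name = character(0), chrom = character(0),
              start = numeric(0), end = numeric(0), strand = character(0),
              stringsAsFactors = FALSE)
}

.makeFeatureFrame <- function(id, name, chrom, start, end, strand,
                              blockStarts = NULL, blockEnds = NULL,
                              attrs = NULL) {
  out <- data.frame(id = id, name = name, chrom = chrom,
                    start = as.numeric(start), end = as.numeric(end),
                    strand = strand, stringsAsFactors = FALSE)
  out$blockStarts <- if (is.null(blockStarts)) rep(list(NULL), nrow(out)) else blockStarts
  out$blockEnds <- if (is.null(blockEnds)) rep(list(NULL), nrow(out)) else blockEnds
  out$attrs <- if (is.null(attrs)) rep("", nrow(out)) else attrs
  out
}

.parseCommaList <- function(x) as.numeric(strsplit(sub(",$", "", x), ",")[[1]])

#' Read a feature file in one of the supported dialects
#'
#' All dialects are normalized to 0-based half-open coordinates:
#' BED and refGene are native; GFF rows [start, end] become
#' [start-1, end); Biomart/generic TSV obey the \code{oneBased} flag.
#' refGene exonStarts/exonEnds populate the feature's sub-blocks.
#'
#' @param path feature file.
#' @param dialect one of "bed", "gff", "refgene", "biomart_tsv",
#'   "generic_tsv".
#' @param columnMap for the TSV dialects: named list/vector mapping
#'   roles (chrom, start, end, strand, id, name) to column names (files
#'   with a header) or 1-based column indices.
#' @param oneBased for the TSV dialects: coordinates are 1-based
#'   inclusive (Biomart default TRUE).
#' @param hasHeader for generic_tsv: file carries a header line
#'   (biomart_tsv always does).
#' @return feature data.frame (id, name, chrom, start, end, strand,
#'   blockStarts, blockEnds, attrs).
#' @export
readFeatures <- function(path, dialect = c("bed", "gff", "refgene",
                                           "biomart_tsv", "generic_tsv"),
                         columnMap = NULL, oneBased = NULL, hasHeader = NULL) {
  dialect <- match.arg(dialect)
  lines <- streamLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (dialect == "bed") {
    if (!length(lines)) return(.emptyFeatures())
    rows <- lapply(lines, function(l) strsplit(l, "[ \t]+")[[1]])
    nf <- lengths(rows)
    if (any(nf < 3)) stop("BED rows need at least chrom/start/end")
    get <- function(k, default) vapply(rows, function(r)
      if (length(r) >= k) r[k] else default, "")
    .makeFeatureFrame(id = get(4, ""), name = get(4, ""),
                      chrom = get(1, ""), start = as.numeric(get(2, "0")),
                      end = as.numeric(get(3, "0")),
                      strand = ifelse(nzchar(get(6, "")), get(6, "."), "."))
  } else if (dialect == "gff") {
    if (!length(lines)) return(.emptyFeatures())
    rows <- lapply(lines, splitTsvLine)
    if (any(lengths(rows) < 8)) stop("GFF rows need 8+ tab-separated fields")
    get <- function(k) vapply(rows, function(r) if (length(r) >= k) r[k] else "", "")
    att <- get(9)
    id <- sub('^.*(?:ID=|gene_id[ =]"?)([^;"]+).*$', "\\1", att, perl = TRUE)
    id[!grepl("ID=|gene_id", att)] <- ""
    .makeFeatureFrame(id = id, name = id, chrom = get(1),
                      start = as.numeric(get(4)) - 1, end = as.numeric(get(5)),
                      strand = ifelse(get(7) %in% c("+", "-"), get(7), "."),
                      attrs = att)
  } else if (dialect == "refgene") {
    if (!length(lines)) return(.emptyFeatures())
    rows <- lapply(lines, splitTsvLine)
    if (any(lengths(rows) < 11)) {
      stop("refGene rows need >= 11 columns (bin..exonEnds)")
    }
    get <- function(k) vapply(rows, `[`, "", k)
    bs <- lapply(rows, function(r) .parseCommaList(r[10]))
    be <- lapply(rows, function(r) .parseCommaList(r[11]))
    name2 <- vapply(rows, function(r) if (length(r) >= 13) r[13] else r[2], "")
    .makeFeatureFrame(id = get(2), name = name2, chrom = get(3),
                      start = as.numeric(get(5)), end = as.numeric(get(6)),
                      strand = get(4), blockStarts = bs, blockEnds = be)
  } else {
    hasHeader <- if (is.null(hasHeader)) dialect == "biomart_tsv" else hasHeader
    oneBased <- if (is.null(oneBased)) dialect == "biomart_tsv" else oneBased
    if (is.null(columnMap)) stop(dialect, " requires a columnMap")
    if (!length(lines)) return(.emptyFeatures())
    header <- if (hasHeader) splitTsvLine(lines[1]) else NULL
    body <- if (hasHeader) lines[-1] else lines
    rows <- lapply(body, splitTsvLine)
    colIdx <- function(role, required = TRUE) {
      v <- columnMap[[role]]
      if (is.null(v)) {
        if (required) stop("columnMap lacks required role '", role, "'")
        return(NA_integer_)
      }
      if (is.numeric(v)) return(as.integer(v))
      i <- match(v, header)
      if (is.na(i)) stop("column '", v, "' not found in header")
      i
    }
    take <- function(i, default = "") {
      if (is.na(i)) rep(default, length(rows))
      else vapply(rows, function(r) if (length(r) >= i) r[i] else default, "")
    }
    start <- as.numeric(take(colIdx("start")))
    end <- as.numeric(take(colIdx("end")))
    if (oneBased) start <- start - 1          # 1-based inclusive -> half-open
    strand <- take(colIdx("strand", required = FALSE), ".")
    strand[strand %in% c("1")] <- "+"; strand[strand %in% c("-1")] <- "-"
    strand[!strand %in% c("+", "-")] <- "."
    id <- take(colIdx("id", required = FALSE))
    nm <- take(colIdx("name", required = FALSE))
    .makeFeatureFrame(id = id, name = nm, chrom = take(colIdx("chrom")),
                      start = start, end = end, strand = strand)
  }
}

#' Write features in BED6
#' @param features feature data.frame.
#' @param path output path.
#' @param provenance optional '#' header lines.
#' @export
writeBed <- function(features, path, provenance = NULL) {
  body <- sprintf("%s\t%d\t%d\t%s\t0\t%s", features$chrom,
                  as.integer(features$start), as.integer(features$end),
                  ifelse(nzchar(features$id), features$id, "."),
                  features$strand)
  writeLines(c(provenance, body), path)
  invisible(path)
}

#' Write features in GFF (1-based inclusive coordinates)
#' @inheritParams writeBed
#' @param source value of the GFF source column.
#' @export
writeGff <- function(features, path, source = "ngskit", provenance = NULL) {
  body <- sprintf("%s\t%s\tfeature\t%d\t%d\t.\t%s\t.\tID=%s",
                  features$chrom, source, as.integer(features$start) + 1L,
                  as.integer(features$end), features$strand, features$id)
  writeLines(c(provenance, body), path)
  invisible(path)
}

#' Write features in the UCSC refGene.txt column layout
#'
#' Emits bin, name, chrom, strand, txStart, txEnd, cdsStart, cdsEnd,
#' exonCount, exonStarts, exonEnds, score, name2.  Features without
#' sub-blocks get a single exon spanning the whole interval.
#' @inheritParams writeBed
#' @export
writeRefGene <- function(features, path, provenance = NULL) {
  body <- vapply(seq_len(nrow(features)), function(i) {
    bs <- features$blockStarts[[i]]; be <- features$blockEnds[[i]]
    if (is.null(bs) || !length(bs)) { bs <- features$start[i]; be <- features$end[i] }
    paste(c("0", features$id[i], features$chrom[i], features$strand[i],
            as.integer(features$start[i]), as.integer(features$end[i]),
            as.integer(features$start[i]), as.integer(features$end[i]),
            length(bs), paste0(paste(as.integer(bs), collapse = ","), ","),
            paste0(paste(as.integer(be), collapse = ","), ","),
            "0", features$name[i]), collapse = "\t")
  }, "")
  writeLines(c(provenance, body), path)
  invisible(path)
}

# ---- wiggle ----------------------------------------------------------------

#' Write a coverage track as fixedStep wiggle
#'
#' One fixedStep block per run of consecutive populated positions;
#' starts are 1-based per the wiggle convention.  Runs of zeros are
#' omitted by starting a new block.
#'
#' @param track a \linkS4class{CoverageTrack}.
#' @param path output path.
#' @param span wiggle span (bases per value).
#' @param which which array to export: "total", "forward", "reverse" or
#'   "mismatch".
#' @param provenance optional comment lines (written as "track"-legal
#'   '#' lines before the first block).
#' @export
writeWiggle <- function(track, path, span = 1, which = "total",
                        provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(provenance, con)
  arrays <- slot(track, switch(which, total = "total", forward = "forward",
                               reverse = "reverse", mismatch = "mismatch"))
  for (contig in names(track@contigLengths)) {
    sv <- arrays[[contig]]
    if (is.null(sv) || !length(sv@pos)) {
      writeLines(sprintf("fixedStep chrom=%s start=1 step=%d span=%d",
                         contig, span, span), con)
      next
    }
    runStart <- c(TRUE, diff(sv@pos) != 1)
    runId <- cumsum(runStart)
    for (r in split(seq_along(sv@pos), runId)) {
      writeLines(sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                         contig, as.integer(sv@pos[r[1]]) + 1L, span, span), con)
      writeLines(sprintf("%.10g", sv@val[r]), con)
    }
  }
  invisible(path)
}

#' Read a fixedStep wiggle file back into a CoverageTrack
#'
#' Values land in the \code{total} array; forward/reverse/mismatch stay
#' empty.  Used for round-trips and for feeding precomputed tracks to
#' the peak caller.
#'
#' @param path wiggle file.
#' @return a \linkS4class{CoverageTrack}.
#' @export
readWiggle <- function(path) {
  lines <- streamLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  pos <- list(); val <- list()
  contig <- NULL; cur <- NA_real_; step <- 1
  for (l in lines) {
    if (startsWith(l, "fixedStep")) {
      f <- strsplit(l, "[ \t]+")[[1]]
      kv <- strsplit(f[-1], "=", fixed = TRUE)
      m <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
      contig <- m[["chrom"]]
      cur <- as.numeric(m[["start"]]) - 1
      step <- if ("step" %in% names(m)) as.numeric(m[["step"]]) else 1
      if (is.null(pos[[contig]])) { pos[[contig]] <- numeric(0); val[[contig]] <- numeric(0) }
    } else {
      if (is.null(contig)) stop("wiggle data before any fixedStep header")
      pos[[contig]] <- c(pos[[contig]], cur)
      val[[contig]] <- c(val[[contig]], as.numeric(l))
      cur <- cur + step
    }
  }
  contigs <- names(pos)
  lens <- vapply(contigs, function(cn)
    if (length(pos[[cn]])) max(pos[[cn]]) + 1 else 0, 0)
  tot <- lapply(contigs, function(cn) {
    keep <- val[[cn]] != 0
    new("SparseVector", pos = pos[[cn]][keep], val = val[[cn]][keep])
  })
  names(tot) <- contigs
  emptySv <- lapply(contigs, function(cn) new("SparseVector", pos = numeric(0), val = numeric(0)))
  names(emptySv) <- contigs
  new("CoverageTrack", contigLengths = lens, forward = emptySv,
      reverse = emptySv, total = tot, mismatch = emptySv,
      readsCounted = 0, normalized = FALSE)
}
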
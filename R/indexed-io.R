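# Random access by line number to large text/TSV/FASTA/FASTQ files via a
# persistent byte-offset sidecar index; '\n' separates lines, a preceding
# '\r' is stripped on return, and a final line without newline counts.

.IDX_WIDTH <- 19L  # digits: enough for any 64-bit byte offset

.idxPath <- function(path) paste0(path, ".idx")

# byte offsets of every line start, by chunked scan for '\n'
.scanOffsets <- function(path) {
  size <- file.info(path)$size
  if (is.na(size)) stop("cannot read file: ", path)
  if (size == 0) return(numeric(0))
  con <- file(path, "rb")
  on.exit(close(con))
  starts <- 0
  done <- 0
  repeat {
    chunk <- readBin(con, "raw", n = 4194304L)
    if (!length(chunk)) break
    nl <- which(chunk == as.raw(10L))
    if (length(nl)) starts <- c(starts, done + nl)  # byte after each '\n'
    done <- done + length(chunk)
  }
  starts[starts < size]
}

.writeIndexFile <- function(idx) {
  header <- sprintf("%d\t%.6f\t%d", idx@size, idx@mtime, idx@width)
  body <- sprintf(paste0("%0", idx@width, "d"), idx@offsets)
  writeLines(c(header, body), .idxPath(idx@path))
}

.readIndexFile <- function(path) {
  lines <- readLines(.idxPath(path), warn = FALSE)
  if (!length(lines)) return(NULL)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(hdr) != 3) return(NULL)
  new("LineIndex", path = path, size = as.numeric(hdr[1]),
      mtime = as.numeric(hdr[2]), offsets = as.numeric(lines[-1]),
      width = as.integer(hdr[3]), persisted = TRUE)
}

.indexIsCurrent <- function(idx, path) {
  fi <- file.info(path)
  !is.null(idx) && idx@size == fi$size &&
    abs(idx@mtime - as.numeric(fi$mtime)) < 1e-6
}

#' Build (or load) a byte-offset line index for a text file
#'
#' Scans the file once, noting the starting byte of every line, and
#' writes the index beside the source as \code{<path>.idx}.  If an
#' up-to-date index already exists it is loaded instead of rebuilt; a
#' stale index (source size or modification time changed) triggers a
#' rebuild.  If the directory is not writable the index is kept in
#' memory only, with a warning.
#'
#' @param path path to a readable text file.
#' @param force rebuild even if a current index exists.
#' @return a \linkS4class{LineIndex}.
#' @examples
#' f <- tempfile(); writeLines(c("abc", "de", ""), f)
#' idx <- buildLineIndex(f)
#' getLine(idx, 2)   # "de"
#' @export
buildLineIndex <- function(path, force = FALSE) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (!force && file.exists(.idxPath(path)) && !dir.exists(.idxPath(path))) {
    idx <- tryCatch(suppressWarnings(.readIndexFile(path)),
                    error = function(e) NULL)
    if (.indexIsCurrent(idx, path)) return(idx)
  }
  fi <- file.info(path)
  idx <- new("LineIndex", path = path, size = fi$size,
             mtime = as.numeric(fi$mtime), offsets = .scanOffsets(path),
             width = .IDX_WIDTH, persisted = TRUE)
  ok <- tryCatch({ .writeIndexFile(idx); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    warning("index directory not writable; keeping index in memory for ", path)
    idx@persisted <- FALSE
  }
  idx
}

#' Number of lines known to a LineIndex
#' @param index a \linkS4class{LineIndex}.
#' @return integer line count.
#' @export
nLines <- function(index) length(index@offsets)

#' Read one line by line number
#'
#' Returns line \code{lineNo} (1-based) without its trailing newline,
#' identical to the corresponding element of a sequential read.
#'
#' @param index a \linkS4class{LineIndex}.
#' @param lineNo 1-based line number.
#' @return the line as a character scalar.
#' @export
getLine <- function(index, lineNo) {
  n <- length(index@offsets)
  if (length(lineNo) != 1 || is.na(lineNo) || lineNo < 1 || lineNo > n) {
    stop(sprintf("line %s out of range [1, %d]", as.character(lineNo), n))
  }
  start <- index@offsets[lineNo]
  end <- if (lineNo < n) index@offsets[lineNo + 1] else index@size
  con <- file(index@path, "rb")
  on.exit(close(con))
  seek(con, where = start)
  bytes <- readBin(con, "raw", n = end - start)
  x <- rawToChar(bytes)
  x <- sub("\n$", "", x)
  sub("\r$", "", x)
}

#' Read one TSV row by line number
#'
#' Splits the line on single tab characters; empty fields (including a
#' trailing one) are preserved and no type coercion is applied.
#'
#' @inheritParams getLine
#' @return character vector of fields.
#' @export
getTsvRow <- function(index, lineNo) {
  splitTsvLine(getLine(index, lineNo))
}

#' Split a line on tabs, preserving empty fields
#' @param line character scalar.
#' @return character vector of fields (length = number of tabs + 1).
#' @export
splitTsvLine <- function(line) {
  nf <- nchar(line) - nchar(gsub("\t", "", line, fixed = TRUE)) + 1L
  out <- strsplit(line, "\t", fixed = TRUE)[[1]]
  length(out) <- nf            # restore trailing empties strsplit drops
  out[is.na(out)] <- ""
  out
}

#' Read all lines of a file sequentially, without creating an index
#'
#' @param path readable text file.
#' @return character vector of lines, CR stripped, in file order.
#' @export
streamLines <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  x <- readLines(path, warn = FALSE)
  sub("\r$", "", x)
}

# ---- FASTA / FASTQ ---------------------------------------------------------

#' Build a record-level index over a FASTA or FASTQ file
#'
#' FASTA records may wrap sequence over multiple lines; FASTQ records are
#' strictly 4 lines.  The returned object supports random access through
#' \code{\link{getSequenceRecord}}.
#'
#' @param path FASTA (first char '>') or FASTQ (first char '@') file.
#' @return list with the underlying \linkS4class{LineIndex}, format,
#'   and the starting line of every record.
#' @export
buildSequenceIndex <- function(path) {
  idx <- buildLineIndex(path)
  n <- nLines(idx)
  if (n == 0) return(list(lineIndex = idx, format = "empty",
                          recordStarts = integer(0), nRecords = 0L))
  first <- substr(getLine(idx, 1), 1, 1)
  if (first == ">") {
    starts <- which(vapply(seq_len(n), function(i)
      startsWith(getLine(idx, i), ">"), TRUE))
    list(lineIndex = idx, format = "fasta", recordStarts = starts,
         nRecords = length(starts))
  } else if (first == "@") {
    if (n %% 4 != 0) stop("FASTQ line count not a multiple of 4: ", path)
    list(lineIndex = idx, format = "fastq",
         recordStarts = seq(1L, n, by = 4L), nRecords = n %/% 4L)
  } else stop("not FASTA or FASTQ (first char '", first, "'): ", path)
}

.fastqRecordAt <- function(getl, lineNo, recordNo) {
  name <- getl(lineNo)
  seqs <- getl(lineNo + 1L)
  plus <- getl(lineNo + 2L)
  qual <- getl(lineNo + 3L)
  if (!startsWith(name, "@")) stop("FASTQ record ", recordNo, ": missing '@' header")
  if (!startsWith(plus, "+")) stop("FASTQ record ", recordNo, ": missing '+' line")
  if (nchar(qual) != nchar(seqs)) {
    stop("FASTQ record ", recordNo, ": quality/sequence length mismatch")
  }
  list(name = substring(name, 2), sequence = seqs, quality = qual)
}

#' Random-access read of one FASTA/FASTQ record
#'
#' @param x a path or a prebuilt index from \code{\link{buildSequenceIndex}}.
#' @param recordNo 1-based record number.
#' @return list with \code{name}, \code{sequence} and (FASTQ only)
#'   \code{quality}.
#' @export
getSequenceRecord <- function(x, recordNo) {
  if (is.character(x)) x <- buildSequenceIndex(x)
  if (recordNo < 1 || recordNo > x$nRecords) {
    stop(sprintf("record %d out of range [1, %d]", recordNo, x$nRecords))
  }
  idx <- x$lineIndex
  start <- x$recordStarts[recordNo]
  if (x$format == "fastq") {
    .fastqRecordAt(function(i) getLine(idx, i), start, recordNo)
  } else {
    end <- if (recordNo < x$nRecords) x$recordStarts[recordNo + 1] - 1L else nLines(idx)
    seqLines <- if (end > start)
      vapply(seq(start + 1L, end), function(i) getLine(idx, i), "") else character(0)
    list(name = substring(getLine(idx, start), 2),
         sequence = paste(seqLines, collapse = ""), quality = NULL)
  }
}

#' Sequentially parse every record of a FASTA/FASTQ file
#'
#' @param path FASTA or FASTQ file.
#' @return list of records as in \code{\link{getSequenceRecord}}.
#' @export
readSequenceRecords <- function(path) {
  lines <- streamLines(path)
  if (!length(lines)) return(list())
  if (startsWith(lines[1], ">")) {
    starts <- which(startsWith(lines, ">"))
    ends <- c(starts[-1] - 1L, length(lines))
    lapply(seq_along(starts), function(k) {
      body <- if (ends[k] > starts[k]) lines[(starts[k] + 1L):ends[k]] else character(0)
      list(name = substring(lines[starts[k]], 2),
           sequence = paste(body, collapse = ""), quality = NULL)
    })
  } else if (startsWith(lines[1], "@")) {
    if (length(lines) %% 4 != 0) stop("FASTQ line count not a multiple of 4: ", path)
    lapply(seq_len(length(lines) %/% 4L), function(k) {
      .fastqRecordAt(function(i) lines[i], (k - 1L) * 4L + 1L, k)
    })
  } else stop("not FASTA or FASTQ: ", path)
}
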
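#' @import methods
#' @importFrom stats rpois rbinom runif convolve mad median quantile sd var
#' @importFrom utils head tail packageVersion
NULL

#' LineIndex: persistent byte-offset index of a text file
#'
#' Maps line numbers to byte offsets so that any line of an arbitrarily
#' large text file can be read in constant time.  The serialized sidecar
#' (\code{<source>.idx}) stores one zero-padded fixed-width offset per
#' line, so the k-th entry starts at byte \code{k * (width + 1)} of the
#' index body and can itself be located without scanning.
#'
#' @slot path source file path.
#' @slot size source size in bytes at index time.
#' @slot mtime source modification time (seconds) at index time.
#' @slot offsets numeric vector of byte offsets, one per line; empty for
#'   an empty file.
#' @slot width digits per serialized offset (19 covers 64-bit sizes).
#' @slot persisted whether the sidecar file was written.
#' @exportClass LineIndex
setClass("LineIndex", representation(
  path = "character", size = "numeric", mtime = "numeric",
  offsets = "numeric", width = "integer", persisted = "logical"
))

setValidity("LineIndex", function(object) {
  o <- object@offsets
  if (length(o) && o[1] != 0) return("offsets[1] must be 0")
  if (length(o) > 1 && any(diff(o) <= 0)) return("offsets must be strictly increasing")
  if (length(o) && o[length(o)] >= object@size) return("offsets must lie within the file")
  TRUE
})

setMethod("show", "LineIndex", function(object) {
  cat("LineIndex on", object@path, "\n ", length(object@offsets), "lines,",
      object@size, "bytes,", if (object@persisted) "persisted" else "in-memory", "\n")
})

#' Table: schema-typed columnar container
#'
#' A relational-style table: an ordered set of named, typed columns of
#' equal length.  Column types are restricted to \code{int}, \code{float},
#' \code{string} and \code{bool}; the schema is closed, so outer joins pad
#' missing sides with per-type sentinels (\code{NA} integer, \code{NaN},
#' \code{""}, \code{FALSE}) rather than introducing an option type.
#'
#' @slot schema data.frame with columns \code{name}, \code{type}.
#' @slot data named list of column vectors, parallel to the schema.
#' @exportClass Table
setClass("Table", representation(schema = "data.frame", data = "list"))

.tableRType <- c(int = "integer", float = "double", string = "character",
                 bool = "logical")

setValidity("Table", function(object) {
  s <- object@schema
  if (!all(c("name", "type") %in% names(s))) return("schema needs name/type")
  if (anyDuplicated(s$name)) return("duplicate column names")
  if (any(!nzchar(s$name))) return("empty column name")
  if (!all(s$type %in% names(.tableRType))) {
    return(paste("unknown column type:", paste(setdiff(s$type, names(.tableRType)), collapse = ",")))
  }
  if (length(object@data) != nrow(s)) return("data/schema length mismatch")
  lens <- vapply(object@data, length, 0L)
  if (length(lens) && length(unique(lens)) > 1) return("columns differ in length")
  for (i in seq_len(nrow(s))) {
    if (typeof(object@data[[i]]) != .tableRType[[s$type[i]]]) {
      return(sprintf("column '%s' is %s, expected %s (type %s)",
                     s$name[i], typeof(object@data[[i]]),
                     .tableRType[[s$type[i]]], s$type[i]))
    }
  }
  TRUE
})

setMethod("show", "Table", function(object) {
  cat("Table:", nrowTable(object), "rows x", nrow(object@schema), "columns\n")
  cat(" ", paste(sprintf("%s<%s>", object@schema$name, object@schema$type),
                 collapse = "  "), "\n")
  n <- nrowTable(object)
  if (n) print(utils::head(asDataFrame(object), 5L))
})

#' SparseVector: default-zero numeric vector keyed by position
#'
#' Stores only populated positions (0-based); any other position reads as
#' the default value 0.  Used for per-base coverage where most of a
#' contig is untouched.
#'
#' @slot pos sorted 0-based positions holding non-default values.
#' @slot val values parallel to \code{pos}.
#' @exportClass SparseVector
setClass("SparseVector", representation(pos = "numeric", val = "numeric"))

setValidity("SparseVector", function(object) {
  if (length(object@pos) != length(object@val)) return("pos/val length mismatch")
  if (length(object@pos) > 1 && any(diff(object@pos) <= 0)) {
    return("positions must be strictly increasing")
  }
  if (length(object@pos) && object@pos[1] < 0) return("negative position")
  TRUE
})

setMethod("show", "SparseVector", function(object) {
  cat("SparseVector:", length(object@pos), "populated positions\n")
})

#' CoverageTrack: strand-specific per-base depth and mismatch counts
#'
#' Per-contig sparse vectors of forward, reverse and total read depth
#' plus the count of mismatched bases observed at each reference
#' position.  \code{total == forward + reverse} at every populated
#' position; mismatch counts stay integer tallies even after depth
#' normalization.
#'
#' @slot contigLengths named numeric vector of contig lengths.
#' @slot forward,reverse,total,mismatch named lists of
#'   \linkS4class{SparseVector}, one per contig.
#' @slot readsCounted number of records that passed filters.
#' @slot normalized whether depths are reads-per-million scaled.
#' @exportClass CoverageTrack
setClass("CoverageTrack", representation(
  contigLengths = "numeric", forward = "list", reverse = "list",
  total = "list", mismatch = "list", readsCounted = "numeric",
  normalized = "logical"
))

setValidity("CoverageTrack", function(object) {
  nm <- names(object@contigLengths)
  if (is.null(nm) && length(object@contigLengths)) return("contigLengths must be named")
  for (slot in c("forward", "reverse", "total", "mismatch")) {
    l <- slot(object, slot)
    if (!all(names(l) %in% nm)) return(paste("unknown contig in", slot))
  }
  TRUE
})

setMethod("show", "CoverageTrack", function(object) {
  cat("CoverageTrack:", length(object@contigLengths), "contig(s),",
      object@readsCounted, "reads counted",
      if (object@normalized) "(per-million normalized)" else "", "\n")
})

#' SmoothedTrack: binned, background-corrected, kernel-smoothed signal
#'
#' Dense per-bin signal for one contig: coverage summed within bins,
#' reads-per-million normalized, control-subtracted (floored at zero)
#' and kernel smoothed.  This is the input of the wavelet transform.
#'
#' @slot contig contig name.
#' @slot binSize bases per bin.
#' @slot values dense numeric vector, finite and non-negative.
#' @slot raw the pre-kernel (binned, normalized, background-subtracted)
#'   values; the spike filter measures sharpness here, where a one-bin
#'   spike is still one bin wide.
#' @slot kernel descriptor string, e.g. "gaussian(40)", "box(50)", "none".
#' @exportClass SmoothedTrack
setClass("SmoothedTrack", representation(
  contig = "character", binSize = "numeric", values = "numeric",
  raw = "numeric", kernel = "character"
))

setValidity("SmoothedTrack", function(object) {
  if (object@binSize < 1) return("binSize must be >= 1")
  if (length(object@values) && (any(!is.finite(object@values)) ||
                                any(object@values < 0))) {
    return("values must be finite and >= 0")
  }
  if (length(object@raw) && length(object@raw) != length(object@values)) {
    return("raw and values must have equal length")
  }
  TRUE
})

setMethod("show", "SmoothedTrack", function(object) {
  cat("SmoothedTrack:", object@contig, "-", length(object@values),
      "bins of", object@binSize, "bp, kernel", object@kernel, "\n")
})
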
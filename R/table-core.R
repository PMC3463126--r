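# Relational-style Table: schema-typed columns, filtering, concatenation,
# stable sorting, bound searches, joins via a key->rows map, smoothing.

.sentinelFor <- list(int = NA_integer_, float = NaN, string = "", bool = FALSE)

#' Construct a table schema
#' @param ... column types by name, e.g. \code{tableSchema(n = "int", s = "string")}.
#' @return schema data.frame with columns \code{name}, \code{type}.
#' @export
tableSchema <- function(...) {
  types <- c(...)
  data.frame(name = names(types), type = unname(types),
             stringsAsFactors = FALSE)
}

#' Construct a Table from columns
#' @param schema a schema from \code{\link{tableSchema}}.
#' @param ... column vectors in schema order (recycled from empty when
#'   omitted entirely).
#' @return a \linkS4class{Table}.
#' @examples
#' t <- newTable(tableSchema(n = "int", s = "string"), c(1L, 2L), c("a", "b"))
#' @export
newTable <- function(schema, ...) {
  cols <- list(...)
  if (!length(cols)) {
    cols <- lapply(schema$type, function(ty) vector(.tableRType[[ty]], 0L))
  }
  names(cols) <- schema$name
  new("Table", schema = schema, data = cols)
}

#' Number of rows of a Table
#' @param t a \linkS4class{Table}.
#' @export
nrowTable <- function(t) if (length(t@data)) length(t@data[[1]]) else 0L

#' Extract one column of a Table
#' @param t a \linkS4class{Table}.
#' @param column column name.
#' @export
getColumn <- function(t, column) {
  i <- match(column, t@schema$name)
  if (is.na(i)) stop("unknown column: ", column)
  t@data[[i]]
}

#' Extract one row as a named list
#' @param t a \linkS4class{Table}.
#' @param i row index.
#' @export
getRow <- function(t, i) lapply(t@data, `[`, i)

#' Convert a Table to a data.frame
#' @param t a \linkS4class{Table}.
#' @export
asDataFrame <- function(t) {
  as.data.frame(t@data, stringsAsFactors = FALSE, optional = TRUE)
}

.subsetTable <- function(t, idx, padKeyFrom = NULL) {
  t@data <- lapply(t@data, `[`, idx)
  t
}

.coerceField <- function(x, type, line, column) {
  bad <- function() stop(sprintf("parse error at line %d, column '%s': cannot coerce '%s' to %s",
                                 line, column, x, type), call. = FALSE)
  switch(type,
    int = if (grepl("^[+-]?[0-9]+$", x)) as.integer(x) else bad(),
    float = { v <- suppressWarnings(as.numeric(x)); if (is.na(v) && !(x %in% c("NaN", "nan", "NA"))) bad() else v },
    string = x,
    bool = if (x %in% c("TRUE", "true", "True", "1")) TRUE
           else if (x %in% c("FALSE", "false", "False", "0")) FALSE else bad())
}

#' Read a TSV file into a typed Table
#'
#' Lines beginning with \code{#} (e.g. provenance headers) are skipped.
#' Each data row must have exactly one field per schema column, each
#' coercible to the declared type; violations report the file line
#' number and column name.
#'
#' @param path TSV file.
#' @param schema a \code{\link{tableSchema}}.
#' @param hasHeader whether the first non-comment line is a header row;
#'   if so it is validated against the schema names.
#' @return a \linkS4class{Table}.
#' @export
readTsvTable <- function(path, schema, hasHeader = FALSE) {
  lines <- streamLines(path)
  keep <- !startsWith(lines, "#")
  lineNos <- which(keep)
  lines <- lines[keep]
  if (hasHeader) {
    if (!length(lines)) stop("header declared but file has no data lines")
    hdr <- splitTsvLine(lines[1])
    if (!identical(hdr, schema$name)) {
      stop("header mismatch: file has [", paste(hdr, collapse = ","),
           "], schema expects [", paste(schema$name, collapse = ","), "]")
    }
    lines <- lines[-1]; lineNos <- lineNos[-1]
  }
  ncolumns <- nrow(schema)
  cols <- lapply(schema$type, function(ty) vector(.tableRType[[ty]], length(lines)))
  for (k in seq_along(lines)) {
    f <- splitTsvLine(lines[k])
    if (length(f) != ncolumns) {
      stop(sprintf("parse error at line %d: %d fields, schema expects %d",
                   lineNos[k], length(f), ncolumns))
    }
    for (j in seq_len(ncolumns)) {
      cols[[j]][k] <- .coerceField(f[j], schema$type[j], lineNos[k], schema$name[j])
    }
  }
  names(cols) <- schema$name
  new("Table", schema = schema, data = cols)
}

.renderColumn <- function(x) {
  if (is.double(x)) vapply(x, function(v) sprintf("%.15g", v), "")
  else as.character(x)
}

#' Write a Table as TSV
#'
#' @param t a \linkS4class{Table}.
#' @param path output path.
#' @param header write the column names as the first line.
#' @param provenance optional character vector of \code{#}-prefixed
#'   lines written before the data (see \code{\link{provenanceHeader}}).
#' @export
writeTsvTable <- function(t, path, header = TRUE, provenance = NULL) {
  cols <- lapply(t@data, .renderColumn)
  body <- if (nrowTable(t)) do.call(paste, c(cols, sep = "\t")) else character(0)
  out <- c(provenance,
           if (header) paste(t@schema$name, collapse = "\t"),
           body)
  writeLines(out, path)
  invisible(path)
}

#' Filter rows of a Table by a predicate
#'
#' @param t a \linkS4class{Table}.
#' @param predicate function taking a named row list, returning a logical
#'   scalar.  An error raised by the predicate is re-signalled with the
#'   offending row index attached.
#' @return a Table with exactly the rows satisfying the predicate, in
#'   the original order; schema unchanged.
#' @export
filterRows <- function(t, predicate) {
  n <- nrowTable(t)
  keep <- logical(n)
  for (i in seq_len(n)) {
    keep[i] <- tryCatch(isTRUE(predicate(getRow(t, i))),
                        error = function(e) stop("predicate failed at row ", i,
                                                 ": ", conditionMessage(e), call. = FALSE))
  }
  .subsetTable(t, which(keep))
}

#' Concatenate two Tables with identical schemas
#' @param a,b \linkS4class{Table}s with identical schemas.
#' @return a Table with the rows of \code{a} followed by those of \code{b}.
#' @export
concatTables <- function(a, b) {
  if (!identical(a@schema, b@schema)) {
    diffs <- union(setdiff(paste(a@schema$name, a@schema$type),
                           paste(b@schema$name, b@schema$type)),
                   setdiff(paste(b@schema$name, b@schema$type),
                           paste(a@schema$name, a@schema$type)))
    stop("schema mismatch: ", paste(diffs, collapse = "; "))
  }
  a@data <- Map(c, a@data, b@data)
  a
}

#' Stable multi-column sort of a Table
#'
#' @param t a \linkS4class{Table}.
#' @param by column names to sort on, in priority order.
#' @param ascending logical, recycled over \code{by}.
#' @return the sorted Table; ties preserve input order (stable).
#' @export
sortTable <- function(t, by, ascending = TRUE) {
  bad <- setdiff(by, t@schema$name)
  if (length(bad)) stop("unknown column: ", paste(bad, collapse = ","))
  ascending <- rep_len(ascending, length(by))
  keys <- lapply(by, function(cn) getColumn(t, cn))
  ord <- do.call(order, c(keys, list(method = "radix", decreasing = !ascending)))
  .subsetTable(t, ord)
}

#' Binary-search bounds in a sorted column
#'
#' \code{lowerBound} returns the smallest 1-based row index whose value
#' in \code{column} is \code{>= value}; \code{upperBound} the smallest
#' with value \code{> value}.  Both return \code{nrowTable(t) + 1} when
#' no such row exists.  The column is assumed (not checked) to be sorted
#' ascending.
#'
#' @param t a \linkS4class{Table}.
#' @param column column name, sorted ascending.
#' @param value probe value of the column's type.
#' @return 1-based row index.
#' @export
lowerBound <- function(t, column, value) {
  col <- getColumn(t, column)
  lo <- 0L; hi <- length(col)
  while (lo < hi) {                      # first index (0-based) with col >= value
    mid <- (lo + hi) %/% 2L
    if (col[mid + 1L] < value) lo <- mid + 1L else hi <- mid
  }
  lo + 1L
}

#' @rdname lowerBound
#' @export
upperBound <- function(t, column, value) {
  col <- getColumn(t, column)
  lo <- 0L; hi <- length(col)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (col[mid + 1L] <= value) lo <- mid + 1L else hi <- mid
  }
  lo + 1L
}

.keyStrings <- function(t, on) {
  cols <- lapply(on, function(cn) {
    x <- getColumn(t, cn)
    if (is.double(x)) sprintf("%.17g", x) else as.character(x)
  })
  if (!length(cols)) return(character(nrowTable(t)))
  do.call(paste, c(cols, sep = "\x1f"))
}

#' Build a key-to-rows map over a Table
#'
#' @param t a \linkS4class{Table}.
#' @param keyColumns column names forming the key.
#' @return list with \code{keyColumns} and \code{mapping}, a named list
#'   from key string to the ordered row indices holding that key.  Every
#'   row index appears in exactly one entry.
#' @export
buildKeyMap <- function(t, keyColumns) {
  keys <- .keyStrings(t, keyColumns)
  list(keyColumns = keyColumns,
       mapping = split(seq_len(nrowTable(t)), factor(keys, levels = unique(keys))))
}

#' Relational join of two Tables
#'
#' Result schema: all of \code{a}'s columns, then \code{b}'s non-key
#' columns (name clashes suffixed \code{"_right"}).  Duplicate keys give
#' the full Cartesian pairing.  Inner rows come in \code{a}-major order;
#' \code{left} keeps unmatched \code{a} rows in place, \code{right} and
#' \code{full} append unmatched \code{b} rows after the matched block.
#' Missing sides are padded with per-type sentinels: integer NA, NaN,
#' \code{""}, \code{FALSE}; key columns of appended \code{b} rows carry
#' \code{b}'s key values.  The lookup is performed through a
#' \code{\link{buildKeyMap}} on the smaller table.
#'
#' @param a,b \linkS4class{Table}s.
#' @param on key column names, present in both with matching types.
#' @param how one of \code{"inner"}, \code{"left"}, \code{"right"},
#'   \code{"full"}.
#' @return the joined \linkS4class{Table}.
#' @export
joinTables <- function(a, b, on, how = c("inner", "left", "right", "full")) {
  how <- match.arg(how)
  for (cn in on) {
    ta <- a@schema$type[match(cn, a@schema$name)]
    tb <- b@schema$type[match(cn, b@schema$name)]
    if (is.na(ta) || is.na(tb)) stop("join column missing: ", cn)
    if (ta != tb) stop("join column '", cn, "' type mismatch: ", ta, " vs ", tb)
  }
  keysA <- .keyStrings(a, on)
  keysB <- .keyStrings(b, on)
  # KeyMap built on the smaller side; pairs then ordered a-major.
  if (nrowTable(a) <= nrowTable(b)) {
    km <- buildKeyMap(a, on)
    hitsA <- km$mapping[keysB]                       # per b-row: a indices
    nb <- lengths(hitsA); nb[is.na(names(hitsA)) | vapply(hitsA, is.null, TRUE)] <- 0L
    ib <- rep(seq_len(nrowTable(b)), nb)
    ia <- unlist(hitsA, use.names = FALSE)
    if (is.null(ia)) ia <- integer(0)
    o <- order(ia, ib, method = "radix")
    ia <- ia[o]; ib <- ib[o]
  } else {
    km <- buildKeyMap(b, on)
    hitsB <- km$mapping[keysA]
    na <- lengths(hitsB); na[vapply(hitsB, is.null, TRUE)] <- 0L
    ia <- rep(seq_len(nrowTable(a)), na)
    ib <- unlist(hitsB, use.names = FALSE)
    if (is.null(ib)) ib <- integer(0)
  }
  matchedA <- unique(ia); matchedB <- unique(ib)
  unA <- setdiff(seq_len(nrowTable(a)), matchedA)
  unB <- setdiff(seq_len(nrowTable(b)), matchedB)

  if (how %in% c("left", "full")) {                  # unmatched a rows, in place
    allA <- sort(c(ia, unA))                         # a-major with pads inline
    padA <- allA %in% unA & !(allA %in% ia)
    # rebuild pair lists keeping a-major order
    ord <- order(c(ia, unA), c(ib, rep(Inf, length(unA))), method = "radix")
    ia2 <- c(ia, unA)[ord]; ib2 <- c(ib, rep(NA_integer_, length(unA)))[ord]
    ia <- ia2; ib <- ib2
  }
  appendB <- if (how %in% c("right", "full")) unB else integer(0)

  bNonKey <- setdiff(b@schema$name, on)
  outNamesB <- ifelse(bNonKey %in% a@schema$name, paste0(bNonKey, "_right"), bNonKey)
  schema <- rbind(a@schema,
                  data.frame(name = outNamesB,
                             type = b@schema$type[match(bNonKey, b@schema$name)],
                             stringsAsFactors = FALSE))

  takeWithPad <- function(x, idx, type) {
    out <- x[ifelse(is.na(idx), 1L, idx)]
    out[is.na(idx)] <- .sentinelFor[[type]]
    out
  }
  nMain <- length(ia)
  cols <- vector("list", nrow(schema))
  for (j in seq_along(a@schema$name)) {
    cn <- a@schema$name[j]; ty <- a@schema$type[j]
    main <- takeWithPad(a@data[[j]], ia, ty)
    app <- if (length(appendB)) {
      if (cn %in% on) getColumn(b, cn)[appendB]      # key values from b
      else rep(.sentinelFor[[ty]], length(appendB))
    } else vector(.tableRType[[ty]], 0L)
    cols[[j]] <- c(main, app)
  }
  for (k in seq_along(bNonKey)) {
    cn <- bNonKey[k]
    ty <- b@schema$type[match(cn, b@schema$name)]
    x <- getColumn(b, cn)
    cols[[length(a@schema$name) + k]] <- c(takeWithPad(x, ib, ty),
                                           x[appendB])
  }
  names(cols) <- schema$name
  new("Table", schema = schema, data = cols)
}

#' Smooth a numeric column with an edge-clipped running mean
#'
#' Value \code{i} is replaced by the mean of the window of \code{window}
#' entries centred on it, clipped to the table bounds (the window
#' shrinks at the edges).  The column type becomes \code{float}.
#'
#' @param t a \linkS4class{Table}.
#' @param column name of an \code{int} or \code{float} column.
#' @param window odd window width \code{>= 1}.
#' @return the Table with the smoothed column.
#' @export
smoothColumn <- function(t, column, window) {
  j <- match(column, t@schema$name)
  if (is.na(j)) stop("unknown column: ", column)
  if (!t@schema$type[j] %in% c("int", "float")) {
    stop("column '", column, "' is not numeric")
  }
  if (window < 1 || window %% 2 != 1) stop("window must be odd and >= 1")
  x <- as.numeric(t@data[[j]])
  n <- length(x)
  h <- (window - 1) %/% 2
  sm <- vapply(seq_len(n), function(i) mean(x[max(1, i - h):min(n, i + h)]), 0)
  t@schema$type[j] <- "float"
  t@data[[j]] <- sm
  t
}
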
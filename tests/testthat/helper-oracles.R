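# Independent oracles: deliberately naive implementations used to check
# the package's optimized paths.  They share no code with R/.

# sequential-scan line reader: raw bytes split at '\n', CR stripped
oracleReadLines <- function(path) {
  size <- file.info(path)$size
  if (size == 0) return(character(0))
  bytes <- readBin(path, "raw", n = size)
  nl <- which(bytes == as.raw(10L))
  starts <- c(1L, nl + 1L)
  ends <- c(nl - 1L, length(bytes))
  keep <- starts <= size
  starts <- starts[keep]; ends <- ends[keep]
  out <- vapply(seq_along(starts), function(k) {
    if (ends[k] < starts[k]) "" else rawToChar(bytes[starts[k]:ends[k]])
  }, "")
  sub("\r$", "", out)
}

# bit-vector interval oracle over positions 0..universe-1
bitvecFromIntervals <- function(df, universe = 1000) {
  v <- logical(universe)
  for (k in seq_len(nrow(df))) {
    s <- df$start[k]; e <- min(df$end[k], universe)
    if (e > s) v[(s + 1):e] <- TRUE
  }
  v
}

bitvecToIntervals <- function(v, chrom = "chr1") {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  genomicIntervals(chrom = rep(chrom, sum(keep)), start = starts[keep],
                   end = ends[keep], strand = ".")
}

# nested-loop relational join oracle over data.frames
oracleJoin <- function(da, db, on, how) {
  sentin <- function(x) {
    if (is.integer(x)) NA_integer_
    else if (is.double(x)) NaN
    else if (is.character(x)) ""
    else FALSE
  }
  bNonKey <- setdiff(names(db), on)
  rows <- list()
  matchedB <- logical(nrow(db))
  for (i in seq_len(max(nrow(da), 0))) {
    hit <- FALSE
    for (j in seq_len(max(nrow(db), 0))) {
      if (all(vapply(on, function(cn)
        identical(da[[cn]][i], db[[cn]][j]), TRUE))) {
        hit <- TRUE; matchedB[j] <- TRUE
        rows[[length(rows) + 1L]] <- c(as.list(da[i, , drop = FALSE]),
                                       as.list(db[j, bNonKey, drop = FALSE]))
      }
    }
    if (!hit && how %in% c("left", "full")) {
      pad <- lapply(db[bNonKey], sentin)
      rows[[length(rows) + 1L]] <- c(as.list(da[i, , drop = FALSE]), pad)
    }
  }
  if (how %in% c("right", "full")) {
    for (j in which(!matchedB)) {
      aside <- lapply(names(da), function(cn) {
        if (cn %in% on) db[[cn]][j] else sentin(da[[cn]])
      })
      names(aside) <- names(da)
      rows[[length(rows) + 1L]] <- c(aside, as.list(db[j, bNonKey, drop = FALSE]))
    }
  }
  rows
}

# canonical multiset rendering of join rows for comparison
rowStrings <- function(rows) {
  sort(vapply(rows, function(r)
    paste(vapply(r, function(v) {
      if (is.double(v)) sprintf("%.12g", v) else as.character(v)
    }, ""), collapse = "\x1f"), ""))
}

tableRowStrings <- function(t) {
  df <- asDataFrame(t)
  rowStrings(lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE])))
}

# independent CIGAR walker: per-base reference positions of covered
# (M/=/X) bases and the outer reference span
oracleCigarWalk <- function(pos0, cigar) {
  covered <- numeric(0)
  cur <- pos0
  num <- 0
  for (ch in strsplit(cigar, "")[[1]]) {
    if (grepl("[0-9]", ch)) { num <- num * 10 + as.integer(ch); next }
    if (ch %in% c("M", "=", "X")) {
      covered <- c(covered, seq(cur, length.out = num)); cur <- cur + num
    } else if (ch %in% c("D", "N")) cur <- cur + num
    num <- 0
  }
  list(covered = covered, spanStart = pos0, spanEnd = cur)
}

# brute-force per-base pileup from parsed SAM text lines
oraclePileup <- function(samPath, midpoint = FALSE) {
  lines <- readLines(samPath, warn = FALSE)
  lines <- lines[!startsWith(lines, "@")]
  depth <- list()   # contig -> named numeric (position -> count), by strand
  bump <- function(cn, strand, p) {
    key <- paste0(cn, "/", strand)
    if (is.null(depth[[key]])) depth[[key]] <<- numeric(0)
    for (x in p) {
      k <- as.character(x)
      depth[[key]][k] <<- if (is.na(depth[[key]][k])) 1 else depth[[key]][k] + 1
    }
  }
  for (l in lines) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L || bitwAnd(flag, 256L) != 0L) next
    w <- oracleCigarWalk(as.numeric(f[4]) - 1, f[6])
    strand <- if (bitwAnd(flag, 16L) != 0L) "-" else "+"
    p <- if (midpoint) floor((w$spanStart + w$spanEnd) / 2) else w$covered
    bump(f[3], strand, p)
  }
  depth
}

# exhaustive ridge-linking oracle: per scale step, enumerate all
# injective ridge->maximum assignments within tolerance and take the
# lexicographically best by the stated priority order
oracleLinkRidges <- function(maxima, gapTolerance, posTolFactor) {
  active <- list(); done <- list()
  for (lvl in maxima) {
    m <- length(lvl$positions)
    if (length(active)) {
      prio <- order(-vapply(active, `[[`, 0, "lastCoef"),
                    -vapply(active, `[[`, 0L, "len"),
                    vapply(active, `[[`, 0, "lastPos"), method = "radix")
      nr <- length(active)
      best <- NULL
      recurse <- function(k, used, dists, assign) {
        if (k > nr) {
          d1 <- pmin(dists, 1e9)
          if (is.null(best)) {
            best <<- list(dists = dists, assign = assign)
          } else {
            d2 <- pmin(best$dists, 1e9)
            nz <- which(d1 != d2)
            if (length(nz) && d1[nz[1]] < d2[nz[1]]) {
              best <<- list(dists = dists, assign = assign)
            }
          }
          return(invisible(NULL))
        }
        r <- active[[prio[k]]]
        tol <- posTolFactor * r$lastScaleBins
        cand <- setdiff(which(abs(lvl$positions - r$lastPos) <= tol), used)
        # order candidates by (distance, position) so lexicographic
        # minimization explores best first but we still enumerate all
        # each ridge's preference is (distance, then position); encode
        # both so lexicographic minimization matches the stated rule
        for (j in cand) {
          recurse(k + 1, c(used, j),
                  c(dists, abs(lvl$positions[j] - r$lastPos),
                    lvl$positions[j]), c(assign, j))
        }
        recurse(k + 1, used, c(dists, Inf, Inf), c(assign, NA_integer_))
      }
      recurse(1L, integer(0), numeric(0), integer(0))
      claimed <- logical(m)
      surviving <- list()
      for (k in seq_len(nr)) {
        r <- active[[prio[k]]]
        j <- best$assign[k]
        if (!is.na(j)) {
          claimed[j] <- TRUE
          r$points[[length(r$points) + 1L]] <-
            c(scale = lvl$scaleBins, pos = lvl$positions[j],
              coef = lvl$coefficients[j])
          r$lastPos <- lvl$positions[j]; r$lastCoef <- lvl$coefficients[j]
          r$lastScaleBins <- lvl$scaleBins
          r$len <- r$len + 1L; r$gaps <- 0L
          surviving[[length(surviving) + 1L]] <- r
        } else {
          r$gaps <- r$gaps + 1L
          if (r$gaps > gapTolerance) done[[length(done) + 1L]] <- r
          else surviving[[length(surviving) + 1L]] <- r
        }
      }
      active <- surviving
    } else claimed <- logical(m)
    for (j in which(!claimed)) {
      active[[length(active) + 1L]] <- list(
        points = list(c(scale = lvl$scaleBins, pos = lvl$positions[j],
                        coef = lvl$coefficients[j])),
        lastPos = lvl$positions[j], lastCoef = lvl$coefficients[j],
        lastScaleBins = lvl$scaleBins, len = 1L, gaps = 0L)
    }
  }
  done <- c(done, active)
  # canonical form: sorted signature of each ridge's (scale, pos) chain
  sort(vapply(done, function(r)
    paste(vapply(r$points, function(p)
      sprintf("%g:%g", p[["scale"]], p[["pos"]]), ""), collapse = "|"), ""))
}

ridgeSignatures <- function(ridges) {
  sort(vapply(ridges, function(r)
    paste(sprintf("%g:%g", r$points$scaleBins, r$points$pos), collapse = "|"),
    ""))
}

# random maxima instance for ridge-linking comparisons
randomMaximaInstance <- function(nScales, maxPerScale = 6, span = 60) {
  scales <- sort(2^sample(1:6, nScales), decreasing = TRUE)
  lapply(scales, function(s) {
    m <- sample.int(maxPerScale + 1, 1) - 1L
    pos <- sort(sample.int(span, m))
    list(scaleBases = s, scaleBins = s, positions = pos,
         coefficients = round(stats::runif(m, 0, 10), 1), noise = 1)
  })
}
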
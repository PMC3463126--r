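trackDense <- function(track, contig, what = "total") {
  svDense(slot(track, what)[[contig]], track@contigLengths[[contig]])
}

samWith <- function(records, contigs = c(chr1 = 3000)) {
  f <- tempfile()
  writeLines(c(sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs),
               records), f)
  f
}

test_that("hand pileups: block coverage, strands and midpoint", {
  f <- samWith(c(
    paste("a", 0, "chr1", 1, 60, "10M", "*", 0, 0, strrep("A", 10), "*", sep = "\t"),
    paste("b", 0, "chr1", 3, 60, "10M", "*", 0, 0, strrep("A", 10), "*", sep = "\t")))
  tr <- computeCoverage(parseSam(f))
  expect_equal(trackDense(tr, "chr1")[1:12],
               c(1, 1, 2, 2, 2, 2, 2, 2, 2, 2, 1, 1))
  expect_equal(trackDense(tr, "chr1", "forward"), trackDense(tr, "chr1"))
  expect_equal(svSum(tr@reverse[["chr1"]]), 0)

  m <- samWith(paste("c", 0, "chr1", 11, 60, "10M", "*", 0, 0,
                     strrep("A", 10), "*", sep = "\t"))
  tm <- computeCoverage(parseSam(m), midpoint = TRUE)
  d <- trackDense(tm, "chr1")
  expect_equal(which(d != 0) - 1, 15)     # floor((10+20)/2)
  expect_equal(svSum(tm@total[["chr1"]]), 1)
})

test_that("coverage equals the per-base pileup oracle on random SAMs", {
  genome <- makeGenome(c(chrA = 2000), seed = 41)
  for (s in 1:5) {
    f <- tempfile()
    makeSam(genome, 300, readLength = 30, mismatchRate = 0.02,
            indelRate = 0.2, seed = s, path = f)
    aln <- parseSam(f)
    tr <- computeCoverage(aln)
    oracle <- oraclePileup(f)
    for (strand in c("+", "-")) {
      o <- oracle[[paste0("chrA/", strand)]]
      got <- slot(tr, if (strand == "+") "forward" else "reverse")[["chrA"]]
      expect_equal(got@pos, as.numeric(sort(as.numeric(names(o)))))
      expect_equal(got@val, unname(o[order(as.numeric(names(o)))]))
    }
    # conservation: total mass == aligned M/=/X bases over counted reads
    aligned <- sum(vapply(seq_len(nrow(aln)), function(i) {
      b <- aln$blocks[[i]]; sum(b[, 2] - b[, 1])
    }, 0))
    expect_equal(svSum(tr@total[["chrA"]]), aligned)
    # strand decomposition at every populated position
    tot <- tr@total[["chrA"]]
    expect_equal(tot@val, svGet(tr@forward[["chrA"]], tot@pos) +
                            svGet(tr@reverse[["chrA"]], tot@pos))
    # midpoint mass equals reads counted
    tm <- computeCoverage(aln, midpoint = TRUE)
    expect_equal(svSum(tm@total[["chrA"]]), tm@readsCounted)
  }
})

test_that("filters, regions and normalization behave as documented", {
  recs <- c(
    paste("u1", 0, "chr1", 1, 60, "4M", "*", 0, 0, "AAAA", "*", "NH:i:1",
          "NM:i:0", sep = "\t"),
    paste("u2", 0, "chr1", 1, 60, "4M", "*", 0, 0, "AAAA", "*", "NH:i:2",
          "NM:i:3", sep = "\t"),
    paste("u3", 0, "chr1", 9, 0, "4M", "*", 0, 0, "AAAA", "*", sep = "\t"))
  f <- samWith(recs)
  aln <- parseSam(f)
  expect_equal(computeCoverage(aln)@readsCounted, 3)
  # unique: NH==1 when present, else mapq>0 (u3 has mapq 0)
  expect_equal(computeCoverage(aln, uniqueOnly = TRUE)@readsCounted, 1)
  expect_equal(computeCoverage(aln, maxErrors = 1)@readsCounted, 2)

  reg <- computeCoverage(aln, regions = genomicIntervals("chr1", 0, 2))
  expect_equal(trackDense(reg, "chr1")[1:4], c(2, 2, 0, 0))
  expect_equal(reg@readsCounted, 3)       # regions do not change the count

  norm <- computeCoverage(aln, normalizePerMillion = TRUE)
  expect_equal(norm@total[["chr1"]]@val,
               computeCoverage(aln)@total[["chr1"]]@val * 1e6 / 3)
  expect_false(any(norm@mismatch[["chr1"]]@val != 0))

  unmapped <- samWith(paste("x", 4, "*", 0, 0, "*", "*", 0, 0, "A", "*",
                            sep = "\t"))
  expect_error(computeCoverage(parseSam(unmapped),
                               normalizePerMillion = TRUE), "no reads")
})

test_that("MD walks locate mismatches despite indels and clips", {
  expect_identical(mdMismatchPositions(100, "10M", "4A5"), 104)
  expect_length(mdMismatchPositions(100, "10M", "10"), 0)
  expect_identical(mdMismatchPositions(100, "4M2I6M", "8T1"), 108)
  expect_identical(mdMismatchPositions(100, "4M2D6M", "4^AC0T5"), 106)
  expect_identical(mdMismatchPositions(50, "3S4M", "2G1"), 52)
  expect_error(mdMismatchPositions(0, "4M", "9"), "inconsistent|span")

  genome <- makeGenome(c(chrA = 3000), seed = 42)
  f <- tempfile()
  ms <- makeSam(genome, 150, readLength = 40, mismatchRate = 0.05,
                indelRate = 0.3, seed = 43, path = f)
  aln <- parseSam(f)
  tr <- countMismatches(aln, computeCoverage(aln))
  got <- tr@mismatch[["chrA"]]
  planted <- sort(unlist(ms$truth$mmPos))
  expect_equal(rep(got@pos, got@val), as.numeric(planted))
  # mismatch count never exceeds depth
  expect_true(all(got@val <= svGet(tr@total[["chrA"]], got@pos)))
})

test_that("windowing reduces non-overlapping windows by sum or mean", {
  sv <- sparseVector0(0:9, rep(1, 10))
  tr <- new("CoverageTrack", contigLengths = c(c1 = 10),
            forward = list(c1 = sv), reverse = list(c1 = sparseVector0()),
            total = list(c1 = sv), mismatch = list(c1 = sparseVector0()),
            readsCounted = 1, normalized = FALSE)
  w <- windowTrack(tr, 5, "sum")
  expect_equal(svDense(w@total[["c1"]], 2), c(5, 5))
  expect_equal(svDense(windowTrack(tr, 1, "sum")@total[["c1"]], 10),
               svDense(sv, 10))

  set.seed(44)
  pos <- sort(sample.int(97, 30)) - 1
  val <- stats::runif(30, 0, 5)
  tr@contigLengths <- c(c1 = 97)
  tr@total <- list(c1 = sparseVector0(pos, val))
  dense <- svDense(tr@total[["c1"]], 97)
  for (win in c(4, 10)) {
    for (stat in c("sum", "mean")) {
      got <- windowTrack(tr, win, stat)
      nW <- ceiling(97 / win)
      want <- vapply(seq_len(nW) - 1, function(k) {
        chunk <- dense[(k * win + 1):min((k + 1) * win, 97)]
        if (stat == "sum") sum(chunk) else mean(chunk)
      }, 0)
      expect_equal(svDense(got@total[["c1"]], nW), want)
    }
  }
})

test_that("scaling multiplies depths and prunes zeros", {
  sv <- sparseVector0(c(3, 7), c(2, 4))
  tr <- new("CoverageTrack", contigLengths = c(a = 10, b = 10),
            forward = list(a = sv, b = sv), reverse = list(a = sparseVector0(),
                                                           b = sparseVector0()),
            total = list(a = sv, b = sv), mismatch = list(a = sparseVector0(),
                                                          b = sparseVector0()),
            readsCounted = 1, normalized = FALSE)
  expect_equal(scaleTrack(tr, 1)@total[["a"]]@val, c(2, 4))
  expect_length(scaleTrack(tr, 0)@total[["a"]]@pos, 0)
  per <- scaleTrack(tr, c(a = 2, b = 10))
  expect_equal(per@total[["a"]]@val, c(4, 8))
  expect_equal(per@total[["b"]]@val, c(20, 40))
})
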
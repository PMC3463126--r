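randomTable <- function(n, withDupes = TRUE) {
  k <- if (withDupes) sample.int(max(2, n %/% 3), n, replace = TRUE)
       else sample.int(n * 10, n)
  newTable(tableSchema(k = "int", s = "string", x = "float", b = "bool"),
           as.integer(k),
           sample(LETTERS[1:6], n, replace = TRUE),
           round(stats::runif(n), 3),
           sample(c(TRUE, FALSE), n, replace = TRUE))
}

test_that("TSV tables read, validate and round-trip", {
  f <- tempfile()
  writeLines(c("# provenance", "1\tfoo", "2\tbar"), f)
  s <- tableSchema(n = "int", s = "string")
  t <- readTsvTable(f, s)
  expect_identical(nrowTable(t), 2L)
  expect_identical(getColumn(t, "n"), c(1L, 2L))

  bad <- tempfile()
  writeLines("x\tfoo", bad)
  expect_error(readTsvTable(bad, s), "line 1, column 'n'")
  writeLines("1\tfoo\textra", bad)
  expect_error(readTsvTable(bad, s), "3 fields")

  out <- tempfile()
  writeTsvTable(t, out, header = TRUE)
  t2 <- readTsvTable(out, s, hasHeader = TRUE)
  expect_identical(asDataFrame(t2), asDataFrame(t))
})

test_that("filterRows keeps exactly the matching rows in order", {
  set.seed(1)
  t <- randomTable(40)
  expect_identical(asDataFrame(filterRows(t, function(r) TRUE)),
                   asDataFrame(t))
  none <- filterRows(t, function(r) FALSE)
  expect_identical(nrowTable(none), 0L)
  expect_identical(none@schema, t@schema)

  even <- filterRows(t, function(r) r$k %% 2 == 0)
  df <- asDataFrame(t)
  expect_identical(asDataFrame(even), {
    d <- df[df$k %% 2 == 0, , drop = FALSE]; rownames(d) <- NULL; d
  })
  expect_error(filterRows(t, function(r) stop("boom")), "row 1")
})

test_that("filter composition equals conjunction", {
  set.seed(2)
  t <- randomTable(60)
  p <- function(r) r$k %% 2 == 0
  q <- function(r) r$x > 0.4
  expect_identical(asDataFrame(filterRows(filterRows(t, p), q)),
                   asDataFrame(filterRows(t, function(r) p(r) && q(r))))
})

test_that("concatenation is an associative monoid with the empty table", {
  set.seed(3)
  a <- randomTable(10); b <- randomTable(7); c3 <- randomTable(5)
  empty <- newTable(a@schema)
  expect_identical(asDataFrame(concatTables(a, empty)), asDataFrame(a))
  expect_identical(nrowTable(concatTables(a, b)), 17L)
  expect_identical(asDataFrame(concatTables(concatTables(a, b), c3)),
                   asDataFrame(concatTables(a, concatTables(b, c3))))
  expect_error(concatTables(a, newTable(tableSchema(z = "int"))),
               "schema mismatch")
})

test_that("sorting is stable and matches an order() oracle", {
  set.seed(4)
  t <- randomTable(80)
  df <- asDataFrame(t)
  s1 <- sortTable(t, "k")
  ord <- order(df$k)                     # stable in base R
  expect_identical(asDataFrame(s1)$k, df$k[ord])
  expect_identical(asDataFrame(s1)$s, df$s[ord])

  s2 <- sortTable(t, c("s", "k"), ascending = c(TRUE, FALSE))
  ord2 <- order(df$s, -df$k)
  expect_identical(asDataFrame(s2)$x, df$x[ord2])

  sorted <- sortTable(s1, "k")           # already sorted: unchanged
  expect_identical(asDataFrame(sorted), asDataFrame(s1))
  expect_error(sortTable(t, "nope"), "unknown column")
})

test_that("lower/upper bounds have textbook semantics", {
  t <- newTable(tableSchema(x = "int"), c(1L, 3L, 3L, 5L))
  expect_identical(lowerBound(t, "x", 3L), 2L)
  expect_identical(upperBound(t, "x", 3L), 4L)
  expect_identical(lowerBound(t, "x", 0L), 1L)
  expect_identical(lowerBound(t, "x", 9L), 5L)

  set.seed(5)
  col <- sort(sample.int(50, 60, replace = TRUE))
  ts <- newTable(tableSchema(x = "int"), as.integer(col))
  for (v in sample.int(55, 40, replace = TRUE)) {
    expect_identical(lowerBound(ts, "x", v), sum(col < v) + 1L)
    expect_identical(upperBound(ts, "x", v), sum(col <= v) + 1L)
  }
})

test_that("joins match the nested-loop oracle in all four modes", {
  s1 <- tableSchema(k = "int", v = "string")
  s2 <- tableSchema(k = "int", w = "string")
  a <- newTable(s1, 1L, "x"); b <- newTable(s2, 1L, "y")
  j <- joinTables(a, b, "k", "inner")
  expect_identical(asDataFrame(j),
                   data.frame(k = 1L, v = "x", w = "y",
                              stringsAsFactors = FALSE))

  dis <- joinTables(newTable(s1, 1:2, c("a", "b")),
                    newTable(s2, 3:4, c("c", "d")), "k", "inner")
  expect_identical(nrowTable(dis), 0L)
  full <- joinTables(newTable(s1, 1:2, c("a", "b")),
                     newTable(s2, 3:4, c("c", "d")), "k", "full")
  expect_identical(nrowTable(full), 4L)

  set.seed(6)
  for (trial in 1:12) {
    na <- sample(0:40, 1); nb <- sample(0:40, 1)
    ta <- randomTable(max(na, 1)); tb <- randomTable(max(nb, 1))
    tb@schema$name <- c("k", "s2", "x", "b2")   # one clash ("x"), key k
    names(tb@data) <- tb@schema$name
    for (how in c("inner", "left", "right", "full")) {
      j <- joinTables(ta, tb, "k", how)
      oracle <- oracleJoin(asDataFrame(ta), asDataFrame(tb), "k", how)
      expect_identical(tableRowStrings(j), rowStrings(oracle))
      expect_identical(j@schema$name,
                       c("k", "s", "x", "b", "s2", "x_right", "b2"))
    }
  }
})

test_that("inner join size equals the KeyMap product sum", {
  set.seed(7)
  a <- randomTable(50); b <- randomTable(50)
  km_a <- buildKeyMap(a, "k"); km_b <- buildKeyMap(b, "k")
  expect_identical(sort(unlist(km_a$mapping, use.names = FALSE)),
                   seq_len(nrowTable(a)))   # partition invariant
  keys <- union(names(km_a$mapping), names(km_b$mapping))
  expected <- sum(vapply(keys, function(k)
    length(km_a$mapping[[k]]) * length(km_b$mapping[[k]]), 0))
  expect_identical(nrowTable(joinTables(a, b, "k", "inner")),
                   as.integer(expected))
})

test_that("join key types must match", {
  a <- newTable(tableSchema(k = "int"), 1L)
  b <- newTable(tableSchema(k = "string"), "1")
  expect_error(joinTables(a, b, "k"), "type mismatch")
})

test_that("column smoothing is an edge-clipped running mean", {
  t <- newTable(tableSchema(x = "float"), c(0, 3, 0))
  expect_equal(getColumn(smoothColumn(t, "x", 3), "x"), c(1.5, 1, 1.5))
  expect_equal(getColumn(smoothColumn(t, "x", 1), "x"), c(0, 3, 0))
  const <- newTable(tableSchema(x = "float"), rep(2, 7))
  expect_equal(getColumn(smoothColumn(const, "x", 5), "x"), rep(2, 7))
  expect_error(smoothColumn(t, "x", 2), "odd")
  expect_error(smoothColumn(newTable(tableSchema(s = "string"), "a"), "s", 3),
               "not numeric")
})
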
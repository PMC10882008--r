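# Clonotype I/O, downsampling, diversity, overlap and sharing statistics.

write_airr_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("junction_aa\tduplicate_count\tproductive", rows), path)
  path
}

test_that("AIRR ingest parses, flags and aggregates", {
  p <- write_airr_fixture(c("CASSL\t2\tT", "CARWG\t1\tT", "CASSF\t4\tT"))
  suppressMessages(tbl <- read_clonotypes(p, day = 5, group = "parallel"))
  expect_identical(nrow(tbl$records), 3L)
  expect_true(all(tbl$records$productive))

  # duplicate rows merge with summed counts
  p2 <- write_airr_fixture(c("CASSL\t2\tT", "CASSL\t3\tT"))
  suppressMessages(tbl2 <- read_clonotypes(p2))
  expect_identical(nrow(tbl2$records), 1L)
  expect_identical(tbl2$records$count, 5L)

  # non-productive rows retained but flagged, and excluded from statistics
  p3 <- write_airr_fixture(c("CASSL\t2\tT", "CARWG\t7\tF"))
  suppressMessages(tbl3 <- read_clonotypes(p3))
  expect_identical(nrow(tbl3$records), 2L)
  expect_equal(inverse_simpson(tbl3), 1)

  # missing mandatory column and empty file raise parse errors
  p4 <- tempfile(fileext = ".tsv")
  writeLines(c("sequence\tduplicate_count\tproductive", "CASSL\t2\tT"), p4)
  expect_error(read_clonotypes(p4), "junction_aa")
  p5 <- tempfile(fileext = ".tsv")
  writeLines("junction_aa\tduplicate_count\tproductive", p5)
  expect_error(read_clonotypes(p5), "empty")
})

test_that("immunoSEQ-style dialect and round-trip writing work", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("aminoAcid\ttemplates\tsequenceStatus",
               "CASSL\t4\tIn", "CARWG\t2\tOut"), p)
  suppressMessages(tbl <- read_clonotypes(p, dialect = "immunoseq"))
  expect_identical(sum(tbl$records$productive), 1L)

  out <- tempfile(fileext = ".tsv")
  write_clonotypes(tbl, out)
  suppressMessages(back <- read_clonotypes(out))
  expect_identical(back$records, tbl$records)
})

test_that("clonotype tables validate sequences and aggregate duplicates", {
  expect_error(make_table(c("CASS1", "CASSL")), "non-amino-acid")
  tbl <- make_table(c("cassl", "CASSL", "CARW"), c(2L, 3L, 1L))
  expect_identical(nrow(tbl$records), 2L)
  expect_identical(tbl$records$count[tbl$records$cdr3_aa == "CASSL"], 5L)
})

test_that("downsampling returns exactly n clonotypes, deterministically", {
  tbl <- make_table(random_aa_strings(1500L), counts = rep(1:3, 500L))
  d1 <- downsample_clonotypes(tbl, 1000L, seed = 4L)
  expect_identical(nrow(d1$records), 1000L)
  expect_identical(d1, downsample_clonotypes(tbl, 1000L, seed = 4L))
  expect_false(identical(d1, downsample_clonotypes(tbl, 1000L, seed = 5L)))
  # identity when the table is already at or below the target
  small <- make_table(random_aa_strings(800L))
  expect_identical(downsample_clonotypes(small, 1000L, seed = 1L), small)
  expect_error(downsample_clonotypes(small, 0L), "n")
  # template-level rarefaction preserves the total template budget
  t2 <- downsample_clonotypes(tbl, 500L, seed = 6L, unit = "templates")
  expect_identical(sum(t2$records$count), 500L)
})

test_that("inverse Simpson matches hand values and the vegan cross-check", {
  expect_equal(inverse_simpson(make_table(c("CA", "CC", "CG", "CT"), 5L)), 4)
  expect_equal(inverse_simpson(make_table("CASSL", 17L)), 1)
  expect_equal(inverse_simpson(c(2, 1, 1)), 1 / (0.25 + 0.0625 + 0.0625))
  counts <- c(40, 10, 5, 3, 1, 1)
  expect_equal(inverse_simpson(counts),
               unname(vegan::diversity(counts, index = "invsimpson")),
               tolerance = 1e-12)
})

test_that("Morisita-Horn matches hand values, vegan, and its invariances", {
  a <- make_table(c("CA", "CC"), c(3L, 1L))
  b <- make_table(c("CA", "CC"), c(1L, 3L))
  expect_equal(morisita_overlap(a, b), 0.6)
  expect_equal(morisita_overlap(a, a), 1)
  expect_equal(morisita_overlap(a, make_table(c("CG", "CT"), c(1L, 1L))), 0)
  # symmetry and invariance under uniform scaling of one table's counts
  x <- make_table(random_aa_strings(50L), sample(1:20, 50L, replace = TRUE))
  y <- make_table(c(x$records$cdr3_aa[1:30], random_aa_strings(30L)),
                  sample(1:20, 60L, replace = TRUE))
  expect_equal(morisita_overlap(x, y), morisita_overlap(y, x), tolerance = 1e-12)
  y10 <- make_table(y$records$cdr3_aa, y$records$count * 10L)
  expect_equal(morisita_overlap(x, y), morisita_overlap(x, y10), tolerance = 1e-12)
  # vegan's Horn-Morisita dissimilarity is 1 - overlap
  keys <- union(x$records$cdr3_aa, y$records$cdr3_aa)
  cx <- stats::setNames(numeric(length(keys)), keys); cy <- cx
  cx[x$records$cdr3_aa] <- x$records$count
  cy[y$records$cdr3_aa] <- y$records$count
  expect_equal(morisita_overlap(x, y),
               1 - as.numeric(vegan::vegdist(rbind(cx, cy), method = "horn")),
               tolerance = 1e-12)
})

test_that("sharing partition is a disjoint cover of the union", {
  pa <- partition_sharing(make_table(c("CW", "CY")), make_table(c("CY", "CM")))
  expect_identical(pa$private_a, "CW")
  expect_identical(pa$private_b, "CM")
  expect_identical(pa$shared, "CY")
  expect_identical(partition_sharing(make_table(c("CA", "CC")),
                                     make_table(c("CG", "CT")))$shared,
                   character(0))
  # set-algebra oracle on random repertoire groups
  set.seed(99)
  pool <- random_aa_strings(300L)
  for (rep in 1:10) {
    ga <- lapply(1:3, function(i) make_table(sample(pool, 80L)))
    gb <- lapply(1:2, function(i) make_table(sample(pool, 80L)))
    part <- partition_sharing(ga, gb)
    u <- union(unlist(lapply(ga, function(t) t$records$cdr3_aa)),
               unlist(lapply(gb, function(t) t$records$cdr3_aa)))
    expect_identical(length(part$private_a) + length(part$private_b) +
                       length(part$shared), length(u))
    expect_length(intersect(part$private_a, part$private_b), 0L)
    expect_length(intersect(part$private_a, part$shared), 0L)
  }
})

test_that("T-cell fraction is a validated ratio", {
  expect_equal(t_cell_fraction(225, 1000), 0.225)
  expect_equal(t_cell_fraction(0, 1000), 0)
  expect_equal(t_cell_fraction(7, 1000), 0.007)
  expect_error(t_cell_fraction(10, 5))
  expect_error(t_cell_fraction(1, 0))
})

test_that("downsampling a uniform repertoire preserves diversity", {
  tbl <- make_table(random_aa_strings(2000L), counts = 1L)
  # clonotype-unit downsampling of uniform abundances keeps diversity = n exactly
  divs <- vapply(1:100, function(s)
    inverse_simpson(downsample_clonotypes(tbl, 1000L, seed = s)), 0)
  expect_lt(abs(mean(divs) - 1000) / 1000, 0.05)
})
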
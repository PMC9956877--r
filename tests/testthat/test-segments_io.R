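test_that("segment tables round-trip through TSV exactly", {
  tab <- make_segments(sample = c("S1", "S1", "S2"),
                       chrom = c("1", "2", "1"),
                       start = c(0, 1e6, 500),
                       end = c(1e6, 3e6, 10500),
                       total_cn = c(2.0, 3.7, 4),
                       minor_cn = c(1.0, 0.3, 0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_segments(tab, path)
  back <- read_segments(path, dialect = "integer")
  expect_identical(as.data.frame(back), as.data.frame(tab))
  expect_identical(segment_dialect(back), "integer")

  gz <- withr::local_tempfile(fileext = ".tsv.gz")
  write_segments(tab, gz)
  expect_identical(as.data.frame(read_segments(gz, "integer")),
                   as.data.frame(tab))
})

test_that("a single-row file yields a one-segment table with its length", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tchrom\tstart\tend\ttotal_cn\tminor_cn",
               "S1\t1\t0\t1000000\t2.0\t1.0"), path)
  tab <- read_segments(path, "continuous")
  expect_equal(nrow(tab), 1L)
  expect_equal(unname(callable_length(tab)), 1e6)
})

test_that("row order in the file does not matter", {
  header <- "sample\tchrom\tstart\tend\ttotal_cn\tminor_cn"
  rows <- c("S1\t2\t0\t100\t2\t1", "S1\t1\t50\t100\t3\t1",
            "S1\t1\t0\t50\t2\t0")
  a <- withr::local_tempfile(fileext = ".tsv")
  b <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(header, rows), a)
  writeLines(c(header, rev(rows)), b)
  expect_identical(as.data.frame(read_segments(a, "integer")),
                   as.data.frame(read_segments(b, "integer")))
})

test_that("validation rejects overlap, negative CN and missing minor", {
  expect_error(make_segments("S1", c("1", "1"), c(0, 50), c(100, 150),
                             c(2, 3), c(1, 1)), "overlap")
  expect_error(make_segments("S1", "1", 0, 100, -1, 0), "negative")
  expect_error(make_segments("S1", "1", 0, 100, 2, NA), "minor_cn")
  expect_error(make_segments("S1", "1", 100, 100, 2, 1), "end <= start")
  # minor allele must be the smaller allele
  expect_error(make_segments("S1", "1", 0, 100, 2, 1.5), "exceeds")
  # same coordinates on different samples or chromosomes are fine
  expect_silent(make_segments(c("S1", "S2"), c("1", "1"), c(0, 0),
                              c(100, 100), c(2, 2), c(1, 1)))
})

test_that("malformed rows are reported with their line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tchrom\tstart\tend\ttotal_cn\tminor_cn",
               "S1\t1\t0\t1000\t2\t1",
               "S1\t1\tx\t2000\t2\t1"), path)
  expect_error(read_segments(path, "integer"), "line 3")
})

test_that("non-autosomal rows are dropped without touching autosomal stats", {
  header <- "sample\tchrom\tstart\tend\ttotal_cn\tminor_cn"
  auto <- c("S1\t1\t0\t1000000\t2\t1", "S1\t2\t0\t2000000\t4\t2")
  a <- withr::local_tempfile(fileext = ".tsv")
  b <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(header, auto), a)
  writeLines(c(header, auto, "S1\tX\t0\t5000000\t1\t0",
               "S1\tchrY\t0\t1000000\t1\t0"), b)
  ta <- read_segments(a, "integer")
  expect_message(tb <- read_segments(b, "integer"), "2 non-autosomal")
  expect_identical(as.data.frame(ta), as.data.frame(tb))
  expect_equal(average_ploidy(ta), average_ploidy(tb))
  expect_equal(loh_fraction(ta), loh_fraction(tb))
})

test_that("1-based input coordinates are converted on read", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tchrom\tstart\tend\ttotal_cn\tminor_cn",
               "S1\t1\t1\t1000000\t2\t1"), path)
  tab <- read_segments(path, "integer", one_based = TRUE)
  expect_equal(tab$start, 0)
  expect_equal(unname(callable_length(tab)), 1e6)
})

test_that("clinical tables parse treatments and enforce unique samples", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\ttumor_type\ttreatments",
               "S1\tcolorectal\tPlatinum;Pyrimidine_antagonist",
               "S2\tlung\t"), path)
  cl <- read_clinical(path)
  expect_equal(cl$treatments[[1]],
               c("platinum", "pyrimidine_antagonist"))
  expect_equal(cl$treatments[[2]], character(0))

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\ttumor_type\ttreatments",
               "S1\tcolorectal\tplatinum", "S1\tlung\t"), dup)
  expect_error(read_clinical(dup), "duplicate")

  extra <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\ttumor_type\ttreatments\tshoe_size",
               "S1\tcolorectal\tplatinum\t42"), extra)
  expect_warning(cl2 <- read_clinical(extra), "shoe_size")
  expect_false("shoe_size" %in% names(cl2))
})

test_that("feature matrices round-trip and reject wrong column sets", {
  canon <- cn_category_space()$label
  zero <- matrix(0L, nrow = 1, ncol = 48, dimnames = list("S1", canon))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(zero, path)
  expect_equal(read_feature_matrix(path), zero + 0)

  set.seed(11)
  mat <- matrix(rpois(2 * 48, 3), nrow = 2,
                dimnames = list(c("S1", "S2"), canon))
  write_feature_matrix(mat, path)
  expect_equal(read_feature_matrix(path), mat + 0)
  # column order in the input does not matter; output is canonical
  write_feature_matrix(mat[, rev(canon)], path)
  expect_equal(read_feature_matrix(path), mat + 0)

  expect_error(write_feature_matrix(mat[, -1], path), "48")
  colnames(mat)[1] <- "not-a-category"
  expect_error(write_feature_matrix(mat, path), "48")
})
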
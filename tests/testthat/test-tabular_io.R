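test_that("wide TSV round-trips and preserves row order", {
  tab <- tiny_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_table(tab, path, "wide_tsv")
  back <- read_abundance_table(path, "wide_tsv")
  expect_identical(back$proteins$accession, tab$proteins$accession)
  expect_equal(back$values, tab$values)
  expect_identical(back$donors, tab$donors)
  expect_identical(back$conditions, tab$conditions)
})

test_that("wide and long dialects read the same values", {
  tab <- tiny_table()
  p_wide <- withr::local_tempfile(fileext = ".tsv")
  p_long <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_table(tab, p_wide, "wide_tsv")
  write_abundance_table(tab, p_long, "long_tsv")
  w <- read_abundance_table(p_wide, "wide_tsv")
  l <- read_abundance_table(p_long, "long_tsv")
  expect_equal(w$values, l$values)
  expect_identical(w$proteins, l$proteins)
})

test_that("malformed tables are hard errors with useful coordinates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\td1:ctrl\td1:doped",
               "P04264\t1\t2",
               "P04264\t3\t4"), path)
  expect_error(read_abundance_table(path, "wide_tsv"), "P04264")

  writeLines(c("accession\td1:ctrl\td2:ctrl\td1:doped",
               "P1\t1\t2\t3"), path)
  expect_error(read_abundance_table(path, "wide_tsv"), "ragged")

  writeLines(c("accession\td1:ctrl\td1:doped",
               "P1\t1\toops"), path)
  err <- tryCatch(read_abundance_table(path, "wide_tsv"),
                  error = conditionMessage)
  expect_match(err, "oops")
  expect_match(err, "P1")
  expect_match(err, "d1:doped")
})

test_that("missing cells are kept explicitly, not dropped", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\td1:ctrl\td2:ctrl\td1:doped\td2:doped",
               "P1\t1\tNA\t3\t",
               "P2\t1\t2\t3\t4"), path)
  tab <- read_abundance_table(path, "wide_tsv")
  expect_equal(sum(is.na(tab$values)), 2L)
  expect_equal(nrow(tab$values), 2L)
})

test_that("round-trip holds on fuzzed tables across dialects", {
  for (seed in 1:5) {
    tab <- random_table(n = 7, seed = seed)
    for (dialect in c("wide_tsv", "wide_csv", "long_tsv")) {
      path <- withr::local_tempfile()
      write_abundance_table(tab, path, dialect)
      back <- read_abundance_table(path, dialect)
      expect_equal(back$values, tab$values, tolerance = 0)
      expect_identical(back$proteins$accession, tab$proteins$accession)
    }
  }
})

test_that("results tables have the fixed layout and round-trip", {
  df <- data.frame(accession = c("A", "B", "C", "D"),
                   gene = "g", name = "n",
                   distance = c(3.2, 2.1, 1.05, 0.5),
                   threshold_flag = c(TRUE, TRUE, FALSE, FALSE),
                   p_value = c(0.03166, 0.77209, 0.5, 0.00015),
                   tier = c("sig", "ns", "ns", "sig"),
                   logFC = c(1.5, -2, 0, 0.25),
                   var_ref = c(13.0, 8.47, 1.83, 0.01),
                   var_trt = c(0.72, 2.79, 5.37, 0.25),
                   abs_var_diff = c(12.28, 5.68, 3.54, 0.24),
                   stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(df, path)
  back <- read_results_table(path)
  expect_identical(names(back)[1:11],
                   c("accession", "gene", "name", "distance",
                     "threshold_flag", "p_value", "tier", "logFC",
                     "var_ref", "var_trt", "abs_var_diff"))
  # printed precision (5 decimals for p, 2 for variances) is stable: a
  # second write/read cycle changes nothing
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(back, path2)
  expect_identical(read_results_table(path2), back)
  expect_equal(back$p_value, df$p_value)
  expect_equal(back$abs_var_diff, df$abs_var_diff)
})

test_that("an empty record set writes a header-only file", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(data.frame(), path)
  expect_length(readLines(path), 1L)
  expect_equal(nrow(read_results_table(path)), 0L)
})
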
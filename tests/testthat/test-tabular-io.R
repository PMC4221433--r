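test_that("read_sheet parses delimited files into padded rectangular grids", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g\ts1\ts2", "a\t1\t2", "b\t3\t4"), tf)
  sh <- read_sheet(tf)
  expect_s3_class(sh, "raw_sheet")
  expect_equal(c(sh$n_rows, sh$n_cols), c(3L, 3L))
  expect_equal(sh$cells[1, ], c("g", "s1", "s2"))
  expect_equal(sh$cells[3, ], c("b", "3", "4"))

  # ragged CSV: first row of 2 fields padded to the 3-field width
  cf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2,3"), cf)
  sh2 <- read_sheet(cf)
  expect_equal(c(sh2$n_rows, sh2$n_cols), c(2L, 3L))
  expect_equal(sh2$cells[1, ], c("a", "b", ""))

  # RFC-4180 quoting in CSV
  qf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c('"x,y",s1', 'g,"1"'), qf)
  expect_equal(read_sheet(qf)$cells[1, 1], "x,y")
})

test_that("read_sheet rejects unreadable or unrecognizable input", {
  expect_error(read_sheet(tempfile()), class = "heatcraft_io_error")
  ef <- withr::local_tempfile(fileext = ".csv")
  file.create(ef)
  expect_error(read_sheet(ef), class = "heatcraft_format_error")
  uf <- withr::local_tempfile(fileext = ".dat")
  writeLines("1,2", uf)
  expect_error(read_sheet(uf), class = "heatcraft_format_error")
  expect_equal(read_sheet(uf, dialect = "csv")$cells[1, ], c("1", "2"))
})

test_that("select_area extracts values and labels at 1-based coordinates", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g\ts1\ts2", "a\t1\t2", "b\t3\t4"), tf)
  sh <- read_sheet(tf)

  tb <- select_area(sh, area_selection(2, 3, 2, 3, title_row = 1, title_col = 1))
  expect_equal(tb$values, matrix(c(1, 3, 2, 4), 2))
  expect_equal(tb$row_labels, c("a", "b"))
  expect_equal(tb$col_labels, c("s1", "s2"))

  # minimal single-cell area without titles synthesizes labels
  one <- select_area(sh, area_selection(2, 2, 2, 2))
  expect_equal(one$values, matrix(1, 1, 1))
  expect_equal(one$row_labels, "R1")
  expect_equal(one$col_labels, "C1")

  expect_error(select_area(sh, area_selection(2, 4, 2, 3)),
               class = "heatcraft_range_error")
  expect_error(area_selection(2, 3, 2, 3, title_row = 2),
               class = "heatcraft_range_error")
})

test_that("non-numeric cells inside the data area are named in the error", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("g,s1", "a,NA", "b,2"), tf)
  sh <- read_sheet(tf)
  err <- expect_error(auto_fill(sh), class = "heatcraft_validation_error")
  expect_match(conditionMessage(err), "row 2, col 2")
  expect_match(conditionMessage(err), "NA")
})

test_that("auto_fill equals select_area with first row/column as titles", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g\ts1\ts2", "a\t1\t2", "b\t3\t4"), tf)
  sh <- read_sheet(tf)
  expect_equal(auto_fill(sh),
               select_area(sh, area_selection(2, 3, 2, 3,
                                              title_row = 1, title_col = 1)))

  m2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",s1", "a,7"), m2)
  tb <- auto_fill(read_sheet(m2))
  expect_equal(tb$values, matrix(7, 1, 1))

  one_row <- withr::local_tempfile(fileext = ".csv")
  writeLines("1,2,3,4,5", one_row)
  expect_error(auto_fill(read_sheet(one_row)), class = "heatcraft_validation_error")
})

test_that("write_table round-trips through read_sheet + auto_fill exactly", {
  withr::with_seed(42, {
    for (dialect in c("tsv", "csv")) {
      for (rep in 1:10) {
        nr <- sample(1:6, 1); nc <- sample(1:5, 1)
        vals <- matrix(stats::rnorm(nr * nc) * 10^sample(-5:5, 1), nr, nc)
        labels_r <- replicate(nr, paste(sample(letters, 4), collapse = ""))
        tb <- expression_table(vals, labels_r, paste0("s", seq_len(nc)))
        path <- tempfile(fileext = paste0(".", dialect))
        write_table(tb, path, dialect)
        back <- auto_fill(read_sheet(path))
        expect_identical(back$values, tb$values)
        expect_identical(back$row_labels, tb$row_labels)
        expect_identical(back$col_labels, tb$col_labels)
        unlink(path)
      }
    }
  })
})

test_that("CSV labels containing the delimiter survive quoting; TSV refuses tabs", {
  tb <- expression_table(matrix(1:4, 2) + 0.5,
                         row_labels = c('ge,ne "1"', ""),
                         col_labels = c("c,1", "c2"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(tb, path, "csv")
  back <- auto_fill(read_sheet(path))
  expect_identical(back$row_labels, tb$row_labels)
  expect_identical(back$col_labels, tb$col_labels)
  expect_identical(back$values, tb$values)

  bad <- expression_table(matrix(1, 1, 1), "a\tb", "c")
  expect_error(write_table(bad, tempfile(), "tsv"),
               class = "heatcraft_validation_error")
})

test_that("Excel workbooks load through the same raw-sheet interface", {
  xf <- withr::local_tempfile(fileext = ".xlsx")
  ok <- write_xlsx_fixture(xf, list(list("g", "s1", "s2"),
                                    list("a", 1, 2),
                                    list("b", 3.25, 4)))
  expect_true(ok)
  sh <- read_sheet(xf)
  expect_equal(c(sh$n_rows, sh$n_cols), c(3L, 3L))
  tb <- auto_fill(sh)
  expect_equal(tb$values, matrix(c(1, 3.25, 2, 4), 2))
  expect_equal(tb$col_labels, c("s1", "s2"))
})
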
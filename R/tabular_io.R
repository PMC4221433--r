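#' Read a raw sheet from a CSV, TSV or Excel file
#'
#' Loads the first worksheet (Excel) or the whole file (delimited text) as a
#' rectangular grid of text cells. Ragged rows are right-padded with empty
#' cells so every row has the same length. Numeric content is kept as text
#' here; parsing to numbers happens when a data area is selected with
#' [select_area()] or [auto_fill()].
#'
#' @param path Path to a `.csv`, `.tsv`, `.xls` or `.xlsx` file.
#' @param dialect Optional format override, one of `"csv"`, `"tsv"`, `"xls"`,
#'   `"xlsx"`. When omitted it is inferred from the file extension.
#' @return A `raw_sheet` object: a list with a character matrix `cells`
#'   (verbatim cell text, `""` for blanks), counts `n_rows`/`n_cols`,
#'   `source_path` and `dialect`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("g\ts1\ts2", "a\t1\t2", "b\t3\t4"), tf)
#' sheet <- read_sheet(tf)
#' sheet$n_rows
#' @export
read_sheet <- function(path, dialect = NULL) {
  if (!file.exists(path)) {
    stop_heatcraft(sprintf("cannot read '%s': file does not exist", path),
                   "heatcraft_io_error")
  }
  if (is.null(dialect)) {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("csv", "tsv", "xls", "xlsx")) {
      stop_heatcraft(sprintf(
        "cannot infer format of '%s' from extension '%s'; pass dialect=",
        path, ext), "heatcraft_format_error")
    }
    dialect <- ext
  }
  dialect <- match.arg(dialect, c("csv", "tsv", "xls", "xlsx"))

  cells <- switch(dialect,
    csv  = read_delimited(path, sep = ",", quote = "\""),
    tsv  = read_delimited(path, sep = "\t", quote = ""),
    xls  = ,
    xlsx = read_excel_cells(path)
  )
  if (is.null(cells) || nrow(cells) == 0L || ncol(cells) == 0L) {
    stop_heatcraft(sprintf("'%s' contains no rows", path),
                   "heatcraft_format_error")
  }
  new_raw_sheet(cells, path, dialect)
}

new_raw_sheet <- function(cells, source_path, dialect) {
  stopifnot(is.matrix(cells), is.character(cells))
  structure(
    list(cells = cells, n_rows = nrow(cells), n_cols = ncol(cells),
         source_path = source_path, dialect = dialect),
    class = "raw_sheet")
}

read_delimited <- function(path, sep, quote) {
  df <- tryCatch(
    utils::read.table(path, sep = sep, quote = quote, header = FALSE,
                      colClasses = "character", fill = TRUE,
                      na.strings = character(0), comment.char = "",
                      blank.lines.skip = FALSE, strip.white = FALSE),
    error = function(e) {
      stop_heatcraft(sprintf("'%s' could not be parsed: %s", path,
                             conditionMessage(e)), "heatcraft_format_error")
    })
  m <- as.matrix(df)
  m[is.na(m)] <- ""
  dimnames(m) <- NULL
  m
}

read_excel_cells <- function(path) {
  df <- readxl::read_excel(path, col_names = FALSE, col_types = "text",
                           .name_repair = "minimal")
  if (nrow(df) == 0L || ncol(df) == 0L) return(matrix(character(0), 0, 0))
  m <- as.matrix(df)
  m[is.na(m)] <- ""
  dimnames(m) <- NULL
  m
}

#' @export
print.raw_sheet <- function(x, ...) {
  cat(sprintf("<raw_sheet> %d x %d cells from %s (%s)\n",
              x$n_rows, x$n_cols, x$source_path, x$dialect))
  invisible(x)
}

#' Describe a rectangular data area inside a raw sheet
#'
#' Coordinates are 1-based and inclusive, matching how spreadsheet interfaces
#' number rows and columns. `title_row`/`title_col`, when given, name the
#' sheet row/column holding the X-axis/Y-axis labels and must lie outside the
#' data area.
#'
#' @param row_start,row_end,col_start,col_end 1-based inclusive bounds of the
#'   numeric data block.
#' @param title_row Optional sheet row providing column (X-axis) labels.
#' @param title_col Optional sheet column providing row (Y-axis) labels.
#' @return An `area_selection` object.
#' @export
area_selection <- function(row_start, row_end, col_start, col_end,
                           title_row = NULL, title_col = NULL) {
  for (v in list(row_start, row_end, col_start, col_end)) {
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != trunc(v)) {
      stop_heatcraft("area bounds must be positive whole numbers",
                     "heatcraft_range_error")
    }
  }
  if (row_start > row_end || col_start > col_end) {
    stop_heatcraft("area start must not exceed area end",
                   "heatcraft_range_error")
  }
  if (!is.null(title_row) && title_row >= row_start && title_row <= row_end) {
    stop_heatcraft("title_row must lie outside the data area",
                   "heatcraft_range_error")
  }
  if (!is.null(title_col) && title_col >= col_start && title_col <= col_end) {
    stop_heatcraft("title_col must lie outside the data area",
                   "heatcraft_range_error")
  }
  structure(list(row_start = as.integer(row_start), row_end = as.integer(row_end),
                 col_start = as.integer(col_start), col_end = as.integer(col_end),
                 title_row = if (!is.null(title_row)) as.integer(title_row),
                 title_col = if (!is.null(title_col)) as.integer(title_col)),
            class = "area_selection")
}

#' Extract a labeled numeric expression table from a raw sheet
#'
#' Every cell inside the data area must parse as a finite number; a blank or
#' textual cell is a hard error naming the offending sheet coordinate (no
#' imputation is attempted). Labels come from the selection's title row and
#' column when set, and are synthesized as `R1..Rn` / `C1..Cn` otherwise.
#'
#' @param sheet A `raw_sheet` from [read_sheet()].
#' @param sel An [area_selection()].
#' @return An `expression_table`: list with numeric matrix `values` and
#'   character vectors `row_labels`, `col_labels` (duplicates preserved).
#' @export
select_area <- function(sheet, sel) {
  stopifnot(inherits(sheet, "raw_sheet"), inherits(sel, "area_selection"))
  if (sel$row_end > sheet$n_rows || sel$col_end > sheet$n_cols ||
      (!is.null(sel$title_row) && sel$title_row > sheet$n_rows) ||
      (!is.null(sel$title_col) && sel$title_col > sheet$n_cols)) {
    stop_heatcraft(sprintf("selection exceeds sheet bounds (%d x %d)",
                           sheet$n_rows, sheet$n_cols),
                   "heatcraft_range_error")
  }
  rows <- sel$row_start:sel$row_end
  cols <- sel$col_start:sel$col_end
  block <- sheet$cells[rows, cols, drop = FALSE]

  ok <- is_number_like(block)
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    r <- rows[(bad - 1L) %% length(rows) + 1L]
    c <- cols[(bad - 1L) %/% length(rows) + 1L]
    stop_heatcraft(sprintf(
      "cell (row %d, col %d) of the data area is not numeric: '%s'",
      r, c, sheet$cells[r, c]), "heatcraft_validation_error")
  }
  values <- matrix(parse_number(block), nrow = length(rows))
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values))[1L]
    r <- rows[(bad - 1L) %% length(rows) + 1L]
    c <- cols[(bad - 1L) %/% length(rows) + 1L]
    stop_heatcraft(sprintf("cell (row %d, col %d) is not finite", r, c),
                   "heatcraft_validation_error")
  }

  row_labels <- if (!is.null(sel$title_col)) {
    as.character(sheet$cells[rows, sel$title_col])
  } else paste0("R", seq_along(rows))
  col_labels <- if (!is.null(sel$title_row)) {
    as.character(sheet$cells[sel$title_row, cols])
  } else paste0("C", seq_along(cols))

  expression_table(values, row_labels, col_labels)
}

#' Construct an expression table directly from a numeric matrix
#'
#' @param values Numeric matrix of finite values.
#' @param row_labels,col_labels Label vectors matching the matrix dimensions;
#'   synthesized as `R1..Rn` / `C1..Cn` when omitted. Duplicates are allowed.
#' @return An `expression_table` object.
#' @export
expression_table <- function(values, row_labels = NULL, col_labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_heatcraft("values must be a numeric matrix", "heatcraft_validation_error")
  }
  if (any(!is.finite(values))) {
    stop_heatcraft("values must all be finite", "heatcraft_validation_error")
  }
  row_labels <- row_labels %||% paste0("R", seq_len(nrow(values)))
  col_labels <- col_labels %||% paste0("C", seq_len(ncol(values)))
  if (length(row_labels) != nrow(values) || length(col_labels) != ncol(values)) {
    stop_heatcraft("label lengths must match matrix dimensions",
                   "heatcraft_validation_error")
  }
  storage.mode(values) <- "double"
  dimnames(values) <- NULL
  structure(list(values = values,
                 row_labels = as.character(row_labels),
                 col_labels = as.character(col_labels)),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("<expression_table> %d x %d\n", nrow(x$values), ncol(x$values)))
  m <- x$values
  dimnames(m) <- list(x$row_labels, x$col_labels)
  print(utils::head(m, 6L))
  if (nrow(m) > 6L) cat(sprintf("... %d more rows\n", nrow(m) - 6L))
  invisible(x)
}

#' @export
dim.expression_table <- function(x) dim(x$values)

#' Treat the first row and column of a sheet as axis titles
#'
#' Convenience equivalent of [select_area()] with the data area set to rows
#' `2..n_rows` and columns `2..n_cols`, the first sheet row giving the X-axis
#' (column) labels and the first column the Y-axis (row) labels.
#'
#' @param sheet A `raw_sheet` of at least 2 x 2 cells.
#' @return An `expression_table`.
#' @export
auto_fill <- function(sheet) {
  stopifnot(inherits(sheet, "raw_sheet"))
  if (sheet$n_rows < 2L || sheet$n_cols < 2L) {
    stop_heatcraft(sprintf(
      "auto_fill needs a sheet of at least 2 x 2 cells, got %d x %d",
      sheet$n_rows, sheet$n_cols), "heatcraft_validation_error")
  }
  select_area(sheet, area_selection(2L, sheet$n_rows, 2L, sheet$n_cols,
                                    title_row = 1L, title_col = 1L))
}

#' Write an expression table to CSV or TSV
#'
#' The layout mirrors the [auto_fill()] convention: an empty corner cell, the
#' column labels as the first row and the row labels as the first column, so
#' that `auto_fill(read_sheet(path))` recovers the table exactly (values at
#' full precision, labels verbatim). CSV fields are quoted per RFC 4180 when
#' needed; TSV does no quoting and refuses labels containing tabs or newlines.
#'
#' @param table An `expression_table`.
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path, dialect = c("tsv", "csv")) {
  stopifnot(inherits(table, "expression_table"))
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","

  quote_field <- function(s) {
    if (dialect == "tsv") {
      if (any(grepl("[\t\n\r]", s))) {
        stop_heatcraft("TSV fields cannot contain tabs or newlines",
                       "heatcraft_validation_error")
      }
      return(s)
    }
    needs <- grepl('[",\n\r]', s)
    s[needs] <- paste0('"', gsub('"', '""', s[needs]), '"')
    s
  }

  header <- paste(c("", quote_field(table$col_labels)), collapse = sep)
  body <- vapply(seq_len(nrow(table$values)), function(i) {
    paste(c(quote_field(table$row_labels[i]),
            format_full_precision(table$values[i, ])), collapse = sep)
  }, character(1))

  con <- tryCatch(file(path, "wb"), error = function(e) {
    stop_heatcraft(sprintf("cannot open '%s' for writing: %s", path,
                           conditionMessage(e)), "heatcraft_io_error")
  })
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}
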
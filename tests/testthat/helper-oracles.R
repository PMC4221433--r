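# Independent oracles and small generators shared across the suite.

# Prim's algorithm on a full distance matrix; returns the sorted MST edge
# weights. Used as the independent reference for single-linkage heights.
prim_mst_weights <- function(d) {
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best <- d[1L, ]
  weights <- numeric(0)
  while (sum(in_tree) < n) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    weights <- c(weights, best[v])
    in_tree[v] <- TRUE
    best <- pmin(best, d[v, ])
  }
  sort(weights)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# random positive matrix with continuous (tie-free) entries
rand_pos_matrix <- function(n, p) {
  matrix(stats::runif(n * p, min = 0.5, max = 10), n, p)
}

# cophenetic distances implied by a stats::hclust fit, as a plain matrix
ref_cophenetic <- function(d, linkage) {
  method <- c(average = "average", minimum = "single", maximum = "complete")[[linkage]]
  as.matrix(stats::cophenetic(stats::hclust(stats::as.dist(d$d), method = method)))
}

# write a small xlsx via the system python/openpyxl (xlsx is a zip container,
# so the fixture has to be produced at test time rather than stored)
write_xlsx_fixture <- function(path, rows) {
  py <- Sys.which("python")
  if (py == "") return(FALSE)
  script <- tempfile(fileext = ".py")
  cells <- vapply(rows, function(r)
    paste0("[", paste(vapply(r, function(x)
      if (is.numeric(x)) format(x, digits = 15) else deparse(x), character(1)),
      collapse = ","), "]"), character(1))
  writeLines(c(
    "import openpyxl",
    "wb = openpyxl.Workbook()",
    "ws = wb.active",
    paste0("rows = [", paste(cells, collapse = ","), "]"),
    "for r in rows:",
    "    ws.append(r)",
    sprintf("wb.save(%s)", deparse(path))), script)
  status <- system2(py, script, stdout = FALSE, stderr = FALSE)
  identical(status, 0L)
}
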
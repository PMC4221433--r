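make_fig <- function(values, spec = heatmap_spec(), ...) {
  tb <- expression_table(values)
  nm <- normalize_linear(tb)
  compose_heatmap(tb, nm, build_lut(color_scale()), spec, ...)
}

test_that("cell centers carry exactly the LUT color of their value", {
  tb <- expression_table(matrix(c(1, 3, 2, 5), 2), c("a", "b"), c("s1", "s2"))
  nm <- normalize_linear(tb)
  lut <- build_lut(color_scale())
  fig <- compose_heatmap(tb, nm, lut, heatmap_spec())
  for (b in seq_len(nrow(fig$cell_boxes))) {
    box <- fig$cell_boxes[b, ]
    cx <- (box$x0 + box$x1 - 1L) %/% 2L
    cy <- (box$y0 + box$y1 - 1L) %/% 2L
    expect_equal(probe_pixel(fig, cx, cy),
                 as.integer(map_value(nm$values[box$row, box$col], lut)))
  }
})

test_that("cell boxes tile the grid without overlap and stay in the raster", {
  fig <- make_fig(matrix(stats::runif(12), 3, 4))
  boxes <- fig$cell_boxes
  expect_true(all(boxes$x1 <= dim(fig$raster)[2]))
  expect_true(all(boxes$y1 <= dim(fig$raster)[1]))
  area <- sum((boxes$x1 - boxes$x0) * (boxes$y1 - boxes$y0))
  expect_equal(area, fig$layout$grid_w * fig$layout$grid_h)
  expect_equal(anyDuplicated(boxes[, c("x0", "y0")]), 0L)
})

test_that("transposition swaps the cell grid", {
  m <- matrix(stats::runif(6, 1, 9), 2, 3)
  fig <- make_fig(m)
  fig_t <- make_fig(m, heatmap_spec(transpose = TRUE))
  for (i in 1:2) for (j in 1:3) {
    b <- fig$cell_boxes[fig$cell_boxes$row == i & fig$cell_boxes$col == j, ]
    bt <- fig_t$cell_boxes[fig_t$cell_boxes$row == j & fig_t$cell_boxes$col == i, ]
    expect_equal(
      probe_pixel(fig, (b$x0 + b$x1 - 1L) %/% 2L, (b$y0 + b$y1 - 1L) %/% 2L),
      probe_pixel(fig_t, (bt$x0 + bt$x1 - 1L) %/% 2L, (bt$y0 + bt$y1 - 1L) %/% 2L))
  }
})

test_that("rows follow the dendrogram leaf order when a tree is supplied", {
  m <- rbind(c(1, 1, 1), c(9, 9, 9), c(1.2, 1.1, 1), c(9.2, 9.1, 9))
  tb <- expression_table(m)
  nm <- normalize_linear(tb)
  lut <- build_lut(color_scale())
  tree <- hier_cluster(pairwise_dist(m, "euclidean"), "average")
  fig <- compose_heatmap(tb, nm, lut, heatmap_spec(), row_tree = tree)
  for (pos in seq_along(tree$order)) {
    orig <- tree$order[pos]
    b <- fig$cell_boxes[fig$cell_boxes$row == pos & fig$cell_boxes$col == 1, ]
    expect_equal(
      probe_pixel(fig, (b$x0 + b$x1 - 1L) %/% 2L, (b$y0 + b$y1 - 1L) %/% 2L),
      as.integer(map_value(nm$values[orig, 1], lut)))
  }
  # mismatched tree is rejected
  small <- hier_cluster(pairwise_dist(m[1:3, ], "euclidean"), "average")
  expect_error(compose_heatmap(tb, nm, lut, heatmap_spec(), row_tree = small),
               class = "heatcraft_validation_error")
})

test_that("canvas size equals the closed-form layout sum for all flag combos", {
  m <- matrix(stats::runif(20, 1, 5), 4, 5)
  tree_r <- hier_cluster(pairwise_dist(m, "euclidean"), "average")
  tree_c <- hier_cluster(pairwise_dist(m, "euclidean", axis = "cols"), "average")
  for (transpose in c(FALSE, TRUE)) {
    for (rd in c(FALSE, TRUE)) for (cd in c(FALSE, TRUE)) for (cb in c(FALSE, TRUE)) {
      spec <- heatmap_spec(transpose = transpose, show_row_dendrogram = rd,
                           show_col_dendrogram = cd, show_colorbar = cb,
                           x_title = "cond", y_title = "gene")
      fig <- make_fig(m, spec, row_tree = tree_r, col_tree = tree_c)
      lay <- fig$layout
      w <- 10 + lay$y_title_w + lay$row_dendro_w + lay$grid_w +
        lay$row_label_w + lay$colorbar_w + 10 + lay$pad_w
      h <- 10 + lay$col_dendro_h + lay$grid_h + lay$col_label_h +
        lay$x_title_h + 10 + lay$pad_h
      expect_equal(dim(fig$raster)[2], w)
      expect_equal(dim(fig$raster)[1], h)
      expect_equal(lay$row_dendro_w, if (rd) 60L else 0L)
      expect_equal(lay$col_dendro_h, if (cd) 60L else 0L)
      expect_equal(w %% 6, 0)
      expect_equal(h %% 6, 0)
    }
  }
})

test_that("label rotation settings are accepted and change the label gutter", {
  m <- matrix(1:6 + 0.0, 2, 3)
  f0 <- make_fig(m, heatmap_spec(rotate_labels = 0))
  f90 <- make_fig(m, heatmap_spec(rotate_labels = 90))
  expect_gt(f90$layout$col_label_h, f0$layout$col_label_h)
  expect_error(heatmap_spec(rotate_labels = 30), class = "heatcraft_validation_error")
})

test_that("exports scale linearly with dpi and record it in metadata", {
  fig <- make_fig(matrix(stats::runif(9, 1, 2), 3, 3))
  p300 <- withr::local_tempfile(fileext = ".png")
  p600 <- withr::local_tempfile(fileext = ".png")
  export_figure(fig, p300, "png", 300)
  export_figure(fig, p600, "png", 600)
  i300 <- png::readPNG(p300, info = TRUE)
  i600 <- png::readPNG(p600, info = TRUE)
  expect_equal(dim(i600)[1:2], 2L * dim(i300)[1:2])
  expect_equal(attr(i300, "info")$dpi, c(300, 300), tolerance = 1e-3)
  expect_equal(dim(i300)[2] / dim(fig$raster)[2], 300 / 72)

  t300 <- withr::local_tempfile(fileext = ".tiff")
  export_figure(fig, t300, "tiff", 300)
  ti <- tiff::readTIFF(t300, info = TRUE)
  expect_equal(dim(ti)[1:2], dim(i300)[1:2])
  expect_equal(attr(ti, "x.resolution"), 300)
  expect_equal(attr(ti, "resolution.unit"), "inch")
  # TIFF pixels equal the PNG pixels (both lossless)
  expect_equal(round(ti * 255), round(i300[, , 1:3] * 255), ignore_attr = TRUE)
})

test_that("PNG export is lossless and byte-deterministic", {
  fig <- make_fig(matrix(stats::runif(16, 1, 3), 4, 4))
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  export_figure(fig, p1, "png", 72)
  export_figure(fig, p2, "png", 72)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  back <- png::readPNG(p1)
  expect_identical(as.integer(round(back * 255)), as.integer(fig$raster))
})

test_that("unsupported export settings are rejected", {
  fig <- make_fig(matrix(c(1, 2, 3, 4), 2))
  expect_error(export_figure(fig, tempfile(), "jpg"),
               class = "heatcraft_validation_error")
  expect_error(export_figure(fig, tempfile(), "png", dpi = 0),
               class = "heatcraft_validation_error")
  expect_error(export_figure(fig, tempfile(), "png", dpi = 72.5),
               class = "heatcraft_validation_error")
})
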
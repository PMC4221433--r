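#' Heatmap layout settings
#'
#' All sizes are in base pixels (the figure's own coordinate system, 72 per
#' inch; export rescales). The canvas is the data grid plus margins, plus a
#' gutter for each requested dendrogram, the label areas and the color bar;
#' its final width and height are padded up to a multiple of 6 px so the
#' 72/300/600 dpi export presets scale pixel dimensions exactly.
#'
#' @param cell_w,cell_h Cell size in px (>= 1).
#' @param margins Four non-negative pads, `c(top, right, bottom, left)`.
#' @param transpose Swap the axes (values, labels, titles and trees).
#' @param rotate_labels Column-label angle: 0, 45 or 90 degrees (default 90,
#'   vertical, which keeps labels from colliding on narrow cells).
#' @param show_row_dendrogram,show_col_dendrogram Draw the tree in a gutter
#'   when the corresponding tree is supplied to [compose_heatmap()].
#' @param show_colorbar Draw the gradient bar with original-scale min/max.
#' @param x_title,y_title Axis titles (empty string = omitted).
#' @param dendro_depth Gutter depth in px reserved for each dendrogram.
#' @return A `heatmap_spec` object.
#' @export
heatmap_spec <- function(cell_w = 18L, cell_h = 18L,
                         margins = c(10L, 10L, 10L, 10L),
                         transpose = FALSE, rotate_labels = 90L,
                         show_row_dendrogram = TRUE,
                         show_col_dendrogram = TRUE,
                         show_colorbar = TRUE,
                         x_title = "", y_title = "",
                         dendro_depth = 60L) {
  if (cell_w < 1 || cell_h < 1) {
    stop_heatcraft("cell_w and cell_h must be >= 1 px", "heatcraft_validation_error")
  }
  if (length(margins) != 4L || any(margins < 0)) {
    stop_heatcraft("margins must be four non-negative pads (top,right,bottom,left)",
                   "heatcraft_validation_error")
  }
  if (!rotate_labels %in% c(0L, 45L, 90L)) {
    stop_heatcraft("rotate_labels must be 0, 45 or 90 degrees",
                   "heatcraft_validation_error")
  }
  structure(list(cell_w = as.integer(cell_w), cell_h = as.integer(cell_h),
                 margins = as.integer(margins), transpose = isTRUE(transpose),
                 rotate_labels = as.integer(rotate_labels),
                 show_row_dendrogram = isTRUE(show_row_dendrogram),
                 show_col_dendrogram = isTRUE(show_col_dendrogram),
                 show_colorbar = isTRUE(show_colorbar),
                 x_title = as.character(x_title), y_title = as.character(y_title),
                 dendro_depth = as.integer(dendro_depth)),
            class = "heatmap_spec")
}

format_tick <- function(x) formatC(signif(x, 4), format = "g")

colorbar_strip_w <- 12L

# Closed-form layout arithmetic, exposed so tests can verify the canvas size
# component by component.
heatmap_layout <- function(spec, n_rows, n_cols, row_labels, col_labels,
                           has_row_tree, has_col_tree, tick_texts) {
  grid_w <- n_cols * spec$cell_w
  grid_h <- n_rows * spec$cell_h
  row_dendro_w <- if (has_row_tree && spec$show_row_dendrogram) spec$dendro_depth else 0L
  col_dendro_h <- if (has_col_tree && spec$show_col_dendrogram) spec$dendro_depth else 0L
  y_title_w <- if (nzchar(spec$y_title)) glyph_h + 4L else 0L
  x_title_h <- if (nzchar(spec$x_title)) glyph_h + 4L else 0L
  row_label_w <- max(vapply(row_labels, function(s) text_extent(s, 0L)["w"],
                            numeric(1)), 0) + 4L
  col_label_h <- max(vapply(col_labels, function(s)
    text_extent(s, spec$rotate_labels)["h"], numeric(1)), 0) + 4L
  colorbar_w <- if (spec$show_colorbar) {
    colorbar_strip_w + 3L +
      max(vapply(tick_texts, function(s) text_extent(s, 0L)["w"], numeric(1))) + 4L
  } else 0L

  w_sum <- spec$margins[4L] + y_title_w + row_dendro_w + grid_w +
    row_label_w + colorbar_w + spec$margins[2L]
  h_sum <- spec$margins[1L] + col_dendro_h + grid_h + col_label_h +
    x_title_h + spec$margins[3L]
  pad_w <- (6L - w_sum %% 6L) %% 6L
  pad_h <- (6L - h_sum %% 6L) %% 6L

  list(grid_w = grid_w, grid_h = grid_h,
       row_dendro_w = row_dendro_w, col_dendro_h = col_dendro_h,
       y_title_w = y_title_w, x_title_h = x_title_h,
       row_label_w = as.integer(row_label_w), col_label_h = as.integer(col_label_h),
       colorbar_w = as.integer(colorbar_w),
       pad_w = pad_w, pad_h = pad_h,
       width = as.integer(w_sum + pad_w), height = as.integer(h_sum + pad_h),
       grid_x0 = as.integer(spec$margins[4L] + y_title_w + row_dendro_w),
       grid_y0 = as.integer(spec$margins[1L] + col_dendro_h))
}

# --- raster primitives (0-based pixel coordinates, origin top-left) --------

new_raster <- function(h, w, fill = 255L) {
  array(as.integer(fill), dim = c(h, w, 3L))
}

# half-open rectangle [x0,x1) x [y0,y1), clipped to the raster
fill_rect <- function(raster, x0, y0, x1, y1, rgb) {
  h <- dim(raster)[1L]; w <- dim(raster)[2L]
  xs <- max(x0, 0L):(min(x1, w) - 1L)
  ys <- max(y0, 0L):(min(y1, h) - 1L)
  if (x0 >= min(x1, w) || y0 >= min(y1, h)) return(raster)
  for (ch in 1:3) raster[ys + 1L, xs + 1L, ch] <- as.integer(rgb[ch])
  raster
}

draw_mask <- function(raster, mask, x, y, rgb = c(0L, 0L, 0L)) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(raster)
  px <- x + idx[, 2L] - 1L
  py <- y + idx[, 1L] - 1L
  h <- dim(raster)[1L]; w <- dim(raster)[2L]
  keep <- px >= 0L & px < w & py >= 0L & py < h
  px <- px[keep]; py <- py[keep]
  for (ch in 1:3) raster[cbind(py + 1L, px + 1L, ch)] <- as.integer(rgb[ch])
  raster
}

rot90ccw <- function(m) {
  n <- t(m)
  n[rev(seq_len(nrow(n))), , drop = FALSE]
}

rot45cw_mask <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(FALSE, 1L, 1L))
  c45 <- 1 / sqrt(2)
  r2 <- round((idx[, 1L] + idx[, 2L]) * c45)
  c2 <- round((idx[, 2L] - idx[, 1L]) * c45)
  r2 <- r2 - min(r2) + 1L
  c2 <- c2 - min(c2) + 1L
  out <- matrix(FALSE, max(r2), max(c2))
  out[cbind(r2, c2)] <- TRUE
  out
}

draw_text_px <- function(raster, text, x, y, angle = 0L, rgb = c(0L, 0L, 0L)) {
  if (!nzchar(text)) return(raster)
  mask <- text_mask(text)
  if (angle == 90L) mask <- rot90ccw(mask)
  if (angle == 45L) mask <- rot45cw_mask(mask)
  draw_mask(raster, mask, x, y, rgb)
}

# Dendrogram node coordinates along the leaf axis (px of subtree centers, in
# display order) and draw into a gutter. `side` is "left" (row tree) or
# "top" (column tree).
draw_dendrogram <- function(raster, tree, side, gutter0, gutter_depth,
                            axis0, cell_px) {
  n <- tree$n_leaves
  pos <- numeric(n - 1L)                     # axis position of each merge node
  hmax <- max(tree$height, .Machine$double.eps)
  leaf_axis <- numeric(n)
  leaf_axis[tree$order] <- axis0 + (seq_len(n) - 0.5) * cell_px

  node_axis <- function(node) if (node < 0L) leaf_axis[-node] else pos[node]
  node_h <- function(node) if (node < 0L) 0 else tree$height[node]

  # depth position: height 0 at the grid edge, max height at the gutter's far edge
  depth_px <- function(h) gutter0 + gutter_depth - 2L - (h / hmax) * (gutter_depth - 4L)

  black <- c(0L, 0L, 0L)
  for (m in seq_len(n - 1L)) {
    kids <- tree$merge[m, ]
    a1 <- node_axis(kids[1L]); a2 <- node_axis(kids[2L])
    pos[m] <- (a1 + a2) / 2
    dm <- depth_px(tree$height[m])
    d1 <- depth_px(node_h(kids[1L]))
    d2 <- depth_px(node_h(kids[2L]))
    if (side == "left") {
      # depth along x, axis along y
      raster <- fill_rect(raster, round(dm), round(min(a1, a2)),
                          round(dm) + 1L, round(max(a1, a2)) + 1L, black)
      raster <- fill_rect(raster, round(dm), round(a1), round(d1) + 1L, round(a1) + 1L, black)
      raster <- fill_rect(raster, round(dm), round(a2), round(d2) + 1L, round(a2) + 1L, black)
    } else {
      raster <- fill_rect(raster, round(min(a1, a2)), round(dm),
                          round(max(a1, a2)) + 1L, round(dm) + 1L, black)
      raster <- fill_rect(raster, round(a1), round(dm), round(a1) + 1L, round(d1) + 1L, black)
      raster <- fill_rect(raster, round(a2), round(dm), round(a2) + 1L, round(d2) + 1L, black)
    }
  }
  raster
}

#' Compose a heatmap raster
#'
#' Lays out and rasterizes the figure: the colored cell grid (rows/columns
#' permuted by the dendrogram leaf orders when trees are given), axis labels
#' and titles, dendrograms drawn in gutters with branch depth proportional to
#' merge height, and a color bar annotated with the original-scale minimum
#' and maximum (plus the log base in log mode). With `transpose = TRUE` the
#' matrix, labels, titles and trees are swapped before layout.
#'
#' @param table The [expression_table()] providing labels.
#' @param nm The matching [normalize_table()] result.
#' @param lut A [build_lut()] color table.
#' @param spec A [heatmap_spec()].
#' @param row_tree,col_tree Optional `heat_dendro` objects whose leaf counts
#'   match the corresponding axis.
#' @return A `rendered_figure`: list with the integer `raster`
#'   (height x width x 3, 0-255), `base_dpi` (72), per-cell pixel rectangles
#'   `cell_boxes` (half-open, 0-based, origin top-left) and the `layout`
#'   component sizes.
#' @export
compose_heatmap <- function(table, nm, lut, spec = heatmap_spec(),
                            row_tree = NULL, col_tree = NULL) {
  stopifnot(inherits(table, "expression_table"),
            inherits(nm, "normalized_matrix"),
            inherits(lut, "color_lut"), inherits(spec, "heatmap_spec"))
  if (!identical(dim(table$values), dim(nm$values))) {
    stop_heatcraft("normalized matrix shape does not match the table",
                   "heatcraft_validation_error")
  }

  values <- nm$values
  row_labels <- table$row_labels
  col_labels <- table$col_labels
  x_title <- spec$x_title; y_title <- spec$y_title

  if (spec$transpose) {
    values <- t(values)
    tmp <- row_labels; row_labels <- col_labels; col_labels <- tmp
    tmp <- x_title; x_title <- y_title; y_title <- tmp
    tmp <- row_tree; row_tree <- col_tree; col_tree <- tmp
  }
  eff_spec <- spec
  eff_spec$x_title <- x_title
  eff_spec$y_title <- y_title

  if (!is.null(row_tree)) {
    if (row_tree$n_leaves != nrow(values)) {
      stop_heatcraft("row tree leaf count does not match the row axis",
                     "heatcraft_validation_error")
    }
    values <- values[row_tree$order, , drop = FALSE]
    row_labels <- row_labels[row_tree$order]
  }
  if (!is.null(col_tree)) {
    if (col_tree$n_leaves != ncol(values)) {
      stop_heatcraft("column tree leaf count does not match the column axis",
                     "heatcraft_validation_error")
    }
    values <- values[, col_tree$order, drop = FALSE]
    col_labels <- col_labels[col_tree$order]
  }

  nr <- nrow(values); nc <- ncol(values)
  ticks <- c(format_tick(nm$ov_min), format_tick(nm$ov_max))
  if (nm$spec$mode == "log") {
    ticks <- c(ticks, paste0("log", format_tick(nm$spec$base)))
  }
  lay <- heatmap_layout(eff_spec, nr, nc, row_labels, col_labels,
                        !is.null(row_tree), !is.null(col_tree), ticks)

  raster <- new_raster(lay$height, lay$width)

  # cell grid
  colors <- map_value(values, lut)
  boxes <- data.frame(row = rep(seq_len(nr), nc), col = rep(seq_len(nc), each = nr))
  boxes$x0 <- lay$grid_x0 + (boxes$col - 1L) * spec$cell_w
  boxes$y0 <- lay$grid_y0 + (boxes$row - 1L) * spec$cell_h
  boxes$x1 <- boxes$x0 + spec$cell_w
  boxes$y1 <- boxes$y0 + spec$cell_h
  for (b in seq_len(nrow(boxes))) {
    raster <- fill_rect(raster, boxes$x0[b], boxes$y0[b], boxes$x1[b], boxes$y1[b],
                        colors[b, ])
  }

  # dendrograms
  if (!is.null(row_tree) && spec$show_row_dendrogram) {
    raster <- draw_dendrogram(raster, row_tree, "left",
                              lay$grid_x0 - lay$row_dendro_w, lay$row_dendro_w,
                              lay$grid_y0, spec$cell_h)
  }
  if (!is.null(col_tree) && spec$show_col_dendrogram) {
    raster <- draw_dendrogram(raster, col_tree, "top",
                              lay$grid_y0 - lay$col_dendro_h, lay$col_dendro_h,
                              lay$grid_x0, spec$cell_w)
  }

  # row labels, right of the grid, vertically centered per row
  lx <- lay$grid_x0 + lay$grid_w + 3L
  for (i in seq_len(nr)) {
    ly <- lay$grid_y0 + (i - 1L) * spec$cell_h +
      max((spec$cell_h - glyph_h) %/% 2L, 0L)
    raster <- draw_text_px(raster, row_labels[i], lx, ly, 0L)
  }

  # column labels under the grid
  for (j in seq_len(nc)) {
    cx <- lay$grid_x0 + (j - 1L) * spec$cell_w
    cy <- lay$grid_y0 + lay$grid_h + 3L
    ext <- text_extent(col_labels[j], spec$rotate_labels)
    if (spec$rotate_labels == 0L) {
      cx <- cx + (spec$cell_w - ext["w"]) %/% 2L
    } else {
      cx <- cx + max((spec$cell_w - ext["w"]) %/% 2L, 0L)
    }
    raster <- draw_text_px(raster, col_labels[j], cx, cy, spec$rotate_labels)
  }

  # titles
  if (nzchar(x_title)) {
    tw <- text_extent(x_title, 0L)["w"]
    raster <- draw_text_px(raster, x_title,
                           lay$grid_x0 + (lay$grid_w - tw) %/% 2L,
                           lay$grid_y0 + lay$grid_h + lay$col_label_h + 2L, 0L)
  }
  if (nzchar(y_title)) {
    th <- text_extent(y_title, 90L)["h"]
    raster <- draw_text_px(raster, y_title, eff_spec$margins[4L],
                           lay$grid_y0 + (lay$grid_h - th) %/% 2L, 90L)
  }

  # color bar: gradient strip spanning the grid height, max at top
  if (spec$show_colorbar) {
    cb_x0 <- lay$grid_x0 + lay$grid_w + lay$row_label_w
    strip_h <- max(lay$grid_h, 2L)
    for (py in 0:(strip_h - 1L)) {
      nv <- 1 - py / (strip_h - 1L)
      raster <- fill_rect(raster, cb_x0, lay$grid_y0 + py,
                          cb_x0 + colorbar_strip_w, lay$grid_y0 + py + 1L,
                          unclass(lut)[lut_index(nv, nrow(lut)), ])
    }
    tx <- cb_x0 + colorbar_strip_w + 3L
    raster <- draw_text_px(raster, ticks[2L], tx, lay$grid_y0, 0L)
    raster <- draw_text_px(raster, ticks[1L], tx,
                           lay$grid_y0 + lay$grid_h - glyph_h, 0L)
    if (length(ticks) == 3L) {
      raster <- draw_text_px(raster, ticks[3L], tx,
                             lay$grid_y0 + (lay$grid_h - glyph_h) %/% 2L, 0L)
    }
  }

  structure(list(raster = raster, base_dpi = 72L, cell_boxes = boxes,
                 layout = lay, transpose = spec$transpose),
            class = "rendered_figure")
}

#' @export
print.rendered_figure <- function(x, ...) {
  cat(sprintf("<rendered_figure> %d x %d px (base 72 dpi), %d cells\n",
              dim(x$raster)[2L], dim(x$raster)[1L], nrow(x$cell_boxes)))
  invisible(x)
}

#' Read one pixel of a rendered figure
#'
#' @param fig A [compose_heatmap()] result.
#' @param x,y 0-based pixel coordinates, origin top-left.
#' @return Integer RGB triple.
#' @export
probe_pixel <- function(fig, x, y) {
  stopifnot(inherits(fig, "rendered_figure"))
  as.integer(fig$raster[y + 1L, x + 1L, ])
}

#' Export resolution presets
#'
#' @return The three preset dpi values, 72, 300 and 600. Any other positive
#'   integer is also accepted by [export_figure()].
#' @export
dpi_presets <- function() c(72L, 300L, 600L)

#' Supported export formats
#'
#' @return `c("png", "tiff")`.
#' @export
figure_formats <- function() c("png", "tiff")

#' Export a rendered figure to PNG or TIFF
#'
#' The figure's physical size is fixed by its base-72-dpi pixel dimensions;
#' exporting at dpi `d` rescales the raster (nearest neighbor) to
#' `round(size * d / 72)` pixels, so pixel dimensions grow linearly with dpi
#' and the 300 and 600 dpi presets differ by exactly 2x. The dpi is recorded
#' in the file metadata (PNG pHYs chunk; TIFF resolution tags). PNG is
#' lossless; TIFF is written uncompressed. Neither format embeds timestamps,
#' so repeated exports are byte-identical.
#'
#' @param fig A [compose_heatmap()] result.
#' @param path Output path.
#' @param format `"png"` or `"tiff"`.
#' @param dpi Positive integer resolution; presets are 72, 300 and 600.
#' @return `path`, invisibly.
#' @export
export_figure <- function(fig, path, format = c("png", "tiff"), dpi = 300L) {
  stopifnot(inherits(fig, "rendered_figure"))
  if (length(format) == 1L && !format %in% figure_formats()) {
    stop_heatcraft(sprintf("unsupported format '%s'; use png or tiff", format),
                   "heatcraft_validation_error")
  }
  format <- match.arg(format)
  if (!is.numeric(dpi) || length(dpi) != 1L || dpi < 1 || dpi != trunc(dpi)) {
    stop_heatcraft("dpi must be a positive whole number", "heatcraft_validation_error")
  }
  dpi <- as.integer(dpi)

  h <- dim(fig$raster)[1L]; w <- dim(fig$raster)[2L]
  out_w <- as.integer(round(w * dpi / fig$base_dpi))
  out_h <- as.integer(round(h * dpi / fig$base_dpi))
  ix <- floor((seq_len(out_w) - 0.5) * w / out_w) + 1L
  iy <- floor((seq_len(out_h) - 0.5) * h / out_h) + 1L
  arr <- fig$raster[iy, ix, , drop = FALSE]

  ok <- tryCatch({
    if (format == "png") {
      png::writePNG(arr / 255, target = path, dpi = dpi)
    } else {
      write_tiff_baseline(arr, path, dpi)
    }
    TRUE
  }, error = function(e) {
    stop_heatcraft(sprintf("cannot write '%s': %s", path, conditionMessage(e)),
                   "heatcraft_io_error")
  })
  invisible(path)
}

# Minimal baseline TIFF writer: little-endian, one uncompressed RGB strip,
# with XResolution/YResolution/ResolutionUnit recorded. Hand-rolled because
# the installed TIFF bindings cannot store resolution metadata.
write_tiff_baseline <- function(arr, path, dpi) {
  h <- dim(arr)[1L]; w <- dim(arr)[2L]
  # interleave RGB per pixel, row-major
  px <- aperm(arr, c(3L, 2L, 1L))          # channel, col, row
  data <- as.raw(as.integer(px))
  n_data <- length(data)

  off_data <- 8L
  off_bits <- off_data + n_data            # 3 SHORTs (6 bytes)
  off_xres <- off_bits + 6L                # RATIONAL (8 bytes)
  off_yres <- off_xres + 8L
  off_ifd  <- off_yres + 8L

  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")

  writeBin(charToRaw("II"), con)
  w2(42L)
  w4(off_ifd)
  writeBin(data, con)
  w2(c(8L, 8L, 8L))                        # BitsPerSample values
  w4(c(dpi, 1L))                           # XResolution dpi/1
  w4(c(dpi, 1L))                           # YResolution

  entry <- function(tag, type, count, value, is_offset = FALSE) {
    w2(tag); w2(type); w4(count)
    if (type == 3L && !is_offset) {        # SHORT packed into 4-byte field
      w2(value); w2(0L)
    } else {
      w4(value)
    }
  }
  w2(12L)                                  # entry count
  entry(256L, 3L, 1L, w)                   # ImageWidth
  entry(257L, 3L, 1L, h)                   # ImageLength
  entry(258L, 3L, 3L, off_bits, is_offset = TRUE)  # BitsPerSample
  entry(259L, 3L, 1L, 1L)                  # Compression = none
  entry(262L, 3L, 1L, 2L)                  # Photometric = RGB
  entry(273L, 4L, 1L, off_data)            # StripOffsets
  entry(277L, 3L, 1L, 3L)                  # SamplesPerPixel
  entry(278L, 3L, 1L, h)                   # RowsPerStrip
  entry(279L, 4L, 1L, n_data)              # StripByteCounts
  entry(282L, 5L, 1L, off_xres)            # XResolution
  entry(283L, 5L, 1L, off_yres)            # YResolution
  entry(296L, 3L, 1L, 2L)                  # ResolutionUnit = inch
  w4(0L)                                   # no next IFD
  invisible(path)
}
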
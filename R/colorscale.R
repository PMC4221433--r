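#' Define a color scale from ordered anchor colors
#'
#' A scale is an ordered list of at least two RGB anchors; the default is the
#' microarray-convention tricolor green - black - red (low - mid - high).
#' Anchors may be given as hex strings (`"#00FF00"`) or as a matrix with one
#' RGB row per anchor (channels 0-255).
#'
#' @param anchors Character vector of hex colors, or an n x 3 numeric matrix.
#' @return A `color_scale` object holding an n x 3 integer anchor matrix.
#' @export
color_scale <- function(anchors = c("#00FF00", "#000000", "#FF0000")) {
  if (is.character(anchors)) {
    ok <- grepl("^#?[0-9a-fA-F]{6}$", anchors)
    if (!all(ok)) {
      stop_heatcraft(sprintf("not a hex RGB color: '%s'", anchors[!ok][1L]),
                     "heatcraft_validation_error")
    }
    hx <- sub("^#", "", anchors)
    anchors <- cbind(strtoi(substr(hx, 1, 2), 16L),
                     strtoi(substr(hx, 3, 4), 16L),
                     strtoi(substr(hx, 5, 6), 16L))
  }
  if (!is.matrix(anchors) || ncol(anchors) != 3L || nrow(anchors) < 2L) {
    stop_heatcraft("a color scale needs at least 2 RGB anchors",
                   "heatcraft_validation_error")
  }
  if (any(anchors < 0 | anchors > 255 | anchors != trunc(anchors))) {
    stop_heatcraft("anchor channels must be integers in 0..255",
                   "heatcraft_validation_error")
  }
  storage.mode(anchors) <- "integer"
  dimnames(anchors) <- list(NULL, c("r", "g", "b"))
  structure(list(anchors = anchors), class = "color_scale")
}

#' Discretize a color scale into the 768-row lookup table
#'
#' The gradient between consecutive anchors is sampled piecewise-linearly
#' into exactly 768 RGB rows (a 256-level color mode times three channels).
#' The 767 inter-row steps are split as evenly as possible among the anchor
#' segments, earlier segments taking any remainder; channel values are
#' rounded half-up. Row 1 equals the first anchor and row 768 the last.
#'
#' @param scale A [color_scale()].
#' @return A `color_lut`: a 768 x 3 integer matrix of class `color_lut`.
#' @examples
#' lut <- build_lut(color_scale())
#' dim(lut)
#' @export
build_lut <- function(scale = color_scale()) {
  stopifnot(inherits(scale, "color_scale"))
  a <- scale$anchors
  n_seg <- nrow(a) - 1L
  steps <- rep(767L %/% n_seg, n_seg)
  rem <- 767L %% n_seg
  if (rem > 0L) steps[seq_len(rem)] <- steps[seq_len(rem)] + 1L

  rows <- matrix(0L, 768L, 3L)
  rows[1L, ] <- a[1L, ]
  pos <- 1L
  for (s in seq_len(n_seg)) {
    for (t in seq_len(steps[s])) {
      frac <- t / steps[s]
      pos <- pos + 1L
      rows[pos, ] <- as.integer(round_half_up(a[s, ] + frac * (a[s + 1L, ] - a[s, ])))
    }
  }
  dimnames(rows) <- list(NULL, c("r", "g", "b"))
  structure(rows, class = c("color_lut", "matrix", "array"))
}

#' @export
print.color_lut <- function(x, ...) {
  cat(sprintf("<color_lut> %d rows; first %s, last %s\n", nrow(x),
              paste(x[1L, ], collapse = ","),
              paste(x[nrow(x), ], collapse = ",")))
  invisible(x)
}

#' Row index of the LUT nearest to a normalized value
#'
#' @param nv Numeric vector of normalized values in `[0,1]`.
#' @param n_rows Number of LUT rows (768 by default).
#' @return 1-based integer row indices, `round_half_up(nv * (n_rows - 1)) + 1`.
#' @export
lut_index <- function(nv, n_rows = 768L) {
  if (any(!is.finite(nv)) || any(nv < 0 | nv > 1)) {
    stop_heatcraft("normalized values must lie in [0,1]",
                   "heatcraft_domain_error")
  }
  as.integer(round_half_up(nv * (n_rows - 1L))) + 1L
}

#' Map normalized values to LUT colors
#'
#' Each value selects the nearest LUT row (half-way points round up).
#'
#' @param nv Numeric vector (or matrix) of values in `[0,1]`.
#' @param lut A [build_lut()] result.
#' @return An integer matrix with one RGB row per element of `nv`
#'   (in column-major order when `nv` is a matrix).
#' @export
map_value <- function(nv, lut) {
  stopifnot(inherits(lut, "color_lut"))
  idx <- lut_index(as.numeric(nv), nrow(lut))
  out <- unclass(lut)[idx, , drop = FALSE]
  dimnames(out) <- list(NULL, c("r", "g", "b"))
  out
}
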
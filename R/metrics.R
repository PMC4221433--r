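#' The seven supported distance metrics
#'
#' Four geometric metrics (Euclidean, squared Euclidean, Manhattan, maximum)
#' and three correlation distances defined as one minus the coefficient
#' (Pearson's r, Spearman's rho with average ranks for ties, Kendall's tau-b).
#' Correlation distances lie in `[0, 2]`.
#'
#' @return Character vector of the seven metric names; the default metric,
#'   `"pearson"`, is carried in attribute `"default"`.
#' @export
heat_metrics <- function() {
  structure(c("euclidean", "squared_euclidean", "manhattan", "maximum",
              "pearson", "spearman", "kendall"),
            default = "pearson")
}

#' Distance between two numeric vectors
#'
#' @param x,y Numeric vectors of equal length >= 2. The correlation metrics
#'   additionally require both vectors to be non-constant.
#' @param metric One of [heat_metrics()]; default `"pearson"`.
#' @return A single non-negative number.
#' @examples
#' vec_distance(c(0, 0), c(3, 4), "euclidean")   # 5
#' vec_distance(1:3, 3:1, "pearson")             # 2
#' @export
vec_distance <- function(x, y, metric = "pearson") {
  metric <- match.arg(metric, heat_metrics())
  if (length(x) != length(y)) {
    stop_heatcraft(sprintf("vector lengths differ (%d vs %d)",
                           length(x), length(y)),
                   "heatcraft_validation_error")
  }
  if (length(x) < 2L) {
    stop_heatcraft("vectors must have length >= 2", "heatcraft_validation_error")
  }
  if (metric %in% c("pearson", "spearman", "kendall")) {
    for (v in list(x, y)) {
      if (max(v) == min(v)) {
        stop_heatcraft(paste0(
          "correlation distance is undefined for a constant vector; ",
          "remove or jitter the flat row/column, or use a geometric metric"),
          "heatcraft_domain_error")
      }
    }
  }
  switch(metric,
    euclidean         = sqrt(sum((x - y)^2)),
    squared_euclidean = sum((x - y)^2),
    manhattan         = sum(abs(x - y)),
    maximum           = max(abs(x - y)),
    pearson           = 1 - pearson_r(x, y),
    spearman          = 1 - pearson_r(rank(x), rank(y)),
    kendall           = 1 - kendall_tau_b(x, y)
  )
}

# Product-moment correlation from its defining sums.
pearson_r <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# Tie-corrected Kendall tau-b by direct pair counting. n here is a heatmap
# axis length, so the O(n^2) loop is never the bottleneck.
kendall_tau_b <- function(x, y) {
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  s <- sum(dx[up] * dy[up])             # concordant minus discordant
  n0 <- sum(up)
  tx <- sum(dx[up] == 0)                # pairs tied in x
  ty <- sum(dy[up] == 0)
  s / sqrt((n0 - tx) * (n0 - ty))
}

#' Pairwise distance matrix over the rows or columns of a matrix
#'
#' @param mat Numeric matrix (an `expression_table` is also accepted).
#' @param metric One of [heat_metrics()].
#' @param axis `"rows"` (default) or `"cols"`: which margin provides the items.
#' @param labels Optional item labels; taken from the `expression_table`
#'   when one is supplied.
#' @return A `distance_matrix`: list with the symmetric zero-diagonal matrix
#'   `d`, the `metric` and `item_labels`.
#' @export
pairwise_dist <- function(mat, metric = "pearson", axis = c("rows", "cols"),
                          labels = NULL) {
  axis <- match.arg(axis)
  metric <- match.arg(metric, heat_metrics())
  if (inherits(mat, "expression_table")) {
    labels <- labels %||%
      (if (axis == "rows") mat$row_labels else mat$col_labels)
    mat <- mat$values
  }
  stopifnot(is.matrix(mat), is.numeric(mat))
  items <- if (axis == "rows") mat else t(mat)
  n <- nrow(items)
  if (n < 2L) {
    stop_heatcraft(sprintf("need >= 2 %s to compute pairwise distances", axis),
                   "heatcraft_validation_error")
  }
  labels <- labels %||% paste0(if (axis == "rows") "R" else "C", seq_len(n))

  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dij <- tryCatch(vec_distance(items[i, ], items[j, ], metric),
        error = function(e) {
          stop_heatcraft(sprintf("items %s and %s: %s",
                                 labels[i], labels[j], conditionMessage(e)),
                         "heatcraft_domain_error")
        })
      d[i, j] <- dij
      d[j, i] <- dij
    }
  }
  structure(list(d = d, metric = metric, item_labels = as.character(labels)),
            class = "distance_matrix")
}

#' Wrap a precomputed symmetric matrix as a distance_matrix
#'
#' @param d Symmetric numeric matrix with zero diagonal and non-negative
#'   entries.
#' @param metric Metric name to record (defaults to `"precomputed"`).
#' @param labels Optional item labels.
#' @return A `distance_matrix` object.
#' @export
as_distance_matrix <- function(d, metric = "precomputed", labels = NULL) {
  stopifnot(is.matrix(d), is.numeric(d))
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12) ||
      any(diag(d) != 0) || any(d < 0)) {
    stop_heatcraft("d must be symmetric and non-negative with a zero diagonal",
                   "heatcraft_validation_error")
  }
  labels <- labels %||% paste0("I", seq_len(nrow(d)))
  structure(list(d = d, metric = metric, item_labels = as.character(labels)),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d items, %s metric\n", nrow(x$d), x$metric))
  invisible(x)
}

#' @export
as.dist.distance_matrix <- function(m, diag = FALSE, upper = FALSE) {
  d <- m$d
  dimnames(d) <- list(m$item_labels, m$item_labels)
  stats::as.dist(d, diag = diag, upper = upper)
}
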
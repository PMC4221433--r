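#' Normalization settings
#'
#' @param mode `"linear"` (default) for plain global min-max rescaling, or
#'   `"log"` to rescale on a logarithmic axis.
#' @param base Logarithm base, used only in log mode. Default 2; the common
#'   alternatives 10 and e may be given as the numbers `10`, `exp(1)` or the
#'   shorthand strings `"2"`, `"10"`, `"e"`. Any positive base other than 1
#'   is accepted.
#' @return A `norm_spec` object with fields `mode` and `base`.
#' @export
norm_spec <- function(mode = c("linear", "log"), base = 2) {
  mode <- match.arg(mode)
  if (is.character(base)) {
    base <- switch(base, e = exp(1),
                   tryCatch(as.numeric(base), warning = function(w) NA_real_))
  }
  if (!is.numeric(base) || length(base) != 1L || !is.finite(base) ||
      base <= 0 || base == 1) {
    stop_heatcraft("log base must be a positive number other than 1",
                   "heatcraft_validation_error")
  }
  structure(list(mode = mode, base = base), class = "norm_spec")
}

#' Rescale an expression table to [0,1] by global linear min-max
#'
#' Every cell is mapped to `(OV - Min) / (Max - Min)` where `Min` and `Max`
#' are the global minimum and maximum over the whole matrix, so the smallest
#' cell maps to 0 and the largest to 1. A constant matrix (`Max == Min`) is
#' rejected.
#'
#' @param table An [expression_table()].
#' @return A `normalized_matrix`: list with `values` in `[0,1]`, the
#'   `norm_spec` used and the global `ov_min`, `ov_max`.
#' @examples
#' tb <- expression_table(matrix(c(1, 3, 2, 5), 2))
#' normalize_linear(tb)$values
#' @export
normalize_linear <- function(table) {
  stopifnot(inherits(table, "expression_table"))
  ov <- table$values
  mn <- min(ov); mx <- max(ov)
  if (mx == mn) {
    stop_heatcraft(
      "all values are equal: the maximum cannot equal the minimum",
      "heatcraft_validation_error")
  }
  new_normalized((ov - mn) / (mx - mn), norm_spec("linear"), mn, mx)
}

#' Rescale an expression table to [0,1] on a logarithmic axis
#'
#' Every cell is mapped to
#' `(log_a(OV) - log_a(Min)) / (log_a(Max) - log_a(Min))`. All values
#' (hence the global minimum) must be strictly positive, and the matrix must
#' not be constant. The result does not depend on the base `a`, which only
#' matters for how the color-bar axis is annotated.
#'
#' @param table An [expression_table()] with all values > 0.
#' @param spec A [norm_spec()]; its `base` is recorded alongside the result.
#' @return A `normalized_matrix`.
#' @export
normalize_log <- function(table, spec = norm_spec("log", 2)) {
  stopifnot(inherits(table, "expression_table"), inherits(spec, "norm_spec"))
  ov <- table$values
  if (any(ov <= 0)) {
    bad <- which(ov <= 0)[1L]
    r <- (bad - 1L) %% nrow(ov) + 1L
    c <- (bad - 1L) %/% nrow(ov) + 1L
    stop_heatcraft(sprintf(
      "log normalization requires all values > 0; cell (row %d, col %d) is %g",
      r, c, ov[r, c]), "heatcraft_domain_error")
  }
  mn <- min(ov); mx <- max(ov)
  if (mx == mn) {
    stop_heatcraft(
      "all values are equal: the maximum cannot equal the minimum",
      "heatcraft_validation_error")
  }
  lov <- log(ov, base = spec$base)
  nv <- (lov - log(mn, base = spec$base)) /
        (log(mx, base = spec$base) - log(mn, base = spec$base))
  # guard against round-off nudging the endpoints outside [0,1]
  nv[nv < 0] <- 0
  nv[nv > 1] <- 1
  new_normalized(nv, norm_spec("log", spec$base), mn, mx)
}

#' Normalize an expression table according to a norm_spec
#'
#' Dispatches to [normalize_linear()] or [normalize_log()].
#'
#' @inheritParams normalize_log
#' @return A `normalized_matrix`.
#' @export
normalize_table <- function(table, spec = norm_spec()) {
  stopifnot(inherits(spec, "norm_spec"))
  if (spec$mode == "linear") normalize_linear(table) else normalize_log(table, spec)
}

new_normalized <- function(values, spec, ov_min, ov_max) {
  structure(list(values = values, spec = spec,
                 ov_min = ov_min, ov_max = ov_max),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix> %d x %d, %s mode (min=%g, max=%g)\n",
              nrow(x$values), ncol(x$values), x$spec$mode, x$ov_min, x$ov_max))
  invisible(x)
}
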
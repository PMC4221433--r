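#' Generate a synthetic expression matrix with planted row clusters
#'
#' Emulates the shape of typical heatmap inputs (genes x conditions, or
#' compounds x targets): rows fall into `n_groups` groups, each group sharing
#' a distinct step-shaped mean profile across the columns, with i.i.d.
#' Gaussian noise on top. Group `g`'s profile is elevated by
#' `effect * noise_sd` over its own block of columns and 0 elsewhere, so the
#' profiles are orthogonal and the between-group separation is `effect` noise
#' standard deviations. With `positive_shift` the whole matrix is shifted so
#' its minimum is at least 0.1, making log normalization applicable. With
#' `ties` values are rounded to one decimal, injecting the duplicated values
#' that exercise average-rank Spearman and tie-corrected Kendall paths.
#' Output is fully determined by `seed`.
#'
#' @param n_rows,n_cols Matrix dimensions (default 60 x 6).
#' @param n_groups Number of planted row groups (default 3,
#'   `n_groups <= n_rows` and `n_groups <= n_cols` so every group gets at
#'   least one column of its own).
#' @param effect Group separation in units of `noise_sd` (default 8).
#' @param noise_sd Noise standard deviation (> 0, default 1).
#' @param positive_shift Force all values positive (default TRUE).
#' @param ties Round to one decimal to inject tied values (default FALSE).
#' @param seed Integer seed (required).
#' @return A `synth_data` list: `table` (an [expression_table()] with row
#'   labels `gene001...` and column labels `cond1...`) and `groups`
#'   (the planted group per row, integers `1..n_groups`).
#' @examples
#' sd1 <- generate_synth(n_rows = 12, n_cols = 6, n_groups = 3, seed = 1)
#' table(sd1$groups)
#' @export
generate_synth <- function(n_rows = 60L, n_cols = 6L, n_groups = 3L,
                           effect = 8, noise_sd = 1, positive_shift = TRUE,
                           ties = FALSE, seed) {
  if (missing(seed)) {
    stop_heatcraft("a seed is required", "heatcraft_validation_error")
  }
  if (n_groups > n_rows || n_groups > n_cols || n_groups < 1L ||
      n_rows < 1L || n_cols < 1L) {
    stop_heatcraft(
      "need n_groups <= n_rows and n_groups <= n_cols (all >= 1)",
      "heatcraft_validation_error")
  }
  if (effect < 0 || noise_sd <= 0) {
    stop_heatcraft("need effect >= 0 and noise_sd > 0",
                   "heatcraft_validation_error")
  }

  groups <- rep(seq_len(n_groups), length.out = n_rows)
  groups <- sort(groups)
  col_block <- rep(seq_len(n_groups), length.out = n_cols)
  col_block <- sort(col_block)
  profiles <- matrix(0, n_groups, n_cols)
  for (g in seq_len(n_groups)) {
    profiles[g, col_block == g] <- effect * noise_sd
  }

  values <- withr::with_seed(as.integer(seed), {
    profiles[groups, , drop = FALSE] +
      matrix(stats::rnorm(n_rows * n_cols, sd = noise_sd), n_rows, n_cols)
  })
  if (positive_shift) {
    mn <- min(values)
    if (mn < 0.1) values <- values + (0.1 - mn)
  }
  if (ties) values <- round(values, 1L)

  tb <- expression_table(values,
                         row_labels = sprintf("gene%03d", seq_len(n_rows)),
                         col_labels = sprintf("cond%d", seq_len(n_cols)))
  structure(list(table = tb, groups = groups, seed = as.integer(seed),
                 spec = list(n_rows = n_rows, n_cols = n_cols,
                             n_groups = n_groups, effect = effect,
                             noise_sd = noise_sd,
                             positive_shift = positive_shift, ties = ties)),
            class = "synth_data")
}

#' @export
print.synth_data <- function(x, ...) {
  cat(sprintf("<synth_data> %d x %d, %d planted groups, effect %g (seed %d)\n",
              x$spec$n_rows, x$spec$n_cols, x$spec$n_groups, x$spec$effect,
              x$seed))
  invisible(x)
}
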
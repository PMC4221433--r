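#' The three supported linkage criteria
#'
#' Inter-cluster distance during agglomeration: `average` (UPGMA, the
#' unweighted mean over all cross pairs; default), `minimum` (single linkage,
#' closest cross pair) and `maximum` (complete linkage, farthest cross pair).
#'
#' @return Character vector of the three linkage names, with the default,
#'   `"average"`, in attribute `"default"`.
#' @export
heat_linkages <- function() {
  structure(c("average", "minimum", "maximum"), default = "average")
}

#' Agglomerative hierarchical clustering
#'
#' Plain bottom-up agglomeration: starting from singletons, repeatedly merge
#' the pair of clusters with the smallest linkage distance, recomputed each
#' step directly from the original pairwise distances (no Lance-Williams
#' shortcut — transparent and easy to verify at heatmap scale). Ties are
#' broken deterministically in favor of the pair whose clusters contain the
#' lexicographically smallest original indices. The merge height is the
#' linkage distance at merge time; all three criteria are reducible, so
#' heights are non-decreasing.
#'
#' @param d A [pairwise_dist()] result.
#' @param linkage One of [heat_linkages()].
#' @return A `heat_dendro`: list with an `hclust`-convention `merge` matrix
#'   (negative entries are leaves, positive entries earlier merges), the
#'   merge `height`s, `labels`, `n_leaves` and the display `order` of leaves.
#' @export
hier_cluster <- function(d, linkage = "average") {
  stopifnot(inherits(d, "distance_matrix"))
  linkage <- match.arg(linkage, heat_linkages())
  dm <- d$d
  n <- nrow(dm)
  if (n < 2L) {
    stop_heatcraft("hierarchical clustering needs >= 2 items",
                   "heatcraft_validation_error")
  }

  members <- lapply(seq_len(n), identity)  # original indices per live cluster
  reps <- seq_len(n)                       # smallest original index per cluster
  node_id <- rep(-seq_len(n))              # hclust convention: -leaf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  link_fun <- switch(linkage,
    average = function(a, b) mean(dm[a, b]),
    minimum = function(a, b) min(dm[a, b]),
    maximum = function(a, b) max(dm[a, b]))

  # current linkage distances between live clusters, always recomputed from
  # the original pairwise distances (Inf marks self and dead clusters)
  L <- dm
  diag(L) <- Inf
  alive <- rep(TRUE, n)

  for (step in seq_len(n - 1L)) {
    h <- min(L)
    cand <- which(L == h, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    keys <- cbind(pmin(reps[cand[, 1L]], reps[cand[, 2L]]),
                  pmax(reps[cand[, 1L]], reps[cand[, 2L]]))
    pick <- order(keys[, 1L], keys[, 2L])[1L]
    a <- cand[pick, 1L]; b <- cand[pick, 2L]
    # put the child containing the smaller original index first
    if (reps[b] < reps[a]) { tmp <- a; a <- b; b <- tmp }

    merge[step, ] <- c(node_id[a], node_id[b])
    height[step] <- h
    members[[a]] <- c(members[[a]], members[[b]])
    reps[a] <- min(reps[a], reps[b])
    members[b] <- list(NULL)
    alive[b] <- FALSE
    L[b, ] <- Inf
    L[, b] <- Inf
    node_id[a] <- step
    for (c in which(alive)) {
      if (c == a) next
      lac <- link_fun(members[[a]], members[[c]])
      L[a, c] <- lac
      L[c, a] <- lac
    }
    L[a, a] <- Inf
  }

  tree <- structure(list(merge = merge, height = height,
                         labels = d$item_labels, n_leaves = n,
                         metric = d$metric, linkage = linkage),
                    class = "heat_dendro")
  tree$order <- leaf_order(tree)
  tree
}

#' Left-to-right leaf ordering of a dendrogram
#'
#' Depth-first traversal with the deterministic convention that, at every
#' merge, the child subtree containing the smaller minimum original leaf
#' index is placed on the left. This is the permutation applied to heatmap
#' rows/columns after clustering.
#'
#' @param tree A `heat_dendro`.
#' @return Integer permutation of `1..n_leaves`.
#' @export
leaf_order <- function(tree) {
  stopifnot(inherits(tree, "heat_dendro"))
  n <- tree$n_leaves
  if (nrow(tree$merge) != n - 1L) {
    stop_heatcraft("malformed tree: need exactly n_leaves - 1 merges",
                   "heatcraft_validation_error")
  }
  leaves_of <- function(node) {
    if (node < 0L) return(-node)
    kids <- tree$merge[node, ]
    left <- leaves_of(kids[1L])
    right <- leaves_of(kids[2L])
    if (min(right) < min(left)) c(right, left) else c(left, right)
  }
  ord <- leaves_of(n - 1L)
  if (!identical(sort(ord), seq_len(n))) {
    stop_heatcraft("malformed tree: leaves are not a permutation",
                   "heatcraft_validation_error")
  }
  ord
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last `k - 1` merges and labels the resulting components
#' `1..k` in order of their first appearance along the leaf order.
#'
#' @param tree A `heat_dendro`.
#' @param k Number of clusters, `1 <= k <= n_leaves`.
#' @return Integer vector of cluster labels, one per original item.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "heat_dendro"))
  n <- tree$n_leaves
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > n || k != trunc(k)) {
    stop_heatcraft(sprintf("k must be a whole number in 1..%d", n),
                   "heatcraft_validation_error")
  }
  k <- as.integer(k)
  comp <- -seq_len(n)                     # component id per leaf (node ids)
  keep <- seq_len(n - k)                  # merges that remain applied
  for (step in keep) {
    kids <- tree$merge[step, ]
    comp[comp %in% kids] <- step
  }
  # renumber components 1..k by first appearance in leaf order
  first_seen <- unique(comp[tree$order])
  match(comp, first_seen)
}

#' @export
print.heat_dendro <- function(x, ...) {
  cat(sprintf("<heat_dendro> %d leaves, %s linkage on %s distance\n",
              x$n_leaves, x$linkage, x$metric))
  invisible(x)
}

#' Convert to a stats::hclust object
#'
#' Allows plotting with [stats::plot.hclust()] and cross-checking against the
#' standard clustering utilities.
#'
#' @param x A `heat_dendro`.
#' @param ... Unused.
#' @return An object of class `hclust`.
#' @export
as.hclust.heat_dendro <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = x$linkage,
                 dist.method = x$metric, call = match.call()),
            class = "hclust")
}

#' Cophenetic distances implied by a dendrogram
#'
#' @param x A `heat_dendro`.
#' @return A `dist` object of merge heights at which each pair first joins.
#' @export
cophenetic.heat_dendro <- function(x) {
  stats::cophenetic(stats::as.hclust(x))
}

#' k-means clustering with a pluggable distance metric
#'
#' Seeded Lloyd-style iteration: `k` distinct rows are sampled as initial
#' centroids; points are assigned to the nearest centroid under `metric`
#' (ties to the lowest centroid index) and centroids are recomputed as the
#' arithmetic means of their members. An emptied cluster is repaired by
#' seizing the point farthest from its current centroid. Iteration stops when
#' assignments no longer change or after `max_iter` rounds. Convergence of
#' the cost is guaranteed only for `squared_euclidean` (for which the mean is
#' the cost-minimizing center); other metrics are bounded by `max_iter`.
#'
#' @param mat Numeric matrix (or `expression_table`), one item per row.
#' @param k Number of clusters, `1 <= k <= n`.
#' @param metric One of [heat_metrics()]; default `"squared_euclidean"`.
#' @param seed Integer seed controlling initialization (required, recorded).
#' @param max_iter Iteration cap (default 100).
#' @return A `heat_kmeans`: list with 1-based `labels`, `centroids`, total
#'   `cost` (sum of point-to-assigned-centroid distances under `metric`),
#'   `cost_history` (cost after each iteration), `n_iter` and `seed`.
#' @export
kmeans_metric <- function(mat, k, metric = "squared_euclidean", seed,
                          max_iter = 100L) {
  if (inherits(mat, "expression_table")) mat <- mat$values
  stopifnot(is.matrix(mat), is.numeric(mat))
  metric <- match.arg(metric, heat_metrics())
  n <- nrow(mat)
  if (!is.numeric(k) || k < 1 || k > n || k != trunc(k)) {
    stop_heatcraft(sprintf("k must be in 1..%d", n), "heatcraft_validation_error")
  }
  if (missing(seed)) {
    stop_heatcraft("a seed is required for reproducible k-means",
                   "heatcraft_validation_error")
  }
  k <- as.integer(k)

  centroid_dist <- function(point, centroid) {
    tryCatch(vec_distance(point, centroid, metric), error = function(e) {
      stop_heatcraft(paste0(
        "a centroid became constant, which is undefined under a correlation ",
        "metric; use a geometric metric such as euclidean"),
        "heatcraft_domain_error")
    })
  }

  centroids <- withr::with_seed(as.integer(seed),
                                mat[sample.int(n, k), , drop = FALSE])
  labels <- rep(1L, n)
  cost_history <- numeric(0)
  n_iter <- 0L

  for (iter in seq_len(max_iter)) {
    n_iter <- iter
    dmat <- matrix(0, n, k)
    for (i in seq_len(n)) {
      for (c in seq_len(k)) dmat[i, c] <- centroid_dist(mat[i, ], centroids[c, ])
    }
    new_labels <- apply(dmat, 1L, which.min)  # which.min ties to lowest index

    # repair empty clusters by seizing the globally farthest-from-centroid point
    for (c in which(tabulate(new_labels, k) == 0L)) {
      resid <- dmat[cbind(seq_len(n), new_labels)]
      resid[tabulate(new_labels, k)[new_labels] <= 1L] <- -Inf
      new_labels[which.max(resid)] <- c
    }

    for (c in seq_len(k)) {
      centroids[c, ] <- colMeans(mat[new_labels == c, , drop = FALSE])
    }
    cost <- sum(vapply(seq_len(n), function(i)
      centroid_dist(mat[i, ], centroids[new_labels[i], ]), numeric(1)))
    cost_history <- c(cost_history, cost)
    if (identical(new_labels, labels) && iter > 1L) break
    labels <- new_labels
  }

  structure(list(labels = labels, centroids = centroids,
                 cost = cost_history[length(cost_history)],
                 cost_history = cost_history, n_iter = n_iter,
                 seed = as.integer(seed), metric = metric, k = k),
            class = "heat_kmeans")
}

#' @export
print.heat_kmeans <- function(x, ...) {
  cat(sprintf("<heat_kmeans> k=%d, %s metric, cost %.4g after %d iterations (seed %d)\n",
              x$k, x$metric, x$cost, x$n_iter, x$seed))
  invisible(x)
}
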
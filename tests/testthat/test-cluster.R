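test_that("agglomeration of three collinear points matches the hand trace", {
  x <- c(0, 1, 10)
  d <- as_distance_matrix(abs(outer(x, x, "-")), "euclidean")
  expect_equal(hier_cluster(d, "minimum")$height, c(1, 9))
  expect_equal(hier_cluster(d, "maximum")$height, c(1, 10))
  expect_equal(hier_cluster(d, "average")$height, c(1, 9.5))
  tr <- hier_cluster(d, "average")
  expect_equal(leaf_order(tr), c(1L, 2L, 3L))
  expect_equal(cut_tree(tr, 2), c(1L, 1L, 2L))
})

test_that("two items force a single merge at their distance", {
  d <- as_distance_matrix(matrix(c(0, 3, 3, 0), 2))
  for (ln in heat_linkages()) {
    tr <- hier_cluster(d, ln)
    expect_equal(tr$height, 3)
    expect_equal(leaf_order(tr), c(1L, 2L))
  }
  expect_error(hier_cluster(as_distance_matrix(matrix(0, 1, 1))),
               class = "heatcraft_validation_error")
})

test_that("dendrograms agree with the reference agglomerator on random inputs", {
  withr::with_seed(19, {
    for (rep in 1:25) {
      n <- sample(4:8, 1)
      m <- rand_pos_matrix(n, 5)
      for (met in c("euclidean", "manhattan", "pearson")) {
        dd <- pairwise_dist(m, met)
        for (ln in heat_linkages()) {
          mine <- hier_cluster(dd, ln)
          expect_true(all(diff(mine$height) >= -1e-12))  # reducibility
          expect_equal(as.matrix(cophenetic(mine)), ref_cophenetic(dd, ln),
                       tolerance = 1e-9, ignore_attr = TRUE)
        }
      }
    }
  })
})

test_that("minimum-linkage merge heights equal the sorted MST edge weights", {
  withr::with_seed(23, {
    for (rep in 1:20) {
      n <- sample(4:9, 1)
      dd <- pairwise_dist(rand_pos_matrix(n, 4), "euclidean")
      tr <- hier_cluster(dd, "minimum")
      expect_equal(sort(tr$height), prim_mst_weights(dd$d), tolerance = 1e-12)
    }
  })
})

test_that("cut_tree covers the degenerate and planted cases", {
  d <- pairwise_dist(rbind(c(0, 0), c(0.2, 0), c(9, 9), c(9.1, 9)), "euclidean")
  tr <- hier_cluster(d, "average")
  expect_equal(cut_tree(tr, 1), rep(1L, 4))
  expect_equal(length(unique(cut_tree(tr, 4))), 4L)
  expect_equal(cut_tree(tr, 2), c(1L, 1L, 2L, 2L))
  expect_error(cut_tree(tr, 5), class = "heatcraft_validation_error")
  expect_error(cut_tree(tr, 0), class = "heatcraft_validation_error")
})

test_that("leaf order is a valid permutation consistent with the tree", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      n <- sample(3:10, 1)
      dd <- pairwise_dist(rand_pos_matrix(n, 3), "maximum")
      tr <- hier_cluster(dd, sample(heat_linkages(), 1))
      expect_setequal(leaf_order(tr), seq_len(n))
      # cutting at any k groups only contiguous runs of the leaf order
      for (k in 1:n) {
        labels <- cut_tree(tr, k)[tr$order]
        expect_equal(length(unique(labels)), k)
        expect_true(all(diff(match(labels, unique(labels))) >= 0))
      }
    }
  })
})

test_that("k-means recovers separated blobs and is deterministic under seed", {
  m <- rbind(c(0, 0), c(0.3, 0.1), c(8, 8), c(8.3, 8.2))
  km <- kmeans_metric(m, 2, "squared_euclidean", seed = 5)
  expect_equal(km$labels[1], km$labels[2])
  expect_equal(km$labels[3], km$labels[4])
  expect_true(km$labels[1] != km$labels[3])
  # cost equals the within-blob spread around the blob means (enumerated
  # optimum over all 2-partitions of 4 points confirms this is minimal)
  blob_cost <- function(rows) sum(scale(m[rows, ], scale = FALSE)^2)
  best <- Inf
  for (subset_size in 1:3) {
    for (pick in utils::combn(4, subset_size, simplify = FALSE)) {
      best <- min(best, blob_cost(pick) + blob_cost(setdiff(1:4, pick)))
    }
  }
  expect_equal(km$cost, best, tolerance = 1e-12)

  km2 <- kmeans_metric(m, 2, "squared_euclidean", seed = 5)
  expect_identical(km$labels, km2$labels)
  expect_identical(km$cost_history, km2$cost_history)
})

test_that("k-means respects its contracts at the edges", {
  m <- matrix(stats::rnorm(12, sd = 4), 4, 3)
  km <- kmeans_metric(m, 4, "squared_euclidean", seed = 1)
  expect_equal(km$cost, 0)
  expect_equal(sort(km$labels), 1:4)
  expect_error(kmeans_metric(m, 5, "squared_euclidean", seed = 1),
               class = "heatcraft_validation_error")
  expect_error(kmeans_metric(m, 2, "squared_euclidean"),
               class = "heatcraft_validation_error")
  # every returned cluster is non-empty
  withr::with_seed(9, {
    for (rep in 1:10) {
      mm <- matrix(stats::rnorm(40), 10, 4)
      kk <- kmeans_metric(mm, 3, sample(c("euclidean", "manhattan"), 1),
                          seed = rep)
      expect_equal(sort(unique(kk$labels)), 1:3)
    }
  })
})

test_that("k-means cost is non-increasing under squared Euclidean", {
  withr::with_seed(13, {
    for (rep in 1:10) {
      m <- matrix(stats::rnorm(60), 15, 4)
      km <- kmeans_metric(m, 3, "squared_euclidean", seed = rep)
      expect_true(all(diff(km$cost_history) <= 1e-9))
    }
  })
})

test_that("hierarchical clustering recovers planted row groups", {
  aris <- vapply(1:5, function(s) {
    sd <- generate_synth(n_rows = 30, n_cols = 6, n_groups = 3, effect = 10,
                         seed = s)
    dd <- pairwise_dist(sd$table, "pearson")
    ari(cut_tree(hier_cluster(dd, "average"), 3), sd$groups)
  }, numeric(1))
  expect_true(mean(aris) >= 0.9)
})

test_that("heat_dendro converts to a plottable hclust object", {
  dd <- pairwise_dist(rand_pos_matrix(5, 3), "euclidean")
  h <- stats::as.hclust(hier_cluster(dd, "average"))
  expect_s3_class(h, "hclust")
  expect_equal(length(h$height), 4L)
  expect_silent(stats::cutree(h, 2))
})
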
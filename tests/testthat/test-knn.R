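test_that("k-NN graph matches hand-enumerated edges on collinear points", {
  g <- build_knn_graph(matrix(c(0, 1, 3), ncol = 1), k = 1)
  expect_equal(g$edges$from, c(1L, 2L))
  expect_equal(g$edges$to, c(2L, 3L))
  expect_equal(g$edges$weight, c(1, 2))
})

test_that("k = N-1 yields the complete graph with Euclidean weights", {
  set.seed(11)
  X <- matrix(rnorm(14), 7, 2)
  g <- build_knn_graph(X, k = 6)
  expect_equal(nrow(g$edges), choose(7, 2))
  D <- as.matrix(dist(X))
  expect_equal(g$edges$weight, D[cbind(g$edges$from, g$edges$to)])
})

test_that("distance ties break toward the lower sample index", {
  # point 1 at 0; points 2 and 3 both at distance 1
  X <- matrix(c(0, 1, -1), ncol = 1)
  g <- build_knn_graph(X, k = 1)
  expect_equal(g$nbr[[1]], 2L)
})

test_that("exact duplicates get machine-epsilon edge weights", {
  X <- matrix(c(0, 0, 5), ncol = 1)
  g <- build_knn_graph(X, k = 1)
  w <- g$edges$weight[g$edges$from == 1 & g$edges$to == 2]
  expect_gt(w, 0)
  expect_equal(w, .Machine$double.eps)
})

test_that("union symmetrization keeps one-sided selections, mutual drops them", {
  # 0, 1, 3: node 3's nearest is 2 but 2's nearest is 1
  X <- matrix(c(0, 1, 3), ncol = 1)
  gu <- build_knn_graph(X, 1, symmetrize = "union")
  gm <- build_knn_graph(X, 1, symmetrize = "mutual")
  expect_true(any(gu$edges$from == 2 & gu$edges$to == 3))
  expect_false(any(gm$edges$from == 2 & gm$edges$to == 3))
})

test_that("every Swiss-roll node has degree >= k after union symmetrization", {
  sr <- make_swiss_roll(300, seed = 5)
  g <- build_knn_graph(sr$points, k = 12)
  deg <- tabulate(c(g$edges$from, g$edges$to), nbins = g$n)
  expect_true(all(deg >= 12))
})

test_that("k out of range is a parameter error", {
  X <- matrix(1:4, ncol = 1)
  expect_error(build_knn_graph(X, k = 4), "k must")
  expect_error(build_knn_graph(X, k = 0), "k must")
})

test_that("backend auto-selection follows the size policy and the override", {
  g_small <- rand_connected_graph(30)
  expect_equal(select_geodesic_backend(g_small), "floyd_warshall")
  expect_equal(select_geodesic_backend(g_small, threshold = 10), "dijkstra")
  expect_equal(select_geodesic_backend(g_small, force = "dijkstra"),
               "dijkstra")
})
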
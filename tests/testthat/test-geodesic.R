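test_that("path graph distances accumulate along the path", {
  X <- matrix(c(0, 1, 2), ncol = 1)
  g <- build_knn_graph(X, 1)
  d <- geodesic_floyd_warshall(g)
  expect_equal(d$values[1, 3], 2)
  expect_true(d$connected)
})

test_that("a heavy edge is bypassed through the two light edges", {
  # triangle with weights 1, 1, 10: direct heavy route loses
  g <- build_knn_graph(matrix(c(0, 0, 1, 0, 0.5, 5), ncol = 2,
                              byrow = TRUE), k = 2)
  g$edges$weight[g$edges$from == 1 & g$edges$to == 2] <- 10
  g$edges$weight[g$edges$from == 1 & g$edges$to == 3] <- 1
  g$edges$weight[g$edges$from == 2 & g$edges$to == 3] <- 1
  fw <- geodesic_floyd_warshall(g)
  dj <- geodesic_dijkstra(g)
  expect_equal(fw$values[1, 2], 2)
  expect_equal(dj$values[1, 2], 2)
})

test_that("star graph leaf-to-leaf distances are 2", {
  X <- rbind(c(0, 0), c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
  g <- build_knn_graph(X, 1)  # all leaves pick the hub
  d <- geodesic_dijkstra(g)
  leaves <- 2:5
  expect_true(all(abs(d$values[leaves, leaves][upper.tri(diag(4))] - 2)
                  < 1e-12))
})

test_that("both backends agree elementwise and with igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(42)
  for (i in 1:15) {
    g <- rand_connected_graph(sample(10:60, 1))
    fw <- geodesic_floyd_warshall(g)
    dj <- geodesic_dijkstra(g)
    expect_lt(max(abs(fw$values - dj$values)), 1e-9)
    ig <- igraph::graph_from_data_frame(
      data.frame(from = g$edges$from, to = g$edges$to),
      directed = FALSE, vertices = data.frame(name = seq_len(g$n)))
    ref <- igraph::distances(ig, weights = g$edges$weight)
    expect_lt(max(abs(fw$values - ref)), 1e-9)
  }
})

test_that("disconnected graphs report infinite cross-component entries", {
  X <- matrix(c(0, 1, 100, 101), ncol = 1)
  g <- build_knn_graph(X, 1)
  d <- geodesic_floyd_warshall(g)
  expect_false(d$connected)
  expect_true(is.infinite(d$values[1, 3]))
  expect_true(is.finite(d$values[1, 2]))
  dj <- geodesic_dijkstra(g)
  expect_equal(is.infinite(d$values), is.infinite(dj$values))
})

test_that("geodesic distances dominate Euclidean within a component", {
  set.seed(7)
  X <- cbind(runif(40), runif(40))
  g <- build_knn_graph(X, 4)
  comp <- nldrmri:::graph_components(g)
  d <- geodesic_distances(g)
  euc <- as.matrix(dist(X))
  same <- outer(comp, comp, "==")
  expect_true(all(d$values[same] >= euc[same] - 1e-9))
})
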
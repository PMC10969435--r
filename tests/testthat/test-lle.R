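test_that("a midpoint is reconstructed with equal weights", {
  X <- matrix(c(0, 1, 2), ncol = 1)  # point 2 is the midpoint of 1 and 3
  g <- build_knn_graph(X, 2)
  W <- lle_weights(X, g, regularization = 1e-9)
  expect_equal(as.numeric(W[2, c(1, 3)]), c(0.5, 0.5), tolerance = 1e-6)
})

test_that("a coincident neighbour absorbs the weight as reg -> 0", {
  # closed form for 2 neighbours: the zero-residual one gets weight ~ 1
  X <- rbind(c(0, 0), c(0, 0), c(10, 0))
  g <- list(n = 3, k = 2, nbr = list(c(2L, 3L), c(1L, 3L), c(1L, 2L)),
            mult = rep(1L, 3))
  W <- lle_weights(X, g, regularization = 1e-10)
  expect_gt(W[1, 2], 0.999)
  expect_lt(abs(W[1, 3]), 1e-3)
})

test_that("weight rows sum to one and vanish off-neighbourhood", {
  set.seed(6)
  X <- matrix(rnorm(80), 40, 2)
  g <- build_knn_graph(X, 6)
  W <- lle_weights(X, g)
  expect_true(all(abs(Matrix::rowSums(W) - 1) < 1e-12))
  for (i in c(1, 17, 40)) {
    expect_setequal(which(W[i, ] != 0), g$nbr[[i]])
  }
})

test_that("zero regularization on a singular local Gram is an error", {
  X <- rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 0))  # collinear: singular Gram
  g <- build_knn_graph(X, 3)
  expect_error(lle_weights(X, g, regularization = 0), "regularization")
})

test_that("collinear data embed in original order", {
  x <- seq(0, 1, length.out = 50)
  X <- cbind(x, 0 * x)
  emb <- lle(X, k = 2, d = 1)
  expect_equal(abs(cor(emb$values[, 1], x, method = "spearman")), 1)
})

test_that("the returned embedding beats random rotations on the LLE cost", {
  set.seed(13)
  sr <- make_swiss_roll(150, seed = 13)
  g <- build_knn_graph(sr$points, 8)
  W <- lle_weights(sr$points, g)
  emb <- lle_embed(W, d = 2)
  base_cost <- lle_cost(W, emb$values)
  for (i in 1:5) {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    Z <- matrix(rnorm(150 * 2), 150, 2)
    Z <- sqrt(150) * qr.Q(qr(scale(Z, scale = FALSE)))[, 1:2]
    expect_gte(lle_cost(W, Z %*% R), base_cost - 1e-8)
  }
})

test_that("excessive target dimension is a parameter error", {
  X <- matrix(rnorm(10), 5, 2)
  g <- build_knn_graph(X, 2)
  W <- lle_weights(X, g)
  expect_error(lle_embed(W, d = 4), "nonzero eigenvalues")
})

test_that("sparse and dense eigensolver paths agree", {
  set.seed(19)
  sr <- make_swiss_roll(250, seed = 19)
  g <- build_knn_graph(sr$points, 10)
  W <- lle_weights(sr$points, g)
  e_dense <- lle_embed(W, d = 2, dense_threshold = 500)
  e_sparse <- lle_embed(W, d = 2, dense_threshold = 10)
  expect_equal(e_dense$eigenvalues, e_sparse$eigenvalues, tolerance = 1e-6)
  for (j in 1:2) {
    expect_gt(abs(cor(e_dense$values[, j], e_sparse$values[, j])), 0.9999)
  }
})
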
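# Shared fixtures: everything is generated in code at test time.

# Small, fast phantom: 64^2 grid with a few well-sized lesions (radii are
# spec'd at 256^2 scale and shrink proportionally).
quick_spec <- function(seed = 1, ...) {
  phantom_spec(grid = 64, n_lesions = 4, lesion_radius = c(8, 12),
               seed = seed, ...)
}

# Random binary mask as a matrix.
rand_mask <- function(n = 16, p = 0.3) {
  matrix(rbinom(n * n, 1, p), n, n)
}

# Random connected k-NN graph over points in the plane; increases k until
# connected.
rand_connected_graph <- function(n, k = 3) {
  X <- cbind(runif(n), runif(n))
  repeat {
    g <- build_knn_graph(X, k)
    if (max(nldrmri:::graph_components(g)) == 1L) return(g)
    k <- k + 1
  }
}

# Independent set-form Dice (the printed set formula), used to cross-check
# the TP/FP/FN implementation.
dice_set_form <- function(A, B) {
  a <- as.vector(A) != 0
  b <- as.vector(B) != 0
  if (sum(a) + sum(b) == 0) return(1)
  2 * sum(a & b) / (sum(a) + sum(b))
}
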
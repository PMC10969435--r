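#' Locally linear embedding: reconstruction weights
#'
#' For each sample, solves the constrained least-squares problem of
#' reconstructing it from its k nearest neighbours,
#' `epsilon(W) = sum_i || x_i - sum_j w_ij x_ij ||^2`, subject to
#' `sum_j w_ij = 1` and `w_ij = 0` off-neighbourhood. The per-sample solve
#' works on the local Gram matrix `C = (x_i - N_i)(x_i - N_i)'`; because the
#' neighbourhood size typically exceeds the ambient dimension, `C` is
#' singular and a ridge term `regularization * tr(C) / k` is added to its
#' diagonal. Rows are renormalized after the solve, so they sum to 1
#' exactly.
#'
#' @param X numeric sample matrix (rows = samples).
#' @param g a `knn_graph` on the same samples; the *directed* neighbour
#'   lists are used, as in the original algorithm.
#' @param regularization ridge scale (default `1e-3`); with exactly 0 a
#'   singular local Gram raises an error advising a positive value.
#' @return An `lle_weights` object: sparse `dgCMatrix` `W` (rows sum to 1,
#'   support equals the directed neighbourhoods) with the regularization
#'   recorded as an attribute.
#' @export
lle_weights <- function(X, g, regularization = 1e-3) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n == g$n)
  if (any(lengths(g$nbr) == 0)) stop("every sample needs >= 1 neighbour")
  trip_i <- rep(seq_len(n), lengths(g$nbr))
  trip_j <- unlist(g$nbr, use.names = FALSE)
  trip_w <- numeric(length(trip_j))
  pos <- 0L
  for (i in seq_len(n)) {
    nb <- g$nbr[[i]]
    k_i <- length(nb)
    Z <- sweep(X[nb, , drop = FALSE], 2, X[i, ])
    C <- tcrossprod(Z)
    if (regularization > 0) {
      tr <- sum(diag(C))
      if (tr <= 0) tr <- 1  # all neighbours coincide with x_i
      diag(C) <- diag(C) + regularization * tr / k_i
    }
    w <- tryCatch(
      solve(C, rep(1, k_i)),
      error = function(e) {
        stop("singular local Gram matrix; use regularization > 0",
             call. = FALSE)
      }
    )
    w <- w / sum(w)
    trip_w[pos + seq_len(k_i)] <- w
    pos <- pos + k_i
  }
  W <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_w,
                            dims = c(n, n))
  structure(W, regularization = regularization, class = c(class(W)))
}

#' Locally linear embedding: spectral embedding step
#'
#' Minimizes the embedding cost `phi(Y) = sum_i || y_i - sum_j w_ij y_j ||^2`
#' under unit-covariance and zero-mean constraints. The minimizers are the
#' eigenvectors of `M = (I - W)'(I - W)` with the `d` smallest *nonzero*
#' eigenvalues; the constant eigenvector (eigenvalue 0) is discarded.
#' Columns are scaled by `sqrt(n)` so the embedding has unit covariance,
#' and the same deterministic sign convention as [classical_mds()] is
#' applied.
#'
#' A dense symmetric solver is used up to `dense_threshold` samples; above
#' that, shift-inverted block subspace iteration on the sparse Cholesky
#' factor of `M + sigma I` extracts only the bottom eigenpairs (fixed
#' deterministic starting block).
#'
#' @param W an `lle_weights` sparse matrix.
#' @param d target dimensionality.
#' @param dense_threshold switch point between solvers (default 2000).
#' @return An `nldr_embedding` with `method = "lle"`; `eigenvalues` holds
#'   the retained (smallest nonzero) eigenvalues, ascending.
#' @export
lle_embed <- function(W, d, dense_threshold = 2000) {
  n <- nrow(W)
  stopifnot(d >= 1)
  if (d >= n - 1) {
    stop("requested d exceeds the number of nonzero eigenvalues")
  }
  IW <- Matrix::Diagonal(n) - W
  M <- Matrix::crossprod(IW)
  # Row sums of (I - W) vanish, so the constant vector is an exact null
  # vector of M. It is removed by deflation rather than by dropping the
  # bottom eigenpair, because in degenerate geometries (data exactly
  # reproduced by its neighbours) the wanted coordinates also sit at
  # eigenvalue ~0 and eigen() would return an arbitrary rotation of that
  # null space mixing in the constant.
  if (n <= dense_threshold) {
    shift <- max(Matrix::diag(M)) + 1
    Md <- as.matrix(M) + shift / n  # + shift * 11'/n
    es <- eigen(Md, symmetric = TRUE)
    ord <- rev(seq_len(n))[seq_len(d)]
    vecs <- es$vectors[, ord, drop = FALSE]
    vals <- es$values[ord]
  } else {
    bs <- bottom_eigen_spsym(M, d + 3L, deflate_constant = TRUE)
    vecs <- bs$vectors[, seq_len(d), drop = FALSE]
    vals <- bs$values[seq_len(d)]
  }
  Y <- vecs * sqrt(n)
  Y <- fix_signs(Y)
  new_embedding(Y, d, eigenvalues = vals, method = "lle")
}

#' Locally linear embedding (full algorithm)
#'
#' Convenience composition of [build_knn_graph()], [lle_weights()] and
#' [lle_embed()]. As in [isomap()], a disconnected graph is reduced to its
#' largest connected component and the remaining samples are flagged.
#'
#' @inheritParams isomap
#' @param regularization passed to [lle_weights()].
#' @return An `nldr_embedding` with `method = "lle"`.
#' @export
lle <- function(X, k, d, regularization = 1e-3,
                symmetrize = c("union", "mutual")) {
  X <- as.matrix(X)
  g <- build_knn_graph(X, k, symmetrize = match.arg(symmetrize))
  lle_graph(X, g, d, regularization)
}

lle_graph <- function(X, g, d, regularization = 1e-3,
                      dense_threshold = 2000) {
  comp <- graph_components(g)
  if (max(comp) > 1L) {
    sizes <- tabulate(comp)
    keep <- which(comp == which.max(sizes))
    excluded <- setdiff(seq_len(g$n), keep)
    W <- lle_weights(X[keep, , drop = FALSE], subgraph(g, keep),
                     regularization)
    emb <- lle_embed(W, d, dense_threshold)
    values <- matrix(NA_real_, g$n, d)
    values[keep, ] <- emb$values
    return(new_embedding(values, d, eigenvalues = emb$eigenvalues,
                         method = "lle", excluded = excluded))
  }
  W <- lle_weights(X, g, regularization)
  lle_embed(W, d, dense_threshold)
}

#' Embedding cost of a configuration under fixed LLE weights
#'
#' `phi(Y) = sum_i || y_i - sum_j w_ij y_j ||^2`, the quantity
#' [lle_embed()] minimizes; exposed for optimality checks.
#'
#' @param W an `lle_weights` sparse matrix.
#' @param Y configuration matrix (n x d).
#' @return scalar cost.
#' @export
lle_cost <- function(W, Y) {
  R <- Y - as.matrix(W %*% Y)
  sum(R^2)
}

# Smallest eigenpairs of a sparse symmetric PSD matrix by shift-inverted
# block subspace iteration: factor M + sigma I once (sparse Cholesky),
# iterate solves on a fixed deterministic starting block, Rayleigh-Ritz at
# the end. Returns `p` ascending eigenpairs.
bottom_eigen_spsym <- function(M, p, tol = 1e-10, max_iter = 200L,
                               deflate_constant = FALSE) {
  n <- nrow(M)
  p <- min(p, n)
  sigma <- 1e-8 * max(Matrix::diag(M))
  ch <- Matrix::Cholesky(M + sigma * Matrix::Diagonal(n), LDL = FALSE)
  Q <- outer(seq_len(n), seq_len(p),
             function(i, j) sin(0.7 * i * j + j) + cos(0.3 * i + j^2))
  drop_const <- function(Q) Q - matrix(colMeans(Q), n, ncol(Q), byrow = TRUE)
  if (deflate_constant) Q <- drop_const(Q)
  Q <- qr.Q(qr(Q))
  prev <- rep(Inf, p)
  for (it in seq_len(max_iter)) {
    Z <- as.matrix(Matrix::solve(ch, Q))
    if (deflate_constant) Z <- drop_const(Z)
    Q <- qr.Q(qr(Z))
    if (it %% 5 == 0 || it == max_iter) {
      Tm <- crossprod(Q, as.matrix(M %*% Q))
      ev <- eigen((Tm + t(Tm)) / 2, symmetric = TRUE)
      cur <- rev(ev$values)
      scale_ref <- max(abs(cur), .Machine$double.eps)
      if (max(abs(cur - prev)) < tol * scale_ref) break
      prev <- cur
    }
  }
  Tm <- crossprod(Q, as.matrix(M %*% Q))
  ev <- eigen((Tm + t(Tm)) / 2, symmetric = TRUE)
  ord <- rev(seq_len(p))
  list(values = ev$values[ord], vectors = Q %*% ev$vectors[, ord, drop = FALSE])
}
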
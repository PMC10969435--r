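#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds a symmetric distance matrix into `d` dimensions by eigenvalue
#' decomposition of the double-centered squared-distance matrix
#' `B = -1/2 J D^2 J` (with `J = I - 11'/n` the centering matrix), the Gram
#' matrix of the configuration. The embedding is the top-`d` eigenvector
#' columns scaled by the square root of their eigenvalues; negative
#' eigenvalues (distances that are not exactly Euclidean, e.g. geodesics)
#' are truncated at zero. Inside Isomap the input is the geodesic distance
#' matrix, which minimizes the pairwise-distance stress over geodesics.
#'
#' Eigenvectors are sign-ambiguous, so a fixed convention is applied: each
#' embedding column is flipped, if needed, so its largest-magnitude entry is
#' positive. Below `dense_threshold` nodes a full dense symmetric solver is
#' used; above it, deterministic subspace iteration extracts only the
#' leading eigenpairs.
#'
#' @param D distance input: a `geodesic_dist`, or a symmetric numeric matrix
#'   with zero diagonal.
#' @param d target dimensionality (positive integer).
#' @param dense_threshold size at or below which the dense solver is used
#'   (default 2000).
#' @return An object of class `nldr_embedding`: list with `values` (n x d
#'   matrix), `d`, `eigenvalues` (the leading eigenvalues, descending),
#'   `method = "mds"`, and `excluded` (empty here; filled by [isomap()] for
#'   samples outside the embedded component).
#' @examples
#' pts <- cbind(runif(10), runif(10))
#' emb <- classical_mds(as.matrix(dist(pts)), d = 2)
#' max(abs(dist(emb$values) - dist(pts)))  # exact Euclidean recovery
#' @export
classical_mds <- function(D, d, dense_threshold = 2000) {
  if (inherits(D, "geodesic_dist")) D <- D$values
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(n == ncol(D), d >= 1)
  if (!all(is.finite(D))) {
    stop("distance matrix has infinite entries (disconnected graph); ",
         "restrict to the largest connected component first")
  }
  if (d > n - 1) stop("d must be at most n - 1")
  # B = -1/2 J D^2 J via row/column mean subtraction (no explicit J)
  D2 <- D^2
  rm_ <- rowMeans(D2)
  gm <- mean(D2)
  B <- -0.5 * (D2 - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm)
  B <- (B + t(B)) / 2
  if (n <= dense_threshold) {
    es <- eigen(B, symmetric = TRUE)
    lambda <- es$values[seq_len(d)]
    V <- es$vectors[, seq_len(d), drop = FALSE]
  } else {
    es <- top_eigen_sym(B, d)
    lambda <- es$values
    V <- es$vectors
  }
  Y <- V %*% diag(sqrt(pmax(lambda, 0)), d, d)
  Y <- fix_signs(Y)
  new_embedding(Y, d, eigenvalues = lambda, method = "mds")
}

new_embedding <- function(values, d, eigenvalues = NULL, method,
                          excluded = integer(0)) {
  structure(
    list(values = values, d = d, eigenvalues = eigenvalues,
         method = method, excluded = excluded),
    class = "nldr_embedding"
  )
}

#' @export
print.nldr_embedding <- function(x, ...) {
  cat(sprintf("<nldr_embedding> %s: %d samples -> %d dimension(s)",
              x$method, nrow(x$values), x$d))
  if (length(x$excluded)) {
    cat(sprintf(" (%d excluded)", length(x$excluded)))
  }
  cat("\n")
  invisible(x)
}

# Flip eigenvector columns so the largest-magnitude entry of each is
# positive (first such entry on exact ties). Removes eigenvector sign
# ambiguity for reproducibility.
fix_signs <- function(Y) {
  for (j in seq_len(ncol(Y))) {
    i <- which.max(abs(Y[, j]))
    if (length(i) && Y[i, j] < 0) Y[, j] <- -Y[, j]
  }
  Y
}

# Leading eigenpairs of a dense symmetric matrix by block subspace
# (orthogonal) iteration with Rayleigh-Ritz extraction. The starting block
# is a fixed quasi-random sinusoid basis, so results are deterministic
# without touching the RNG. Intended for the largest (most positive)
# eigenvalues of Gram matrices, whose spectra decay quickly.
top_eigen_sym <- function(B, d, extra = 4L, tol = 1e-10, max_iter = 300L) {
  n <- nrow(B)
  p <- min(n, d + extra)
  Q <- outer(seq_len(n), seq_len(p),
             function(i, j) sin(0.7 * i * j + j) + cos(0.3 * i + j^2))
  Q <- qr.Q(qr(Q))
  prev <- rep(Inf, d)
  for (it in seq_len(max_iter)) {
    Z <- B %*% Q
    Q <- qr.Q(qr(Z))
    if (it %% 5 == 0 || it == max_iter) {
      Tm <- crossprod(Q, B %*% Q)
      ev <- eigen((Tm + t(Tm)) / 2, symmetric = TRUE)
      cur <- ev$values[seq_len(d)]
      scale_ref <- max(abs(cur), .Machine$double.eps)
      if (max(abs(cur - prev)) < tol * scale_ref) break
      prev <- cur
    }
  }
  Tm <- crossprod(Q, B %*% Q)
  ev <- eigen((Tm + t(Tm)) / 2, symmetric = TRUE)
  list(values = ev$values[seq_len(d)],
       vectors = Q %*% ev$vectors[, seq_len(d), drop = FALSE])
}
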
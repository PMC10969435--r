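#' Build a k-nearest-neighbour graph
#'
#' Computes the directed k-nearest-neighbour relation under Euclidean
#' distance and symmetrizes it by union (an edge is kept if either endpoint
#' selects the other), the usual convention in Isomap implementations, so
#' that geodesic distances are symmetric. Ties in distance are broken by the
#' lower sample index. Exact duplicate points are allowed; the zero distance
#' between them is recorded as a machine-epsilon edge weight so that graph
#' algorithms treat them as (almost) coincident rather than disconnected.
#'
#' @param X numeric matrix, one row per sample, one column per feature.
#' @param k neighbourhood size, `1 <= k < nrow(X)`.
#' @param symmetrize `"union"` (default) keeps an edge when either endpoint
#'   selects it; `"mutual"` keeps it only when both do (may isolate nodes).
#' @return An object of class `knn_graph`: a list with `n`, `k`, `nbr` (the
#'   directed neighbour index lists, in increasing distance order), `edges`
#'   (a tibble of symmetrized undirected edges `from < to` with Euclidean
#'   `weight`), and `mult` (per-node multiplicities, all 1 here; codebook
#'   graphs carry voxel counts).
#' @examples
#' X <- matrix(c(0, 1, 3), ncol = 1)
#' g <- build_knn_graph(X, k = 1)
#' g$edges
#' @export
build_knn_graph <- function(X, k, symmetrize = c("union", "mutual")) {
  symmetrize <- match.arg(symmetrize)
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(is.numeric(X), n >= 2)
  if (!all(is.finite(X))) stop("X must be finite")
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < nrow(X)")
  D <- as.matrix(stats::dist(X))
  nbr <- vector("list", n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    # order() is stable, so equal distances resolve to the lower index
    nbr[[i]] <- order(d)[seq_len(k)]
  }
  new_knn_graph(nbr, D, n, k, symmetrize, mult = rep(1L, n))
}

# Assemble the graph object from directed neighbour lists and a distance
# lookup (full matrix or function of index pairs).
new_knn_graph <- function(nbr, D, n, k, symmetrize, mult) {
  from <- rep(seq_len(n), lengths(nbr))
  to <- unlist(nbr, use.names = FALSE)
  key_lo <- pmin(from, to)
  key_hi <- pmax(from, to)
  if (symmetrize == "union") {
    keep <- !duplicated(key_lo * (n + 1) + key_hi)
  } else {
    cnt <- table(key_lo * (n + 1) + key_hi)
    keep <- !duplicated(key_lo * (n + 1) + key_hi) &
      cnt[as.character(key_lo * (n + 1) + key_hi)] == 2L
  }
  lo <- key_lo[keep]
  hi <- key_hi[keep]
  w <- D[cbind(lo, hi)]
  w <- pmax(w, .Machine$double.eps)  # duplicates: epsilon, never zero
  structure(
    list(
      n = n, k = k,
      nbr = nbr,
      edges = tibble::tibble(from = lo, to = hi, weight = w),
      mult = mult,
      symmetrize = symmetrize
    ),
    class = "knn_graph"
  )
}

#' @export
print.knn_graph <- function(x, ...) {
  cat(sprintf(
    "<knn_graph> %d nodes, k = %d, %d undirected edges (%s symmetrization)\n",
    x$n, x$k, nrow(x$edges), x$symmetrize
  ))
  invisible(x)
}

# Compressed sparse row form of the symmetric arc set, 0-based, for the
# compiled shortest-path and component routines.
graph_csr <- function(g) {
  from <- c(g$edges$from, g$edges$to)
  to <- c(g$edges$to, g$edges$from)
  w <- c(g$edges$weight, g$edges$weight)
  o <- order(from, to)
  from <- from[o]; to <- to[o]; w <- w[o]
  indptr <- c(0L, cumsum(tabulate(from, nbins = g$n)))
  list(indptr = as.integer(indptr), indices = as.integer(to - 1L),
       weights = as.numeric(w))
}

# Connected component labels (1-based) of a knn_graph.
graph_components <- function(g) {
  csr <- graph_csr(g)
  cpp_components(csr$indptr, csr$indices, g$n)
}

#' Choose the geodesic backend for a graph
#'
#' Deterministic policy: Floyd-Warshall for small dense problems (its cubic
#' cost is negligible and it has no data-structure overhead), Dijkstra on the
#' sparse adjacency otherwise. The decision is made at run time from the
#' graph size, and can be overridden.
#'
#' @param g a `knn_graph`.
#' @param threshold node count at or below which Floyd-Warshall is used
#'   (default 500).
#' @param force `NULL` (default) to apply the policy, or
#'   `"floyd_warshall"` / `"dijkstra"` to override it.
#' @return `"floyd_warshall"` or `"dijkstra"`.
#' @export
select_geodesic_backend <- function(g, threshold = 500, force = NULL) {
  if (!is.null(force)) {
    return(match.arg(force, c("floyd_warshall", "dijkstra")))
  }
  if (g$n <= threshold) "floyd_warshall" else "dijkstra"
}
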
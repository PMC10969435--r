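#' Geodesic distances by the Floyd-Warshall recurrence
#'
#' All-pairs shortest-path distances over a symmetrized k-NN graph, computed
#' by dynamic programming over intermediate vertices:
#' `d_ij^(k) = min(d_ij^(k-1), d_ik^(k-1) + d_kj^(k-1))`, initialized at the
#' edge weights. Cubic in the number of nodes, so suited to small graphs;
#' [select_geodesic_backend()] switches to [geodesic_dijkstra()] above a
#' size threshold.
#'
#' Disconnection is reported, not raised: unreachable pairs are `Inf` and the
#' `connected` flag is `FALSE`.
#'
#' @param g a `knn_graph`.
#' @return An object of class `geodesic_dist`: list with `values` (symmetric
#'   matrix with zero diagonal, `Inf` between components), `connected`
#'   (logical), `backend`.
#' @export
geodesic_floyd_warshall <- function(g) {
  w <- matrix(Inf, g$n, g$n)
  diag(w) <- 0
  e <- g$edges
  w[cbind(e$from, e$to)] <- e$weight
  w[cbind(e$to, e$from)] <- e$weight
  d <- cpp_floyd_warshall(w)
  new_geodesic(d, "floyd_warshall")
}

#' Geodesic distances by repeated Dijkstra
#'
#' Runs textbook single-source Dijkstra (binary-heap priority queue, edge
#' relaxation `D_ik = min(D_ik, D_ij + w_jk)`) from every node of the
#' symmetrized k-NN graph. Near-linear per source on sparse graphs, so this
#' is the backend of choice for large node counts.
#'
#' @inheritParams geodesic_floyd_warshall
#' @return As [geodesic_floyd_warshall()].
#' @export
geodesic_dijkstra <- function(g) {
  csr <- graph_csr(g)
  d <- cpp_dijkstra_all(csr$indptr, csr$indices, csr$weights, g$n)
  new_geodesic(d, "dijkstra")
}

#' Geodesic distances with automatic backend selection
#'
#' @inheritParams geodesic_floyd_warshall
#' @param backend `"auto"` (default, policy of [select_geodesic_backend()]),
#'   `"floyd_warshall"`, or `"dijkstra"`.
#' @param threshold passed to [select_geodesic_backend()].
#' @return As [geodesic_floyd_warshall()].
#' @export
geodesic_distances <- function(g, backend = c("auto", "floyd_warshall",
                                              "dijkstra"),
                               threshold = 500) {
  backend <- match.arg(backend)
  force <- if (backend == "auto") NULL else backend
  chosen <- select_geodesic_backend(g, threshold = threshold, force = force)
  switch(chosen,
    floyd_warshall = geodesic_floyd_warshall(g),
    dijkstra = geodesic_dijkstra(g)
  )
}

new_geodesic <- function(d, backend) {
  d <- (d + t(d)) / 2  # enforce exact symmetry against fp drift
  diag(d) <- 0
  structure(
    list(values = d, connected = all(is.finite(d)), backend = backend),
    class = "geodesic_dist"
  )
}

#' @export
print.geodesic_dist <- function(x, ...) {
  cat(sprintf(
    "<geodesic_dist> %d x %d (%s backend), %s\n",
    nrow(x$values), ncol(x$values), x$backend,
    if (x$connected) "connected" else "disconnected"
  ))
  invisible(x)
}
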
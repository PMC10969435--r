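#' Isometric feature mapping (Isomap)
#'
#' Four-step composition: (1) build the k-nearest-neighbour graph, (2)
#' compute graph-geodesic distances between all samples with the selected
#' shortest-path backend, (3) apply classical MDS to the geodesic distance
#' matrix, (4) return the low-dimensional embedding. Geodesics along the
#' graph approximate on-manifold distances, which is what lets Isomap
#' unfold manifolds (e.g. the Swiss roll) that defeat plain MDS on
#' Euclidean distances.
#'
#' If the k-NN graph is disconnected, the largest connected component is
#' embedded and the remaining samples are flagged in `excluded` with `NA`
#' rows in the embedding (downstream image reconstruction assigns them the
#' background value).
#'
#' @inheritParams build_knn_graph
#' @param d target dimensionality.
#' @param backend,threshold passed to [geodesic_distances()].
#' @return An `nldr_embedding` (see [classical_mds()]) with
#'   `method = "isomap"`; `excluded` holds indices outside the embedded
#'   component, whose rows in `values` are `NA`.
#' @examples
#' sr <- make_swiss_roll(300, seed = 1)
#' emb <- isomap(sr$points, k = 8, d = 2)
#' @export
isomap <- function(X, k, d, backend = c("auto", "floyd_warshall", "dijkstra"),
                   threshold = 500, symmetrize = c("union", "mutual")) {
  backend <- match.arg(backend)
  X <- as.matrix(X)
  g <- build_knn_graph(X, k, symmetrize = match.arg(symmetrize))
  isomap_graph(g, d, backend = backend, threshold = threshold)
}

# Isomap steps 2-4 given a prebuilt graph (shared with the imaging
# pipeline, which builds a multiplicity-aware codebook graph).
isomap_graph <- function(g, d, backend = "auto", threshold = 500) {
  comp <- graph_components(g)
  keep <- seq_len(g$n)
  excluded <- integer(0)
  if (max(comp) > 1L) {
    sizes <- tabulate(comp)
    main <- which.max(sizes)
    keep <- which(comp == main)
    excluded <- which(comp != main)
    g <- subgraph(g, keep)
  }
  gd <- geodesic_distances(g, backend = backend, threshold = threshold)
  emb <- classical_mds(gd, d)
  if (length(excluded)) {
    values <- matrix(NA_real_, length(comp), d)
    values[keep, ] <- emb$values
    emb <- new_embedding(values, d, eigenvalues = emb$eigenvalues,
                         method = "isomap", excluded = excluded)
  } else {
    emb$method <- "isomap"
  }
  emb
}

# Node-induced subgraph, relabelling nodes to 1..length(keep).
subgraph <- function(g, keep) {
  idx <- match(seq_len(g$n), keep)
  e <- g$edges
  sel <- !is.na(idx[e$from]) & !is.na(idx[e$to])
  nbr <- lapply(g$nbr[keep], function(v) idx[v][!is.na(idx[v])])
  structure(
    list(
      n = length(keep), k = g$k,
      nbr = nbr,
      edges = tibble::tibble(
        from = idx[e$from[sel]], to = idx[e$to[sel]],
        weight = e$weight[sel]
      ),
      mult = g$mult[keep],
      symmetrize = g$symmetrize
    ),
    class = "knn_graph"
  )
}
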
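#' Embed a multiparametric volume into a single scalar image
#'
#' The core imaging pipeline: stack the four non-contrast channels into a
#' voxel feature matrix, embed it to one dimension with Isomap, LLE or
#' classical MDS, and map the coordinate back onto the grid (polarity
#' anchored to FLAIR so lesions render bright).
#'
#' Exact all-pairs geodesics over every voxel of a 256^2 slice are not
#' tractable (the dense distance matrix alone is tens of gigabytes), so
#' the feature matrix is first collapsed to a joint-intensity codebook:
#' z-scored channel vectors are quantized to a fixed step and duplicate
#' rows are merged, with multiplicities. Identical feature vectors must
#' receive identical embedding coordinates, so the collapse is exact at
#' quantization granularity. The k-NN rule on the codebook is
#' multiplicity-aware — a codeword links to its nearest distinct codewords
#' until at least `k` voxels are covered — which keeps `k` on the voxel
#' scale of the usual neighbourhood-size parameter. If the codebook graph
#' is disconnected, the default is to bridge components through their
#' closest codeword pair (in quantized intensity space whole tissue
#' classes can form separate components, and dropping them would discard
#' exactly the structure of interest); `connect = "largest"` instead keeps
#' the largest component and flags the rest, which then render as
#' background.
#'
#' @param vol an `mpmri_volume` (or `mp_phantom`).
#' @param method `"isomap"` (default), `"lle"`, or `"mds"` (linear
#'   reference).
#' @param k neighbourhood size in voxels (default 100).
#' @param channels embedding input channels (default PD, T2W, FLAIR,
#'   T1pre).
#' @param normalize passed to [stack_channels()].
#' @param quantize_step codebook quantization step in z-score units
#'   (default 0.25). If the codebook would exceed `max_codebook` codewords
#'   the step is coarsened by 25% steps until it fits (recorded in the
#'   provenance).
#' @param max_codebook codebook size cap (default 4000).
#' @param connect `"bridge"` (default) or `"largest"`; see Details.
#' @param backend,backend_threshold geodesic backend control, see
#'   [geodesic_distances()].
#' @param regularization LLE ridge scale (pipeline default 1e-2, stiffer
#'   than the in-memory [lle()] default because quantized codewords are
#'   noisier local patches than raw samples).
#' @param min_nbrs minimum number of distinct codewords each codeword
#'   links to, regardless of multiplicity coverage; stable local LLE fits
#'   need comfortably more neighbours than channels. Default `NULL` scales
#'   the floor with the neighbourhood size as `ceiling(k / 5)`, clamped to
#'   [2, 20], so small-k runs keep their (deliberately) fragile sparse
#'   graphs.
#' @return An `embedded_image` (grid matrix) with attributes `excluded`,
#'   `flipped`, and `provenance` (a list logging every runtime decision:
#'   quantization step, codebook size, backend chosen, components bridged,
#'   polarity flip).
#' @export
embed_volume <- function(vol, method = c("isomap", "lle", "mds"), k = 100,
                         channels = c("PD", "T2W", "FLAIR", "T1pre"),
                         normalize = "zscore", quantize_step = 0.25,
                         max_codebook = 4000,
                         connect = c("bridge", "largest"),
                         backend = "auto", backend_threshold = 500,
                         regularization = 1e-2, min_nbrs = NULL) {
  method <- match.arg(method)
  connect <- match.arg(connect)
  feats <- stack_channels(vol, channel_order = channels,
                          normalize = normalize)
  cb <- quantize_codebook(feats$X, quantize_step, max_codebook)
  if (k >= nrow(feats$X)) stop("k must be below the voxel count")
  g <- codebook_graph(cb$codebook, cb$mult, k, min_nbrs = min_nbrs)
  bridged <- 0L
  if (connect == "bridge") {
    b <- bridge_components(g, cb$codebook)
    g <- b$graph
    bridged <- b$added
  }
  emb <- switch(method,
    isomap = isomap_graph(g, d = 1, backend = backend,
                          threshold = backend_threshold),
    lle = lle_graph(cb$codebook, g, d = 1, regularization = regularization),
    mds = classical_mds(as.matrix(stats::dist(cb$codebook)), d = 1)
  )
  y <- emb$values[cb$assignment, 1]
  anchor <- if ("FLAIR" %in% colnames(feats$X)) feats$X[, "FLAIR"] else NULL
  img <- embedding_to_image(y, feats, anchor = anchor)
  attr(img, "provenance") <- list(
    method = method, k = k, channels = channels,
    quantize_step = cb$step, codebook_size = nrow(cb$codebook),
    backend = if (method == "isomap") {
      select_geodesic_backend(g, threshold = backend_threshold,
                              force = if (backend == "auto") NULL
                              else backend)
    } else NA_character_,
    components_bridged = bridged,
    excluded_codewords = length(emb$excluded),
    flipped = attr(img, "flipped")
  )
  img
}

# Quantize z-scored features to a joint-intensity codebook; coarsen the
# step geometrically until the codebook fits the cap. Rare codewords (the
# extreme noise tail) are then pruned down to the smallest set covering
# `coverage` of the voxels and their voxels remapped to the nearest kept
# codeword: isolated single-voxel codewords otherwise dangle off the
# neighbourhood graph and destabilize the spectral embeddings.
quantize_codebook <- function(X, step, max_codebook, coverage = 0.995) {
  repeat {
    Xq <- round(X / step) * step
    key <- do.call(paste, c(as.data.frame(Xq), list(sep = "\r")))
    first <- !duplicated(key)
    if (sum(first) <= max_codebook) break
    step <- step * 1.25
  }
  assignment <- match(key, key[first])
  codebook <- Xq[first, , drop = FALSE]
  mult <- tabulate(assignment, nbins = sum(first))
  if (coverage < 1 && nrow(codebook) > 2) {
    o <- order(mult, decreasing = TRUE)
    n_keep <- which(cumsum(mult[o]) >= coverage * nrow(X))[1]
    n_keep <- max(n_keep, 2L)
    if (n_keep < nrow(codebook)) {
      keep <- sort(o[seq_len(n_keep)])
      dropped <- setdiff(seq_len(nrow(codebook)), keep)
      # nearest kept codeword for each dropped one
      cross <- proxy_cross_dist(codebook[dropped, , drop = FALSE],
                                codebook[keep, , drop = FALSE])
      remap <- integer(nrow(codebook))
      remap[keep] <- seq_along(keep)
      remap[dropped] <- apply(cross, 1, which.min)
      assignment <- remap[assignment]
      codebook <- codebook[keep, , drop = FALSE]
      mult <- tabulate(assignment, nbins = length(keep))
    }
  }
  list(codebook = codebook, mult = mult, assignment = assignment,
       step = step)
}

# Euclidean cross-distance matrix between two point sets.
proxy_cross_dist <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

# Multiplicity-aware k-NN on codewords: each codeword links to its nearest
# distinct codewords until the linked voxel count reaches k (own
# duplicates excluded — counting them would disconnect every codeword
# whose multiplicity exceeds k), with a floor of `min_nbrs` distinct
# codewords. The floor matters for LLE: a stable local linear fit in D
# dimensions needs comfortably more than D neighbours, but a codeword in
# a dense region can cover k voxels with 2-3 neighbours. Union
# symmetrization as in build_knn_graph().
codebook_graph <- function(codebook, mult, k, min_nbrs = NULL) {
  n <- nrow(codebook)
  if (n < 2) stop("codebook has fewer than 2 codewords")
  D <- as.matrix(stats::dist(codebook))
  if (is.null(min_nbrs)) min_nbrs <- min(max(ceiling(k / 5), 2L), 20L)
  min_nbrs <- min(min_nbrs, n - 1L)
  nbr <- vector("list", n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    o <- order(d)
    cum <- cumsum(mult[o])
    m <- which(cum >= k)[1]
    if (is.na(m)) m <- n - 1L
    nbr[[i]] <- o[seq_len(max(m, min_nbrs))]
  }
  new_knn_graph(nbr, D, n, k, "union", mult = mult)
}

# Join disconnected components through their globally closest cross-
# component codeword pair, repeatedly, until connected.
bridge_components <- function(g, codebook) {
  added <- 0L
  repeat {
    comp <- graph_components(g)
    if (max(comp) == 1L) break
    D <- as.matrix(stats::dist(codebook))
    same <- outer(comp, comp, "==")
    D[same] <- Inf
    ij <- arrayInd(which.min(D), dim(D))
    i <- min(ij); j <- max(ij)
    g$edges <- dplyr::bind_rows(
      g$edges,
      tibble::tibble(from = i, to = j, weight = max(D[i, j],
                                                    .Machine$double.eps))
    )
    g$nbr[[i]] <- union(g$nbr[[i]], j)
    g$nbr[[j]] <- union(g$nbr[[j]], i)
    added <- added + 1L
  }
  list(graph = g, added = added)
}

#' Segment active lesions and form the ground-truth mask
#'
#' Runs [embed_volume()], thresholds the embedded image into the predicted
#' active-lesion mask (hierarchical Otsu by default, restricted to the
#' brain mask), and thresholds the contrast-subtraction image (plain Otsu)
#' into the ground-truth mask.
#'
#' @inheritParams embed_volume
#' @param threshold method for the embedded image (see [binarize()]).
#' @param gt_threshold method for the subtraction image.
#' @param ... further arguments to [embed_volume()].
#' @return list with `pred_mask`, `gt_mask` (both `lesion_mask`),
#'   `embedded` (the `embedded_image`), `subimage`.
#' @export
segment_active_lesions <- function(vol, method = "isomap", k = 100,
                                   threshold = "otsu2",
                                   gt_threshold = "otsu", ...) {
  emb <- embed_volume(vol, method = method, k = k, ...)
  pred <- binarize(emb, method = threshold, mask = vol$brain_mask)
  sub <- subtraction_image(vol)
  gt <- binarize(sub, method = gt_threshold)
  list(pred_mask = pred, gt_mask = gt, embedded = emb, subimage = sub)
}

#' Run the full pipeline on one volume and score it
#'
#' Convenience wrapper around [segment_active_lesions()] and [dice()]
#' returning one tidy result row.
#'
#' @inheritParams segment_active_lesions
#' @param resolution optional target side length; the volume is block-mean
#'   downsampled first (see [resample_volume()]).
#' @param subject optional subject identifier carried into the result.
#' @return A one-row tibble: `subject`, `method`, `k`, `resolution`,
#'   `dice`, `tp`, `fp`, `fn`, `threshold`.
#' @export
evaluate_volume <- function(vol, method = "isomap", k = 100,
                            resolution = NULL, threshold = "otsu2",
                            gt_threshold = "otsu", subject = NA_character_,
                            ...) {
  if (!is.null(resolution) && resolution != vol$grid[1]) {
    vol <- resample_volume(vol, resolution)
  }
  seg <- segment_active_lesions(vol, method = method, k = k,
                                threshold = threshold,
                                gt_threshold = gt_threshold, ...)
  res <- dice(seg$gt_mask, seg$pred_mask)
  tibble::tibble(
    subject = subject, method = method, k = k,
    resolution = vol$grid[1],
    dice = res$dice, tp = res$tp, fp = res$fp, fn = res$fn,
    threshold = attr(seg$pred_mask, "threshold")
  )
}

#' Evaluate every subject of a cohort
#'
#' @param cohort an `mp_cohort` (list of phantoms).
#' @inheritParams evaluate_volume
#' @return tibble with one row per subject (see [evaluate_volume()]).
#' @export
evaluate_cohort <- function(cohort, method = "isomap", k = 100,
                            resolution = NULL, ...) {
  purrr::list_rbind(purrr::imap(cohort, function(vol, i) {
    evaluate_volume(vol, method = method, k = k, resolution = resolution,
                    subject = sprintf("synthetic-%02d", i), ...)
  }))
}
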
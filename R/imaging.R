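#' Multiparametric MRI volume container
#'
#' Bundles co-registered scalar channels (2-D slice matrices by default, or
#' 3-D arrays) on a shared grid. Channels are named; the conventional set is
#' `PD`, `T2W`, `FLAIR`, `T1pre` and, when contrast was given, `T1post`
#' (used only to form the ground-truth subtraction image, never as an
#' embedding input).
#'
#' @param channels named list of numeric matrices/arrays with identical
#'   dimensions and finite values.
#' @param voxel_size numeric voxel edge lengths in mm (recycled to the grid
#'   dimensionality; default 1 mm).
#' @param brain_mask optional logical mask on the same grid restricting all
#'   downstream processing to intracranial voxels.
#' @return An `mpmri_volume` object.
#' @export
mpmri_volume <- function(channels, voxel_size = 1, brain_mask = NULL) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), !anyDuplicated(names(channels)))
  dims <- dim(as.array(channels[[1]]))
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!identical(dim(as.array(ch)), dims)) {
      stop("channel '", nm, "' is not on the shared grid")
    }
    if (!all(is.finite(ch))) stop("channel '", nm, "' has non-finite values")
  }
  if (!is.null(brain_mask)) {
    brain_mask <- array(as.logical(brain_mask), dims)
    if (!any(brain_mask)) stop("brain mask is empty")
  }
  structure(
    list(channels = channels, grid = dims,
         voxel_size = rep_len(voxel_size, length(dims)),
         brain_mask = brain_mask),
    class = "mpmri_volume"
  )
}

#' @export
print.mpmri_volume <- function(x, ...) {
  cat(sprintf("<mpmri_volume> %s, channels: %s%s\n",
              paste(x$grid, collapse = " x "),
              paste(names(x$channels), collapse = ", "),
              if (is.null(x$brain_mask)) "" else
                sprintf(" (mask: %d voxels)", sum(x$brain_mask))))
  invisible(x)
}

#' Stack channels into a voxel feature matrix
#'
#' Flattens the requested channels into one row per in-mask voxel and one
#' column per channel, the high-dimensional input to the manifold methods.
#' The post-contrast channel is a contract violation here: it defines the
#' ground truth and must not leak into the embedding input. Each channel is
#' normalized over the included voxels (default per-channel z-score, since
#' Euclidean k-NN is scale sensitive); a zero-variance channel yields a
#' zero column with a warning.
#'
#' @param vol an `mpmri_volume`.
#' @param channel_order channels to include, in column order (default the
#'   four non-contrast channels).
#' @param normalize `"zscore"` (default) or `"none"`.
#' @return A `voxel_features` object: list with `X` (matrix), `voxel_idx`
#'   (linear indices of the included voxels, the inverse map back onto the
#'   grid), `grid`, `channels`, `normalize`.
#' @export
stack_channels <- function(vol, channel_order = c("PD", "T2W", "FLAIR",
                                                  "T1pre"),
                           normalize = c("zscore", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(vol, "mpmri_volume"))
  if ("T1post" %in% channel_order) {
    stop("T1post is ground-truth only and cannot be an embedding input")
  }
  missing_ch <- setdiff(channel_order, names(vol$channels))
  if (length(missing_ch)) {
    stop("channel(s) not in volume: ", paste(missing_ch, collapse = ", "))
  }
  idx <- if (is.null(vol$brain_mask)) {
    seq_len(prod(vol$grid))
  } else {
    which(as.vector(vol$brain_mask))
  }
  X <- vapply(channel_order, function(nm) as.vector(vol$channels[[nm]])[idx],
              numeric(length(idx)))
  X <- matrix(X, nrow = length(idx),
              dimnames = list(NULL, channel_order))
  if (normalize == "zscore") {
    for (j in seq_len(ncol(X))) {
      s <- stats::sd(X[, j])
      if (s == 0) {
        warning("channel '", channel_order[j],
                "' has zero variance; z-score column set to 0")
        X[, j] <- 0
      } else {
        X[, j] <- (X[, j] - mean(X[, j])) / s
      }
    }
  }
  structure(
    list(X = X, voxel_idx = idx, grid = vol$grid,
         channels = channel_order, normalize = normalize),
    class = "voxel_features"
  )
}

#' Map a one-dimensional embedding back onto the image grid
#'
#' Places each included voxel's scalar embedding coordinate at its grid
#' position. Excluded voxels (outside the brain mask, or flagged because
#' they fell outside the embedded graph component) receive the image
#' minimum, i.e. background. Because eigenvector sign is arbitrary, the
#' polarity is anchored to the FLAIR channel when provided: lesions are
#' hyperintense on FLAIR, so the embedding is flipped unless the mean value
#' over high-FLAIR voxels (top decile) exceeds the mean over the rest —
#' lesions then render bright and a one-sided threshold is meaningful.
#'
#' @param embedding an `nldr_embedding` with `d = 1`, or a numeric vector,
#'   over the included voxels of `features`.
#' @param features the `voxel_features` the embedding was computed from.
#' @param anchor optional numeric vector (same length as rows of
#'   `features$X`) used for the polarity rule; conventionally the FLAIR
#'   column. `NULL` disables the flip.
#' @return An `embedded_image`: the grid matrix plus attributes `excluded`
#'   (linear indices), `flipped` (logical).
#' @export
embedding_to_image <- function(embedding, features, anchor = NULL) {
  y <- if (inherits(embedding, "nldr_embedding")) {
    stopifnot(embedding$d == 1)
    embedding$values[, 1]
  } else {
    as.numeric(embedding)
  }
  if (length(y) != nrow(features$X)) {
    stop("embedding length does not match included voxel count")
  }
  flipped <- FALSE
  ok <- is.finite(y)
  if (!is.null(anchor)) {
    stopifnot(length(anchor) == length(y))
    hi <- anchor >= stats::quantile(anchor[ok], 0.9)
    if (mean(y[hi & ok]) < mean(y[!hi & ok])) {
      y <- -y
      flipped <- TRUE
    }
  }
  lo <- min(y[ok])
  img <- array(lo, features$grid)
  img[features$voxel_idx[ok]] <- y[ok]
  excluded <- c(setdiff(seq_len(prod(features$grid)), features$voxel_idx),
                features$voxel_idx[!ok])
  structure(img, excluded = sort(excluded), flipped = flipped,
            class = c("embedded_image", class(img)))
}

#' Contrast-subtraction ground-truth image
#'
#' `T1post - T1pre`, clipped at zero: gadolinium enhancement is an
#' intensity increase, so negative differences are registration or noise
#' artifacts. Bright regions of this "subimage" define ground-truth active
#' lesions.
#'
#' @param vol an `mpmri_volume` containing both `T1pre` and `T1post`.
#' @return numeric matrix/array on the volume grid.
#' @export
subtraction_image <- function(vol) {
  stopifnot(inherits(vol, "mpmri_volume"))
  for (nm in c("T1pre", "T1post")) {
    if (!nm %in% names(vol$channels)) stop("missing channel: ", nm)
  }
  pmax(vol$channels$T1post - vol$channels$T1pre, 0)
}

#' Threshold an image into a binary lesion mask
#'
#' Pixels above the threshold are labelled 1 (lesion), the rest 0. Methods:
#' \describe{
#'   \item{`otsu`}{Otsu's criterion, maximizing between-class variance over
#'     all candidate cuts of the (optionally masked) intensity sample.
#'     Appropriate for clearly bimodal images such as the ground-truth
#'     subtraction image.}
#'   \item{`otsu2`}{hierarchical (recursive bright-tail) Otsu, the default
#'     for embedded images: Otsu cuts are applied repeatedly, keeping the
#'     bright side, until that side is a minority tail (at most
#'     `tail_frac` of the pixels — the lesional tissue, since lesion load
#'     is a few percent while the tissue bulk is ~90%), and one final cut
#'     within the tail isolates its brightest mode, the enhancing
#'     (active) extreme. A single global cut on an embedded image splits
#'     the dominant tissue contrast (CSF vs parenchyma) instead of the
#'     few-percent active-lesion class; the recursion peels those large
#'     modes off first. If the tail has no second mode (no enhancing
#'     pixels, e.g. constant tail) the mask is empty, with a warning.}
#'   \item{`percentile`}{threshold at the `p`-th percentile of the masked
#'     intensities.}
#'   \item{`absolute`}{fixed threshold `t`.}
#' }
#' A constant image under `otsu`/`otsu2` yields an empty mask with a
#' warning.
#'
#' @param img numeric image (matrix/array), e.g. an `embedded_image` or a
#'   subtraction image.
#' @param method thresholding rule, see Details.
#' @param p percentile in (0, 100) for `method = "percentile"`.
#' @param t cut value for `method = "absolute"`.
#' @param tail_frac bright-tail fraction at which the `otsu2` recursion
#'   stops (default 0.1).
#' @param mask optional logical image; threshold is estimated from (and the
#'   mask restricted to) these pixels.
#' @return A `lesion_mask`: integer 0/1 image with attributes `threshold`
#'   and `method` (provenance).
#' @export
binarize <- function(img, method = c("otsu", "otsu2", "percentile",
                                     "absolute"),
                     p = 99, t = NULL, mask = NULL, tail_frac = 0.1) {
  method <- match.arg(method)
  x <- as.vector(img)
  if (!all(is.finite(x))) stop("image must be finite")
  sel <- if (is.null(mask)) rep(TRUE, length(x)) else as.vector(mask)
  v <- x[sel]
  thr <- switch(method,
    otsu = otsu_threshold(v),
    otsu2 = otsu2_threshold(v, tail_frac),
    percentile = stats::quantile(v, p / 100, names = FALSE),
    absolute = {
      if (is.null(t)) stop("method = 'absolute' needs t")
      t
    }
  )
  if (is.na(thr)) {
    warning("constant image: Otsu threshold undefined, returning empty mask")
    m <- array(0L, dim(as.array(img)))
  } else {
    m <- array(as.integer(x > thr & sel), dim(as.array(img)))
  }
  structure(m, threshold = thr, method = method,
            class = c("lesion_mask", class(m)))
}

# Recursive bright-tail Otsu: peel off the dark majority until the bright
# side is a minority tail, then cut once more inside the tail to isolate
# its brightest (enhancing) mode. NA when no cut is defined.
otsu2_threshold <- function(v, tail_frac = 0.1) {
  n <- length(v)
  sub <- v
  repeat {
    t1 <- otsu_threshold(sub)
    if (is.na(t1)) return(NA_real_)
    bright <- sub[sub > t1]
    if (length(bright) <= tail_frac * n || length(bright) < 3) {
      return(otsu_threshold(bright))
    }
    sub <- bright
  }
}

# Otsu's threshold by exact search over all cuts of the sorted sample
# (embedded images are continuous-valued, so no histogram binning).
# Returns NA for a constant sample.
otsu_threshold <- function(v) {
  v <- sort(v)
  n <- length(v)
  if (n < 2 || v[1] == v[n]) return(NA_real_)
  i <- seq_len(n - 1)
  csum <- cumsum(v)
  mu0 <- csum[i] / i
  mu1 <- (csum[n] - csum[i]) / (n - i)
  w0 <- i / n
  between <- w0 * (1 - w0) * (mu0 - mu1)^2
  # only cuts between distinct values are valid thresholds
  valid <- v[i] < v[i + 1]
  between[!valid] <- -Inf
  best <- which.max(between)
  (v[best] + v[best + 1]) / 2
}

#' Block-mean downsampling
#'
#' Reduces a 2-D image to a coarser grid by averaging non-overlapping
#' blocks (anti-aliased by construction), emulating lower acquisition
#' resolution. Binary masks are downsampled by majority vote and
#' re-binarized. Upsampling is not supported.
#'
#' @param img numeric or 0/1 matrix.
#' @param target target side length (e.g. 128 for a 256 -> 128 reduction);
#'   must divide the source evenly.
#' @param as_mask treat the image as a binary mask (majority vote +
#'   re-binarization instead of block means); defaults to `TRUE` for
#'   `lesion_mask` objects.
#' @return matrix of dimension `target x target` (masks keep 0/1 values).
#' @export
resample_image <- function(img, target, as_mask = inherits(img,
                                                           "lesion_mask")) {
  dims <- dim(img)
  stopifnot(length(dims) == 2, dims[1] == dims[2])
  if (target > dims[1]) stop("upsampling is not supported")
  if (dims[1] %% target != 0) stop("target must divide the source size")
  f <- dims[1] %/% target
  m <- matrix(as.numeric(img), dims[1], dims[2])
  # average f x f blocks via two reshapes
  m <- .block_mean(m, f)
  if (as_mask) m <- (m > 0.5) + 0L
  m
}

.block_mean <- function(m, f) {
  n <- nrow(m) %/% f
  p <- ncol(m) %/% f
  # collapse rows then columns
  dim(m) <- c(f, n, ncol(m))
  m <- colMeans(m)
  m <- t(m)
  dim(m) <- c(f, p, n)
  t(colMeans(m))
}

#' Downsample a whole volume
#'
#' Applies [resample_image()] to every channel (block mean) and to the
#' brain and ground-truth masks (majority vote) of a 2-D volume or phantom.
#'
#' @param vol an `mpmri_volume` (or `mp_phantom`).
#' @param target target side length.
#' @return object of the same class on the coarser grid.
#' @export
resample_volume <- function(vol, target) {
  stopifnot(inherits(vol, "mpmri_volume") || inherits(vol, "mp_phantom"))
  out <- vol
  out$channels <- lapply(vol$channels, resample_image, target = target)
  if (!is.null(vol$brain_mask)) {
    bm <- resample_image((vol$brain_mask) + 0L, target, as_mask = TRUE)
    out$brain_mask <- bm > 0
  }
  for (nm in c("lesion_mask", "active_mask")) {
    if (!is.null(vol[[nm]])) {
      out[[nm]] <- resample_image(vol[[nm]], target, as_mask = TRUE)
    }
  }
  if (!is.null(vol$labels)) {
    out$labels <- .block_mode(vol$labels, nrow(vol$labels) %/% target)
  }
  out$grid <- rep(target, 2)
  out$voxel_size <- vol$voxel_size * nrow(vol$channels[[1]]) / target
  out
}

# majority (modal) label in each f x f block
.block_mode <- function(lab, f) {
  n <- nrow(lab) %/% f
  out <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      blk <- lab[((i - 1) * f + 1):(i * f), ((j - 1) * f + 1):(j * f)]
      tb <- tabulate(blk + 1L)
      out[i, j] <- which.max(tb) - 1L
    }
  }
  out
}
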
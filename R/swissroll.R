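#' Swiss-roll benchmark sample
#'
#' Draws `n` points on the standard Swiss roll: with roll parameter
#' `t ~ U(1.5*pi, 4.5*pi)` and height `h ~ U(0, 21)`, the ambient
#' coordinates are `(t cos t, h, t sin t)`, plus optional isotropic
#' Gaussian noise. The intrinsic (unrolled) coordinates are the spiral arc
#' length `s(t) = (t sqrt(1 + t^2) + asinh(t)) / 2` and the height, which
#' makes intrinsic pairwise distances available in closed form for judging
#' whether an embedding has unfolded the manifold.
#'
#' @param n number of points (>= 50).
#' @param noise_sd standard deviation of ambient Gaussian noise (default 0).
#' @param seed RNG seed; generation is a pure function of `(n, noise_sd,
#'   seed)`.
#' @return A `swiss_roll` object: list with `points` (n x 3), `intrinsic`
#'   (n x 2: arc length, height), `noise_sd`, `seed`.
#' @examples
#' sr <- make_swiss_roll(500, seed = 42)
#' @export
make_swiss_roll <- function(n, noise_sd = 0, seed = 1) {
  stopifnot(n >= 50, noise_sd >= 0)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  t <- runif(n, 1.5 * pi, 4.5 * pi)
  h <- runif(n, 0, 21)
  pts <- cbind(t * cos(t), h, t * sin(t))
  if (noise_sd > 0) pts <- pts + matrix(rnorm(3 * n, sd = noise_sd), n, 3)
  arc <- (t * sqrt(1 + t^2) + asinh(t)) / 2
  structure(
    list(points = pts, intrinsic = cbind(arc = arc, height = h),
         noise_sd = noise_sd, seed = seed),
    class = "swiss_roll"
  )
}

#' @export
print.swiss_roll <- function(x, ...) {
  cat(sprintf("<swiss_roll> %d points, noise sd %g, seed %d\n",
              nrow(x$points), x$noise_sd, x$seed))
  invisible(x)
}

#' Spearman correlation between embedded and intrinsic distances
#'
#' The unfolding score used on the Swiss-roll benchmark: rank correlation
#' between all pairwise distances in the embedding and the corresponding
#' intrinsic (unrolled-plane) distances. Near 1 means the embedding
#' recovered the manifold's geometry; plain MDS on ambient Euclidean
#' distances scores visibly lower than Isomap or LLE.
#'
#' @param embedding an `nldr_embedding` or a coordinate matrix.
#' @param roll the `swiss_roll` the embedding was computed from.
#' @return scalar Spearman correlation.
#' @export
intrinsic_distance_correlation <- function(embedding, roll) {
  Y <- if (inherits(embedding, "nldr_embedding")) embedding$values
       else as.matrix(embedding)
  stopifnot(nrow(Y) == nrow(roll$intrinsic))
  d_emb <- as.vector(stats::dist(Y))
  d_int <- as.vector(stats::dist(roll$intrinsic))
  stats::cor(d_emb, d_int, method = "spearman")
}

# Seed handling: run generators under a caller-given seed without
# disturbing the session RNG stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
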
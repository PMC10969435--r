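#' Tidy an embedding into one row per sample
#'
#' @param x an `nldr_embedding`.
#' @param ... unused.
#' @return tibble with `sample`, one `dim<i>` column per embedding
#'   dimension, and `excluded` (logical).
#' @export
tidy.nldr_embedding <- function(x, ...) {
  n <- nrow(x$values)
  out <- tibble::as_tibble(as.data.frame(x$values),
                           .name_repair = ~ paste0("dim", seq_along(.x)))
  dplyr::bind_cols(tibble::tibble(sample = seq_len(n)), out) |>
    dplyr::mutate(excluded = .data$sample %in% x$excluded)
}

#' One-row summary of an embedding
#'
#' @param x an `nldr_embedding`.
#' @param ... unused.
#' @return tibble with `method`, `n`, `d`, `n_excluded`, and
#'   `leading_eigenvalue` when available.
#' @export
glance.nldr_embedding <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n = nrow(x$values),
    d = x$d,
    n_excluded = length(x$excluded),
    leading_eigenvalue = if (is.null(x$eigenvalues)) NA_real_
                         else x$eigenvalues[1]
  )
}

#' Plot an embedding
#'
#' Scatter of the first two embedding dimensions (or index vs value for
#' 1-D embeddings).
#'
#' @param object an `nldr_embedding`.
#' @param colour optional vector mapped to point colour (e.g. an intrinsic
#'   coordinate or tissue label).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.nldr_embedding <- function(object, colour = NULL, ...) {
  df <- tidy(object)
  if (!is.null(colour)) df$.colour <- colour
  aes <- if (object$d >= 2) {
    ggplot2::aes(x = .data$dim1, y = .data$dim2)
  } else {
    ggplot2::aes(x = .data$sample, y = .data$dim1)
  }
  p <- ggplot2::ggplot(df, aes)
  if (!is.null(colour)) {
    p <- p + ggplot2::aes(colour = .data$.colour) +
      ggplot2::labs(colour = NULL)
  }
  p + ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::labs(x = if (object$d >= 2) "dimension 1" else "sample",
                  y = if (object$d >= 2) "dimension 2" else "embedding",
                  title = sprintf("%s embedding", object$method)) +
    ggplot2::theme_minimal()
}

#' Plot a phantom's channels
#'
#' Faceted raster view of every channel of a volume, with the active-lesion
#' outline implicit in the T1post channel.
#'
#' @param object an `mp_phantom` (or `mpmri_volume`).
#' @param channels channels to show (default all).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mpmri_volume <- function(object,
                                  channels = names(object$channels), ...) {
  df <- purrr::list_rbind(lapply(channels, function(nm) {
    m <- object$channels[[nm]]
    tibble::tibble(
      channel = nm,
      row = rep(seq_len(nrow(m)), times = ncol(m)),
      col = rep(seq_len(ncol(m)), each = nrow(m)),
      intensity = as.vector(m)
    )
  }))
  df$channel <- factor(df$channel, levels = channels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
}

#' @export
autoplot.mp_phantom <- autoplot.mpmri_volume

#' Plot a sensitivity sweep
#'
#' Dice score against the swept parameter (neighbourhood size or working
#' resolution).
#'
#' @param object a `sweep_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sweep_report <- function(object, ...) {
  swept <- attr(object, "swept")
  xvar <- if (identical(swept, "k")) "k" else "resolution"
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data[[xvar]], y = .data$dice)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = if (xvar == "k") "neighbourhood size K"
                  else "resolution (side length)",
                  y = "Dice similarity") +
    ggplot2::theme_minimal()
}

#' Box plot of cohort Dice scores by method
#'
#' Mirrors the usual cohort-performance figure: one box per method over
#' per-subject Dice scores.
#'
#' @param results tibble with `method` and `dice` columns (e.g. stacked
#'   [evaluate_cohort()] outputs).
#' @return a ggplot object.
#' @export
plot_cohort_dice <- function(results) {
  ggplot2::ggplot(results, ggplot2::aes(x = .data$method, y = .data$dice)) +
    ggplot2::geom_boxplot(width = 0.4, outlier.size = 0.8) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "Dice similarity") +
    ggplot2::theme_minimal()
}
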
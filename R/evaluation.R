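#' Dice similarity between two binary masks
#'
#' `DS = 2|A intersect B| / (|A| + |B|)`, equivalently
#' `2 TP / (2 TP + FN + FP)` with A as ground truth and B as prediction:
#' 0 when the masks are disjoint, 1 when they coincide. When both masks
#' are empty the score is defined as 1 (perfect agreement on absence)
#' with a warning, avoiding 0/0.
#'
#' @param A ground-truth 0/1 mask (matrix/array).
#' @param B predicted 0/1 mask on the same grid.
#' @return A one-row tibble: `dice`, `tp`, `fp`, `fn`.
#' @examples
#' A <- matrix(c(1, 1, 0, 0), 2)
#' B <- matrix(c(1, 0, 1, 0), 2)
#' dice(A, B)  # 2*1 / (2*1 + 1 + 1) = 0.5
#' @export
dice <- function(A, B) {
  a <- as.vector(A) != 0
  b <- as.vector(B) != 0
  if (!identical(dim(as.array(A)), dim(as.array(B)))) {
    stop("masks are not on the same grid")
  }
  tp <- sum(a & b)
  fp <- sum(!a & b)
  fn <- sum(a & !b)
  ds <- if (tp + fp + fn == 0) {
    warning("both masks empty; Dice defined as 1")
    1
  } else {
    2 * tp / (2 * tp + fn + fp)
  }
  tibble::tibble(dice = ds, tp = tp, fp = fp, fn = fn)
}

#' Cohort summary statistics
#'
#' Median and sample (n-1) standard deviation of the per-subject Dice
#' scores, the cohort-level figures of merit.
#'
#' @param results tibble with a `dice` column (e.g. from
#'   [evaluate_cohort()]), optionally grouped columns `method`.
#' @return tibble with `n`, `median_dice`, `sd_dice` (per method when a
#'   `method` column is present).
#' @export
cohort_summary <- function(results) {
  if (nrow(results) == 0) stop("empty result set")
  by <- intersect("method", names(results))
  results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_dice = stats::median(.data$dice),
      sd_dice = if (dplyr::n() > 1) stats::sd(.data$dice) else 0,
      .groups = "drop"
    )
}

#' Neighbourhood-size sensitivity sweep
#'
#' Runs the full pipeline once per value of `k` (identical volume, hence
#' identical noise realization across `k`) and reports the Dice score per
#' value with per-sweep summary statistics. Both NLDR methods are
#' insensitive to large neighbourhoods (k >= 100) but degrade for small
#' ones, LLE more so than Isomap.
#'
#' @param vol volume or phantom to sweep on.
#' @param method embedding method.
#' @param k_values integer vector of neighbourhood sizes.
#' @param resolution optional working resolution (see
#'   [evaluate_volume()]).
#' @param ... further pipeline arguments.
#' @return A `sweep_report` tibble (one row per `k`) with attribute
#'   `summary` (median and sd of Dice over the sweep).
#' @export
k_sensitivity_sweep <- function(vol, method = "isomap", k_values,
                                resolution = NULL, ...) {
  stopifnot(length(k_values) >= 1, all(k_values >= 1))
  rows <- purrr::list_rbind(lapply(k_values, function(kv) {
    evaluate_volume(vol, method = method, k = kv, resolution = resolution,
                    ...)
  }))
  new_sweep_report(rows, swept = "k")
}

#' Resolution sensitivity sweep
#'
#' Runs the pipeline at each working resolution (block-mean downsampling
#' from the native grid) with fixed `k`. Partial-volume blurring of lesion
#' boundaries lowers Dice as resolution drops.
#'
#' @inheritParams k_sensitivity_sweep
#' @param resolutions target side lengths, e.g. `c(256, 128, 64)`.
#' @param k fixed neighbourhood size.
#' @return A `sweep_report` tibble (one row per resolution).
#' @export
resolution_sensitivity_sweep <- function(vol, method = "isomap",
                                         resolutions = c(256, 128, 64),
                                         k = 100, ...) {
  stopifnot(length(resolutions) >= 1)
  rows <- purrr::list_rbind(lapply(resolutions, function(r) {
    evaluate_volume(vol, method = method, k = k, resolution = r, ...)
  }))
  new_sweep_report(rows, swept = "resolution")
}

new_sweep_report <- function(rows, swept) {
  out <- tibble::new_tibble(rows, swept = swept,
                            class = "sweep_report")
  attr(out, "summary") <- tibble::tibble(
    swept = swept,
    median_dice = stats::median(rows$dice),
    sd_dice = if (nrow(rows) > 1) stats::sd(rows$dice) else 0
  )
  out
}

#' @export
summary.sweep_report <- function(object, ...) {
  attr(object, "summary")
}

#' Write a result table to CSV and JSON
#'
#' @param results tibble of Dice results or a sweep report.
#' @param path output path without extension; `.csv` and `.json` files are
#'   written next to each other.
#' @return invisibly, the two paths.
#' @export
write_results <- function(results, path) {
  csv <- paste0(path, ".csv")
  js <- paste0(path, ".json")
  utils::write.csv(as.data.frame(results), csv, row.names = FALSE)
  jsonlite::write_json(results, js, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(c(csv, js))
}
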
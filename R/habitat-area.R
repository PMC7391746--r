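#' Mean July-August temperature per cell and year
#'
#' Equal-weight mean of the daily mean temperatures over July 1 - August 31
#' for each cell and year, the quantity thresholded by [compute_sha()].
#'
#' @inheritParams temp_index
#' @return Tibble with `cell_id`, `year`, `summer_mean_c`.
#' @export
summer_cell_means <- function(grid, years = NULL, cells = NULL) {
  summer <- summer_records(grid, years = years, cells = cells)
  summer |>
    dplyr::group_by(.data$cell_id, .data$year) |>
    dplyr::summarise(summer_mean_c = mean(.data$tmean_c), .groups = "drop") |>
    dplyr::arrange(.data$cell_id, .data$year)
}

#' Summer habitat area below a temperature threshold
#'
#' Total area of grid cells whose July-August mean daily temperature does
#' not exceed the threshold, per year. The comparison is inclusive (a cell
#' sitting exactly at the threshold counts as habitat), matching the
#' "does not exceed" reading of thermal suitability for a species whose
#' reproductive diapause is thought to require cool summer refuges. Cell
#' areas default to 1 km2 each.
#'
#' @inheritParams temp_index
#' @param threshold_c Threshold(s) in degrees C; the customary sensitivity
#'   sweep is `21:25` around the 23 degC hypothesis.
#' @return Tibble with `year`, `threshold_c`, `sha_km2` (one row per year
#'   and threshold).
#' @export
#' @examples
#' # 4 cool cells of 1 km2 and 6 warm ones -> SHA = 4 km2 at 23 degC
compute_sha <- function(grid, threshold_c = 23, years = NULL, cells = NULL) {
  if (!is.numeric(threshold_c) || length(threshold_c) < 1) {
    abort("`threshold_c` must be numeric.")
  }
  summer <- summer_records(grid, years = years, cells = cells)
  cell_meta <- attr(summer, "cells", exact = TRUE)
  means <- summer |>
    dplyr::group_by(.data$cell_id, .data$year) |>
    dplyr::summarise(summer_mean_c = mean(.data$tmean_c), .groups = "drop") |>
    dplyr::left_join(cell_meta[, c("cell_id", "area_km2")], by = "cell_id")

  purrr::map_dfr(threshold_c, function(th) {
    means |>
      dplyr::group_by(.data$year) |>
      dplyr::summarise(
        threshold_c = th,
        sha_km2 = sum(.data$area_km2[.data$summer_mean_c <= th]),
        .groups = "drop"
      )
  }) |>
    dplyr::arrange(.data$threshold_c, .data$year)
}

#' Regress growth rates on the change in summer habitat area
#'
#' Convenience wrapper pairing [growth_rates()] output with the first
#' difference of a habitat-area series (same-year with `lag = 0`,
#' previous-year with `lag = 1`) through [fit_growth_model()]. The slope is
#' per km2 of habitat change.
#'
#' @param growth Tibble from [growth_rates()].
#' @param sha Tibble from [compute_sha()] restricted to a single threshold.
#' @param lag 0 (same-year change) or 1 (previous-year change).
#' @param window Analysis years; default `1993:2004`.
#' @return A `growth_fit` with `model_id` `"sha_lag0"` or `"sha_lag1"`.
#' @export
sha_regression <- function(growth, sha, lag = 0, window = 1993:2004) {
  if (!is.data.frame(sha) || !all(c("year", "sha_km2") %in% names(sha))) {
    abort("`sha` must have columns `year` and `sha_km2` (see compute_sha()).")
  }
  if ("threshold_c" %in% names(sha) &&
      dplyr::n_distinct(sha$threshold_c) > 1) {
    abort("`sha` holds several thresholds; filter to one before fitting.")
  }
  fit_growth_model(
    growth,
    predictor = sha[, c("year", "sha_km2")],
    model = "custom",
    lag = lag,
    window = window,
    model_id = paste0("sha_lag", lag)
  )
}
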
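#' Annual summer-temperature index from gridded daily means
#'
#' For each year, computes within each grid cell the 90th percentile (by
#' default) of the daily mean temperatures over July 1 to August 31, then
#' averages those per-cell percentiles across cells. Using an upper
#' percentile of the daily *means* targets sustained heat rather than
#' momentary maxima; aggregation is percentile-per-cell first, spatial mean
#' second (never a percentile of pooled days). The spatial mean is
#' unweighted unless `area_weighted = TRUE`, in which case cell areas from
#' the grid's cell metadata are used as weights.
#'
#' @param grid Daily temperature grid (see [validate_grid()]).
#' @param years Optional contiguous integer years to index; defaults to all
#'   years with July-August records. Every cell must have at least one
#'   summer record in every requested year.
#' @param cells Optional cell metadata, as in [validate_grid()].
#' @param prob Percentile level in (0, 1]; default 0.9.
#' @param quantile_type Percentile convention, passed to [stats::quantile()]
#'   `type`; default 7 (linear interpolation between order statistics).
#' @param area_weighted Weight the spatial mean by cell area? Default FALSE.
#' @return Tibble with columns `year` and `temp_c` (index in degrees
#'   Celsius), one row per year.
#' @seealso [moving_average()] to append the 5-year moving average.
#' @export
#' @examples
#' g <- tibble::tibble(
#'   cell_id = "c1",
#'   date = as.Date("2000-07-01") + 0:61,
#'   tmean_c = 1:62
#' )
#' temp_index(g) # 90th percentile of 1..62 = 55.9
temp_index <- function(grid, years = NULL, cells = NULL, prob = 0.9,
                       quantile_type = 7, area_weighted = FALSE) {
  stopifnot(is.numeric(prob), length(prob) == 1, prob > 0, prob <= 1)
  summer <- summer_records(grid, years = years, cells = cells)
  cell_meta <- attr(summer, "cells", exact = TRUE)

  per_cell <- summer |>
    dplyr::group_by(.data$year, .data$cell_id) |>
    dplyr::summarise(
      q = quantile(.data$tmean_c, probs = prob, type = quantile_type,
                   names = FALSE),
      .groups = "drop"
    )
  w <- if (area_weighted) {
    setNames(cell_meta$area_km2, cell_meta$cell_id)
  } else {
    setNames(rep(1, nrow(cell_meta)), cell_meta$cell_id)
  }
  per_cell |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      temp_c = sum(.data$q * w[.data$cell_id]) / sum(w[.data$cell_id]),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$year)
}

#' Centred moving average of an annual index
#'
#' Appends a `temp_ma_c` column holding the centred `width`-year mean of
#' `temp_c`. Years lacking a complete window get `NA`: the window is never
#' shortened at the edges, so with the default width the first and last two
#' years carry no moving average. The annual index fluctuates too widely
#' from year to year for raw decadal differences to be meaningful; the
#' moving average is what the decadal trend statistics operate on.
#'
#' @param index Tibble with columns `year` (contiguous) and `temp_c`.
#' @param width Odd window width in years; default 5. `width = 1` returns
#'   the series itself.
#' @return The input tibble with a `temp_ma_c` column added (replaced if
#'   already present).
#' @export
#' @examples
#' idx <- tibble::tibble(year = 1990:1994, temp_c = 1:5)
#' moving_average(idx) # MA defined only in 1992 (= 3)
moving_average <- function(index, width = 5) {
  check_annual_series(index, "temp_c")
  if (!is.numeric(width) || length(width) != 1 || width < 1 ||
      width != as.integer(width)) {
    abort("`width` must be a single positive integer.")
  }
  if (width %% 2 == 0) {
    abort("`width` must be odd: a centred moving-average window of even width is undefined.")
  }
  index <- dplyr::arrange(index, .data$year)
  v <- index$temp_c
  n <- length(v)
  k <- (width - 1) / 2
  ma <- rep(NA_real_, n)
  if (n >= width) {
    sm <- as.numeric(stats::filter(v, rep(1 / width, width), sides = 2))
    ma[(k + 1):(n - k)] <- sm[(k + 1):(n - k)]
  }
  index$temp_ma_c <- ma
  index
}

# shared check for tibbles holding one contiguous annual series
check_annual_series <- function(x, value_col, arg = deparse(substitute(x))) {
  if (!is.data.frame(x) || !all(c("year", value_col) %in% names(x))) {
    abort(paste0("`", arg, "` must be a data frame with columns `year` and `",
                 value_col, "`."))
  }
  yrs <- sort(x$year)
  if (anyDuplicated(yrs)) {
    abort(paste0("`", arg, "` has duplicated years."))
  }
  if (length(yrs) > 1 && !all(diff(yrs) == 1)) {
    abort(paste0("`", arg, "` must cover a contiguous run of years (gap ",
                 "after ", yrs[which(diff(yrs) != 1)[1]], ")."))
  }
  invisible(x)
}
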
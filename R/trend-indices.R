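#' Decadal trend statistics of the summer-temperature index
#'
#' Summarises how much the index moved over a decade relative to how much
#' it wobbles from year to year. Three statistics are reported for a window
#' from `start_year` to `end_year`:
#' \describe{
#'   \item{`diff_c`}{MA(end) - MA(start), the change in the 5-year moving
#'     average over the decade, in degrees C.}
#'   \item{`rate_pct`}{100 * diff_c / MA(start), the percentage rate of
#'     change.}
#'   \item{`stdiff`}{diff_c / SD, the decadal change standardized to the
#'     standard deviation of the *annual* (not smoothed) index over
#'     `sd_years`. `|stdiff| < 1` means the decadal shift lies within the
#'     range of ordinary interannual fluctuation, the qualitative criterion
#'     reported as `within_fluctuation`.}
#' }
#' stdiff is a dimensionless ratio even though decadal summaries sometimes
#' print it under a degrees-C heading.
#'
#' Decade presets: `"1990s"` is 1990-1999 and `"2000s"` is 2000-2009;
#' `"1980s"` is 1983-1989 (monitoring data only reach back to 1983). The
#' SD window defaults to the same annual span.
#'
#' @param index Tibble with `year` and `temp_c`; a `temp_ma_c` column is
#'   used if present, otherwise the 5-year moving average is computed. The
#'   moving average must be defined (full window available) at both
#'   endpoints.
#' @param decade Optional preset label (`"1980s"`, `"1990s"`, `"2000s"`)
#'   setting the years below.
#' @param start_year,end_year Decade endpoints (years of the two moving
#'   averages differenced).
#' @param sd_years Years over which the interannual SD of the annual index
#'   is taken; default `start_year:end_year`; needs >= 2 values.
#' @param sd_method `"sample"` (n-1 denominator, default) or
#'   `"population"` (n).
#' @return One-row tibble: `decade`, `start_year`, `end_year`, `diff_c`,
#'   `rate_pct`, `sd_c`, `stdiff`, `within_fluctuation`. A zero SD leaves
#'   `stdiff` as `NA` with a warning (the standardized difference is
#'   undefined).
#' @export
#' @examples
#' idx <- tibble::tibble(year = 1986:2003, temp_c = 24 + 0.05 * (0:17))
#' decadal_indices(idx, start_year = 1990, end_year = 1999)
decadal_indices <- function(index, decade = NULL, start_year = NULL,
                            end_year = NULL, sd_years = NULL,
                            sd_method = c("sample", "population")) {
  sd_method <- match.arg(sd_method)
  if (!is.null(decade)) {
    preset <- decade_years(decade)
    start_year <- start_year %||% preset$start
    end_year <- end_year %||% preset$end
  }
  if (is.null(start_year) || is.null(end_year)) {
    abort("Supply either `decade` or both `start_year` and `end_year`.")
  }
  if (end_year <= start_year) abort("`end_year` must exceed `start_year`.")
  sd_years <- sd_years %||% seq(start_year, end_year)
  check_annual_series(index, "temp_c", arg = "index")
  if (!"temp_ma_c" %in% names(index)) {
    index <- moving_average(index, width = 5)
  }
  index <- dplyr::arrange(index, .data$year)

  ma_at <- function(y) {
    row <- index[index$year == y, ]
    if (nrow(row) == 0 || is.na(row$temp_ma_c)) {
      abort(paste0(
        "Moving average undefined at ", y, ": the full 5-year window (",
        y - 2, "-", y + 2, ") of annual index values is required."
      ))
    }
    row$temp_ma_c
  }
  ma_start <- ma_at(start_year)
  ma_end <- ma_at(end_year)

  annual <- index$temp_c[index$year %in% sd_years]
  if (length(annual) < 2) {
    abort("`sd_years` must cover at least 2 annual index values.")
  }
  sd_c <- sd(annual)
  if (sd_method == "population") {
    sd_c <- sd_c * sqrt((length(annual) - 1) / length(annual))
  }

  diff_c <- ma_end - ma_start
  rate_pct <- 100 * diff_c / ma_start
  if (sd_c == 0) {
    warn("Interannual SD is zero; the standardized difference is undefined (NA).")
    stdiff <- NA_real_
  } else {
    stdiff <- diff_c / sd_c
  }
  tibble::tibble(
    decade = decade %||% paste0(start_year, "-", end_year),
    start_year = as.integer(start_year),
    end_year = as.integer(end_year),
    diff_c = diff_c,
    rate_pct = rate_pct,
    sd_c = sd_c,
    stdiff = stdiff,
    within_fluctuation = abs(stdiff) < 1
  )
}

#' Decade preset year ranges
#'
#' @param decade `"1980s"`, `"1990s"` or `"2000s"`.
#' @return List with `start` and `end` years. The 1980s run 1983-1989
#'   because the population monitoring only reaches back to 1983.
#' @export
decade_years <- function(decade) {
  switch(as.character(decade),
    "1980s" = list(start = 1983L, end = 1989L),
    "1990s" = list(start = 1990L, end = 1999L),
    "2000s" = list(start = 2000L, end = 2009L),
    abort(paste0("Unknown decade preset '", decade,
                 "'; use \"1980s\", \"1990s\" or \"2000s\"."))
  )
}
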
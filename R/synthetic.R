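#' Describe a synthetic gridded-temperature scenario
#'
#' Parameters of the generative model behind [simulate_temperature_grid()].
#' The daily mean for cell c on day d of year t is
#'
#'   seasonal(d) - lapse * elevation_c / 100 + trend * (t - t0)
#'     + A_t + eta_{c,d}
#'
#' with a sinusoidal seasonal cycle peaking in early August, a linear
#' elevational lapse, an optional linear warming trend, a year-level
#' anomaly A_t ~ N(0, annual_anomaly_sd_c^2) shared by all cells and days
#' of the year (the dominant source of interannual index variability), and
#' iid daily noise eta ~ N(0, daily_noise_sd_c^2). Defaults emulate a
#' temperate lowland-to-hill prefecture: sea-level summer peak near 26
#' degC, interannual anomaly SD 0.7 degC, daily noise SD 1.5 degC, lapse
#' 0.6 degC per 100 m, warming 0.3 degC per decade — a regime whose
#' decadal change typically stays within interannual fluctuation
#' (|stdiff| < 1).
#'
#' @param n_cells Number of grid cells (>= 1).
#' @param elevations_m Per-cell elevations; default an even ramp 0-800 m.
#' @param lapse_rate_c_per_100m Lapse rate, degrees C per 100 m; default 0.6.
#' @param seasonal_mean_c Annual mean at sea level; default 14.
#' @param seasonal_amplitude_c Seasonal half-range; default 12 (so the
#'   sea-level peak is 26 degC).
#' @param peak_doy Day of year of the seasonal peak; default 216 (Aug 4).
#' @param annual_anomaly_sd_c SD of the shared annual anomaly; default 0.7.
#' @param daily_noise_sd_c SD of iid daily noise; default 1.5.
#' @param trend_c_per_decade Linear warming trend; default 0.3.
#' @param years Contiguous calendar years; default 1981:2010.
#' @param summer_only Emit July-August days only (default TRUE), or full
#'   calendar years.
#' @return A `temperature_scenario` list.
#' @export
temperature_scenario <- function(n_cells = 9,
                                 elevations_m = NULL,
                                 lapse_rate_c_per_100m = 0.6,
                                 seasonal_mean_c = 14,
                                 seasonal_amplitude_c = 12,
                                 peak_doy = 216,
                                 annual_anomaly_sd_c = 0.7,
                                 daily_noise_sd_c = 1.5,
                                 trend_c_per_decade = 0.3,
                                 years = 1981:2010,
                                 summer_only = TRUE) {
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 1) abort("`n_cells` must be >= 1.")
  elevations_m <- elevations_m %||%
    (if (n_cells == 1) 0 else seq(0, 800, length.out = n_cells))
  if (length(elevations_m) != n_cells) {
    abort("`elevations_m` must have one value per cell.")
  }
  years <- as.integer(years)
  if (length(years) == 0) abort("`years` must not be empty.")
  if (length(years) > 1 && !all(diff(years) == 1L)) {
    abort("`years` must be contiguous.")
  }
  for (nm in c("annual_anomaly_sd_c", "daily_noise_sd_c")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 0) {
      abort(paste0("`", nm, "` must be a single non-negative number."))
    }
  }
  structure(
    list(
      n_cells = n_cells,
      elevations_m = as.numeric(elevations_m),
      lapse_rate_c_per_100m = lapse_rate_c_per_100m,
      seasonal_mean_c = seasonal_mean_c,
      seasonal_amplitude_c = seasonal_amplitude_c,
      peak_doy = peak_doy,
      annual_anomaly_sd_c = annual_anomaly_sd_c,
      daily_noise_sd_c = daily_noise_sd_c,
      trend_c_per_decade = trend_c_per_decade,
      years = years,
      summer_only = isTRUE(summer_only)
    ),
    class = "temperature_scenario"
  )
}

seasonal_curve <- function(doy, scenario) {
  scenario$seasonal_mean_c + scenario$seasonal_amplitude_c *
    cos(2 * pi * (doy - scenario$peak_doy) / 365.25)
}

#' Simulate a gridded daily-temperature dataset
#'
#' Draws a daily temperature grid from a [temperature_scenario()]. Random
#' draws come from named per-component streams derived from `seed` (one
#' for the annual anomalies, one for the daily noise), so changing one
#' component's SD leaves the realized values of the others untouched, and
#' the same scenario and seed always yield an identical grid.
#'
#' @param scenario A [temperature_scenario()].
#' @param seed Integer seed.
#' @return A daily temperature grid tibble (`cell_id`, `date`, `tmean_c`)
#'   with a `"cells"` attribute (`cell_id`, `elevation_m`, `area_km2 = 1`),
#'   ready for [temp_index()] or [compute_sha()].
#' @export
#' @examples
#' sc <- temperature_scenario(n_cells = 2, years = 1995:1999)
#' g <- simulate_temperature_grid(sc, seed = 1)
#' temp_index(g)
simulate_temperature_grid <- function(scenario, seed = 1) {
  if (!inherits(scenario, "temperature_scenario")) {
    abort("`scenario` must come from temperature_scenario().")
  }
  years <- scenario$years
  dates_one_year <- function(y) {
    if (scenario$summer_only) {
      seq(as.Date(sprintf("%d-07-01", y)), as.Date(sprintf("%d-08-31", y)),
          by = "day")
    } else {
      seq(as.Date(sprintf("%d-01-01", y)), as.Date(sprintf("%d-12-31", y)),
          by = "day")
    }
  }
  dates <- do.call(c, lapply(years, dates_one_year))
  cells <- tibble::tibble(
    cell_id = sprintf("cell%02d", seq_len(scenario$n_cells)),
    elevation_m = scenario$elevations_m,
    area_km2 = 1
  )

  set.seed(sub_seed(seed, "annual_anomaly"))
  anomaly <- rnorm(length(years), 0, scenario$annual_anomaly_sd_c)
  names(anomaly) <- years

  grid <- tidyr::expand_grid(cell_id = cells$cell_id, date = dates)
  yr <- format(grid$date, "%Y")
  doy <- as.integer(format(grid$date, "%j"))
  elev <- setNames(cells$elevation_m, cells$cell_id)

  set.seed(sub_seed(seed, "daily_noise"))
  eta <- rnorm(nrow(grid), 0, scenario$daily_noise_sd_c)

  grid$tmean_c <- seasonal_curve(doy, scenario) -
    scenario$lapse_rate_c_per_100m * unname(elev[grid$cell_id]) / 100 +
    scenario$trend_c_per_decade * (as.integer(yr) - years[1]) / 10 +
    unname(anomaly[yr]) + eta
  grid <- dplyr::arrange(grid, .data$cell_id, .data$date)
  attr(grid, "cells") <- cells
  grid
}

#' Simulate an annual population density series from the growth model
#'
#' Generates N_t = N_{t-1} * exp(alpha + beta * dTEMP_{t-lag} + eps_t) with
#' eps_t iid N(0, sigma_eps^2), i.e. data that conform exactly to the
#' regression models fitted by [fit_growth_model()] — `model = "model1"`
#' uses the same-year temperature change (lag 0), `"model2"` the
#' previous-year change (lag 1). The realized eps draws are returned in an
#' `eps` column so the generated growth rates can be audited exactly.
#'
#' @param index Temperature index tibble (`year`, `temp_c`) covering every
#'   needed lagged year.
#' @param alpha Intercept (temperature-independent log growth per year).
#' @param beta Slope per degree C.
#' @param sigma_eps SD of the error term; 0 gives a deterministic series.
#' @param model `"model1"` (default) or `"model2"`.
#' @param n0 Density in the first year; default 100 individuals/h.
#' @param years Series years (first year carries `n0`); default the widest
#'   run the index supports at the model's lag.
#' @param seed Integer seed (its own named stream).
#' @return Tibble with `year`, `density`, `eps` (`NA` in the first year).
#' @export
simulate_population <- function(index, alpha = 0.1, beta = -0.232,
                                sigma_eps = 0.3,
                                model = c("model1", "model2"),
                                n0 = 100, years = NULL, seed = 1) {
  model <- match.arg(model)
  lag <- if (model == "model1") 0L else 1L
  check_annual_series(index, "temp_c", arg = "index")
  if (!is.numeric(n0) || n0 <= 0) abort("`n0` must be positive.")
  if (sigma_eps < 0) abort("`sigma_eps` must be non-negative.")
  index <- dplyr::arrange(index, .data$year)
  years <- as.integer(years %||% seq(min(index$year) + lag, max(index$year)))
  if (length(years) < 2) abort("`years` must span at least 2 years.")
  if (!all(diff(years) == 1L)) abort("`years` must be contiguous.")

  deltas <- delta_series(index, lag = lag)
  growth_years <- years[-1]
  d <- deltas$delta[match(growth_years, deltas$year)]
  if (anyNA(d)) {
    abort(paste0(
      "Temperature change unavailable for year(s) ",
      paste(growth_years[is.na(d)], collapse = ", "),
      "; the index must reach back to ", min(years) - 1 - lag, "."
    ))
  }
  set.seed(sub_seed(seed, "epsilon"))
  eps <- rnorm(length(growth_years), 0, sigma_eps)
  lambda <- alpha + beta * d + eps
  density <- n0 * exp(cumsum(c(0, lambda)))
  tibble::tibble(
    year = years,
    density = density,
    eps = c(NA_real_, eps)
  )
}
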
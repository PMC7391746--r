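#' Temperature-only population projection
#'
#' Projects relative population density from a fitted temperature slope
#' under the assumption that temperature is the only driver: the intercept
#' and the error term of the growth model are set to zero, so the annual
#' growth rate is lambda_t = beta * dTEMP_t. The recursion
#' N_t = N_{t-1} * exp(beta * dTEMP_t) telescopes to the closed form
#' N_t = exp(beta * (TEMP_t - TEMP_base)), which is what is evaluated; the
#' density of the base year is exactly 1. The band transforms the 95%
#' confidence limits of beta through the same closed form (pointwise in the
#' slope, not a predictive interval). Any temperature series can be
#' supplied, including what-if warming scenarios.
#'
#' @param index Tibble with `year` and `temp_c`, contiguous from
#'   `base_year` onward (earlier years are ignored).
#' @param beta Slope per degree C, or a `growth_fit` from
#'   [fit_growth_model()] (its slope and 95% CI are used).
#' @param beta_ci Optional length-2 numeric, the slope's confidence limits;
#'   ignored when `beta` is a fit.
#' @param base_year Year whose density defines the reference value 1.
#' @return Tibble of class `density_projection`: `year`,
#'   `relative_density`, and (when a CI is available) `band_lo`, `band_hi`.
#' @export
#' @examples
#' idx <- tibble::tibble(year = 1993:1996, temp_c = c(24, 24.5, 25, 26))
#' project_density(idx, beta = -0.25, base_year = 1993)
project_density <- function(index, beta, beta_ci = NULL, base_year) {
  if (inherits(beta, "growth_fit")) {
    est <- slope_estimate(beta)
    beta_ci <- est$ci
    beta <- est$beta
  }
  if (!is.numeric(beta) || length(beta) != 1 || !is.finite(beta)) {
    abort("`beta` must be a single finite slope (or a growth_fit).")
  }
  check_annual_series(index, "temp_c", arg = "index")
  index <- dplyr::arrange(index, .data$year)
  if (!base_year %in% index$year) {
    abort(paste0("`base_year` ", base_year, " is absent from the index."))
  }
  index <- index[index$year >= base_year, ]
  if (nrow(index) > 1 && !all(diff(index$year) == 1)) {
    abort("The index must be contiguous from `base_year` onward.")
  }
  d <- index$temp_c - index$temp_c[index$year == base_year]
  out <- tibble::tibble(
    year = index$year,
    relative_density = exp(beta * d)
  )
  if (!is.null(beta_ci)) {
    if (!is.numeric(beta_ci) || length(beta_ci) != 2) {
      abort("`beta_ci` must be a numeric vector of length 2.")
    }
    a <- exp(beta_ci[1] * d)
    b <- exp(beta_ci[2] * d)
    out$band_lo <- pmin(a, b)
    out$band_hi <- pmax(a, b)
  }
  out <- structure(out, base_year = as.integer(base_year), beta = beta)
  class(out) <- c("density_projection", class(out))
  out
}
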
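#' Benchmark results for the Toyama monitoring analysis
#'
#' Reference values of the growth-rate regressions (1993-2004 window) and
#' of the Toyama 1990s decadal trend row that the pipeline reproduces when
#' run on the original external inputs: the ~1-km2 agro-meteorological
#' temperature grids and the prefectural dragonfly monitoring series.
#' Neither input ships with the package (`requires_external_data` is TRUE
#' on every row), so these are documented expectations for users who
#' obtain the data, not test fixtures. The package's own verification is
#' property-based on synthetic data with known parameters.
#'
#' @return Tibble with `quantity`, `species`, `model_id`, `value`,
#'   `requires_external_data`.
#' @export
#' @examples
#' reference_fits()
reference_fits <- function() {
  tibble::tribble(
    ~quantity,    ~species,     ~model_id, ~value,
    "beta",       "frequens",   "model1",  -0.232,
    "p_beta",     "frequens",   "model1",   0.029,
    "r_squared",  "frequens",   "model1",   0.429,
    "aic",        "frequens",   "model1",  22.07,
    "aic",        "frequens",   "null",    26.24,
    "r_squared",  "frequens",   "model2",   0.143,
    "aic",        "frequens",   "model2",  26.54,
    "beta",       "infuscatum", "model1",  -0.242,
    "p_beta",     "infuscatum", "model1",   0.002,
    "r_squared",  "infuscatum", "model1",   0.659,
    "aic",        "infuscatum", "model1",  12.63,
    "aic",        "infuscatum", "null",    22.45,
    "beta",       "infuscatum", "model2",   0.214,
    "aic",        "infuscatum", "model2",  15.70,
    "diff_c",     NA,           "trend_1990s",  0.41,
    "rate_pct",   NA,           "trend_1990s",  1.73,
    "stdiff",     NA,           "trend_1990s",  0.33
  ) |>
    dplyr::mutate(requires_external_data = TRUE)
}
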
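Package: climepop
Title: Summer Temperature Indices and Climate-Driven Population Trend Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether summer warming can explain declines in
    annual wildlife monitoring series, built around red dragonfly (Sympetrum)
    population indices. Computes a summer temperature index (the spatial mean,
    across ~1-km2 grid cells, of each cell's 90th percentile of July-August
    daily mean temperature) from gridded daily data, decadal trend statistics
    on its 5-year moving average (difference, percentage rate, and difference
    standardized to interannual variability), linear regressions of annual
    log population growth rates on same-year or lagged temperature change with
    AIC model comparison and Durbin-Watson diagnostics, temperature-only
    population projections with confidence bands, and thermal habitat-area
    thresholding. Includes a seeded synthetic-data generator for gridded
    temperatures and model-conformant population series so the full pipeline
    is testable with known parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lmtest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
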
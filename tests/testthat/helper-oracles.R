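# Independent oracles, deliberately kept free of package internals.

# Percentile by explicit sort-and-interpolate between order statistics:
# rank h = 1 + p * (n - 1), linear interpolation between floor(h), ceiling(h).
percentile_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- 1 + p * (n - 1)
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# OLS via the normal equations, computed by hand from sums.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  beta <- sxy / sxx
  alpha <- mean(y) - beta * mean(x)
  resid <- y - alpha - beta * x
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(alpha = alpha, beta = beta, r_squared = r2, resid = resid)
}

# Gaussian AIC with the error variance counted as a parameter:
# -2 logLik + 2k, logLik at the MLE sigma^2 = RSS/n.
aic_oracle <- function(resid, n_coef) {
  n <- length(resid)
  rss <- sum(resid^2)
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  -2 * ll + 2 * (n_coef + 1)
}

# small deterministic single-cell grid whose summer days are given directly
grid_from_summer_values <- function(values_by_year, cell_id = "c1") {
  purrr::imap_dfr(values_by_year, function(vals, yr) {
    tibble::tibble(
      cell_id = cell_id,
      date = seq(as.Date(paste0(yr, "-07-01")), by = "day",
                 length.out = length(vals)),
      tmean_c = vals
    )
  })
}

# constant-summer grid over several cells and years
constant_grid <- function(cell_values, years) {
  purrr::map_dfr(years, function(yr) {
    dates <- seq(as.Date(paste0(yr, "-07-01")),
                 as.Date(paste0(yr, "-08-31")), by = "day")
    purrr::imap_dfr(cell_values, function(v, id) {
      tibble::tibble(cell_id = id, date = dates, tmean_c = v)
    })
  })
}
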
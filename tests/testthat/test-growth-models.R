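test_that("growth rates are log first differences, skipping zeros", {
  pop <- tibble::tibble(year = 2000:2001, density = c(1, exp(1)))
  expect_equal(growth_rates(pop)$lambda, 1)

  const <- tibble::tibble(year = 1995:2000, density = rep(7, 6))
  expect_equal(growth_rates(const)$lambda, rep(0, 5))

  drop4 <- tibble::tibble(year = 2002:2004, density = c(2, 4, 1))
  gr <- growth_rates(drop4)
  expect_equal(gr$lambda[gr$year == 2004], -log(4), tolerance = 1e-12)

  withzero <- tibble::tibble(year = 2000:2003, density = c(1, 0, 2, 4))
  expect_message(gz <- growth_rates(withzero), "zero")
  expect_equal(gz$year, 2003L)

  expect_error(growth_rates(tibble::tibble(year = 2000, density = 1)),
               "2 years")
  expect_error(growth_rates(tibble::tibble(year = 2000:2002,
                                           density = c(0, 0, 0))), "zero")
})

test_that("growth rates respect a species grouping column", {
  pop <- dplyr::bind_rows(
    tibble::tibble(species = "a", year = 2000:2002, density = c(1, 2, 4)),
    tibble::tibble(species = "b", year = 2000:2002, density = c(4, 2, 1))
  )
  gr <- growth_rates(pop)
  expect_equal(gr$lambda[gr$species == "a"], rep(log(2), 2))
  expect_equal(gr$lambda[gr$species == "b"], rep(-log(2), 2))
})

test_that("delta series align to the response year at each lag", {
  idx <- tibble::tibble(year = 1993:1994, temp_c = c(24, 25.5))
  expect_equal(delta_series(idx), tibble::tibble(year = 1994L, delta = 1.5))

  idx3 <- tibble::tibble(year = 1992:1994, temp_c = c(24, 26, 25))
  lag1 <- delta_series(idx3, lag = 1)
  expect_equal(lag1$delta[lag1$year == 1994], 2)

  const <- tibble::tibble(year = 1990:1999, temp_c = rep(24, 10))
  expect_true(all(delta_series(const)$delta == 0))

  gap <- tibble::tibble(year = c(1990, 1992), temp_c = c(24, 25))
  expect_error(delta_series(gap), "contiguous")
})

test_that("a noiseless linear relation is recovered exactly", {
  d <- tibble::tibble(year = 1993:2004,
                      temp_c = 24 + cumsum(c(0, 0.3, -0.2, 0.5, -0.4, 0.1,
                                             0.2, -0.3, 0.4, -0.1, 0.2, -0.2)))
  deltas <- delta_series(d)
  gr <- tibble::tibble(year = deltas$year,
                       lambda = 0.5 - 0.2 * deltas$delta)
  # summary.lm warns about the essentially perfect fit; that is the point
  suppressWarnings({
    fit <- fit_growth_model(gr, d, model = "model1", window = 1994:2004)
    est <- coef(fit)
    r2 <- glance(fit)$r.squared
  })
  expect_equal(unname(est[["(Intercept)"]]), 0.5, tolerance = 1e-9)
  expect_equal(unname(est[["predictor"]]), -0.2, tolerance = 1e-9)
  expect_equal(r2, 1, tolerance = 1e-9)
})

test_that("OLS matches the normal-equations oracle on small random data", {
  set.seed(101)
  for (i in 1:25) {
    x <- rnorm(12, 0, 1)
    y <- 0.2 - 0.3 * x + rnorm(12, 0, 0.4)
    idx <- tibble::tibble(year = 1992:2004, temp_c = cumsum(c(24, x)))
    gr <- tibble::tibble(year = 1993:2004, lambda = y)
    fit <- fit_growth_model(gr, idx, model = "model1")
    oracle <- ols_oracle(x, y)
    expect_equal(unname(coef(fit)[["(Intercept)"]]), oracle$alpha,
                 tolerance = 1e-9)
    expect_equal(unname(coef(fit)[["predictor"]]), oracle$beta,
                 tolerance = 1e-9)
    expect_equal(glance(fit)$r.squared, oracle$r_squared, tolerance = 1e-9)
    expect_equal(glance(fit)$aic, aic_oracle(oracle$resid, 2),
                 tolerance = 1e-9)
  }
})

test_that("an orthogonal predictor yields a zero slope", {
  x <- c(-1, 1, -1, 1)
  y <- c(1, 1, -1, -1)              # centred, sum(x*y) = 0 by construction
  stopifnot(sum(x * y) == 0, sum(x) == 0, sum(y) == 0)
  idx <- tibble::tibble(year = 1992:1996, temp_c = cumsum(c(24, x)))
  gr <- tibble::tibble(year = 1993:1996, lambda = y)
  fit <- fit_growth_model(gr, idx, model = "model1", window = 1993:1996)
  expect_equal(unname(coef(fit)[["predictor"]]), 0, tolerance = 1e-12)
})

test_that("slope is invariant to constant shifts of the predictor in delta mode", {
  set.seed(5)
  idx <- tibble::tibble(year = 1992:2004, temp_c = 24 + rnorm(13, 0, 0.7))
  gr <- tibble::tibble(year = 1993:2004, lambda = rnorm(12, 0, 0.3))
  f1 <- fit_growth_model(gr, idx, model = "model1")
  idx2 <- dplyr::mutate(idx, temp_c = temp_c + 3.2)
  f2 <- fit_growth_model(gr, idx2, model = "model1")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-9)
})

test_that("guard rails: variance, coverage, sample size", {
  gr <- tibble::tibble(year = 1993:2004, lambda = rnorm(12))
  flat <- tibble::tibble(year = 1992:2004, temp_c = rep(24, 13))
  expect_error(fit_growth_model(gr, flat, model = "model1"),
               "zero variance")
  short_idx <- tibble::tibble(year = 1996:2004, temp_c = rnorm(9, 24))
  expect_error(fit_growth_model(gr, short_idx, model = "model1"),
               "cover every response year")
  expect_error(
    fit_growth_model(gr[1:2, ], tibble::tibble(year = 1992:2004,
                                               temp_c = rnorm(13, 24)),
                     model = "model1", window = 1993:1994),
    "at least 3"
  )
  expect_error(fit_growth_model(gr,
                                tibble::tibble(year = 2010:2020,
                                               temp_c = rnorm(11, 24)),
                                model = "model1", window = 2015:2016),
               "window")
})

test_that("model 2 uses the previous year's temperature change", {
  set.seed(11)
  idx <- tibble::tibble(year = 1991:2004, temp_c = 24 + rnorm(14, 0, 0.7))
  d_lag1 <- delta_series(idx, lag = 1)
  gr <- tibble::tibble(
    year = 1993:2004,
    lambda = 0.1 + 0.25 * d_lag1$delta[match(1993:2004, d_lag1$year)]
  )
  fit <- fit_growth_model(gr, idx, model = "model2")
  expect_equal(unname(coef(fit)[["predictor"]]), 0.25, tolerance = 1e-9)
})

test_that("covariates enter as additional regressors", {
  set.seed(21)
  idx <- tibble::tibble(year = 1992:2004, temp_c = 24 + rnorm(13, 0, 0.7))
  d <- delta_series(idx)
  cov <- tibble::tibble(year = 1993:2004, usage = seq(1, 0.4, length.out = 12))
  gr <- tibble::tibble(
    year = 1993:2004,
    lambda = 0.1 - 0.3 * d$delta[match(1993:2004, d$year)] + 0.5 * cov$usage
  )
  fit <- fit_growth_model(gr, idx, model = "model1", covariates = cov)
  expect_equal(unname(coef(fit)[["predictor"]]), -0.3, tolerance = 1e-9)
  expect_equal(unname(coef(fit)[["usage"]]), 0.5, tolerance = 1e-9)
})

test_that("Durbin-Watson statistic follows its definition", {
  expect_equal(durbin_watson(rep(c(1, -1), 5)), 3.6)
  expect_error(durbin_watson(rep(0, 10)), "zero")
  expect_error(durbin_watson(c(1, -1)), "3")

  set.seed(2024)
  e <- rnorm(1e4)
  expect_lt(abs(durbin_watson(e) - 2), 0.1)

  # agrees with the lmtest statistic on a real fit
  set.seed(8)
  idx <- tibble::tibble(year = 1992:2004, temp_c = 24 + rnorm(13, 0, 0.7))
  gr <- tibble::tibble(year = 1993:2004, lambda = rnorm(12, 0, 0.3))
  fit <- fit_growth_model(gr, idx, model = "model1")
  expect_equal(fit$dw_statistic,
               unname(lmtest::dwtest(fit$lm)$statistic),
               tolerance = 1e-9)
})

test_that("AIC prefers the predictor model exactly above the analytic R2 threshold", {
  # AIC(model) < AIC(null) iff n*log(1 - R2) + 2 < 0, i.e. R2 > 1 - exp(-2/n)
  set.seed(61)
  n <- 12
  x <- scale(rnorm(n))[, 1]
  z <- scale(stats::resid(lm(rnorm(n) ~ x)))[, 1] # orthogonal to x
  for (r2 in c(0.05, 0.10, 0.1535, 0.1545, 0.25, 0.6)) {
    y <- sqrt(r2) * x + sqrt(1 - r2) * z
    idx <- tibble::tibble(year = 1992:2004, temp_c = cumsum(c(24, x)))
    gr <- tibble::tibble(year = 1993:2004, lambda = y)
    f1 <- fit_growth_model(gr, idx, model = "model1")
    f0 <- fit_growth_model(gr, idx, model = "null")
    better <- glance(f1)$aic < glance(f0)$aic
    expect_equal(better, r2 > 1 - exp(-2 / n))
  }
})

test_that("model comparison ranks by AIC and validates observation sets", {
  set.seed(31)
  idx <- tibble::tibble(year = 1991:2004, temp_c = 24 + rnorm(14, 0, 0.7))
  d <- delta_series(idx)
  gr <- tibble::tibble(
    year = 1993:2004,
    lambda = 0.1 - 0.3 * d$delta[match(1993:2004, d$year)] + rnorm(12, 0, 0.1)
  )
  f1 <- fit_growth_model(gr, idx, model = "model1")
  f2 <- fit_growth_model(gr, idx, model = "model2")
  f0 <- fit_growth_model(gr, idx, model = "null")
  cmp <- compare_models(f1, f2, f0)
  expect_equal(cmp$model_id[1], "model1") # data generated under model 1
  expect_equal(cmp$delta_aic[1], 0)
  expect_equal(cmp$delta_aic, cmp$aic - min(cmp$aic))
  expect_true("delta_aic_null" %in% names(cmp))

  # identical fits tie with a stable order
  f1b <- fit_growth_model(gr, idx, model = "model1", model_id = "model1b")
  cmp2 <- compare_models(f1, f1b)
  expect_equal(cmp2$delta_aic, c(0, 0))
  expect_equal(cmp2$model_id, c("model1", "model1b"))

  other <- fit_growth_model(gr[-1, ], idx, model = "model1")
  expect_error(compare_models(f1, other), "invalid")
})

test_that("tidy/glance/augment expose the full fit surface", {
  set.seed(41)
  idx <- tibble::tibble(year = 1992:2004, temp_c = 24 + rnorm(13, 0, 0.7))
  gr <- tibble::tibble(year = 1993:2004, lambda = rnorm(12, 0, 0.3))
  fit <- fit_growth_model(gr, idx, model = "model1")
  td <- tidy(fit)
  expect_setequal(td$term, c("(Intercept)", "predictor"))
  beta_row <- td[td$term == "predictor", ]
  expect_true(beta_row$conf.low <= beta_row$estimate &&
                beta_row$estimate <= beta_row$conf.high)
  gl <- glance(fit)
  expect_true(gl$r.squared >= 0 && gl$r.squared <= 1)
  expect_equal(gl$nobs, 12L)
  au <- augment(fit)
  expect_equal(au$.fitted + au$.resid, au$lambda, tolerance = 1e-12)
})
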
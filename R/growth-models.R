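#' Annual log growth rates from a population density series
#'
#' Computes lambda_t = ln N_t - ln N_{t-1} for every pair of consecutive
#' years with positive densities. Monitoring indices are densities per
#' observer-hour, so a zero is a censored observation rather than a true
#' log-scale value: pairs touching a zero are skipped with a message, never
#' patched with a pseudo-count. If a `species` (and/or `region`) column is
#' present the computation is done per group.
#'
#' @param pop Tibble with columns `year` and `density` (or `density_per_h`),
#'   optionally `species` and `region`.
#' @return Tibble with the grouping columns, `year` and `lambda`; errors if
#'   no group yields at least one consecutive positive pair.
#' @export
#' @examples
#' pop <- tibble::tibble(year = 2000:2003, density = c(1, exp(1), 4, 1))
#' growth_rates(pop)
growth_rates <- function(pop) {
  if (!is.data.frame(pop) || !"year" %in% names(pop)) {
    abort("`pop` must be a data frame with a `year` column.")
  }
  dens_col <- intersect(c("density", "density_per_h"), names(pop))[1]
  if (is.na(dens_col)) {
    abort("`pop` must have a `density` (or `density_per_h`) column.")
  }
  group_cols <- intersect(c("species", "region"), names(pop))
  pop <- tibble::as_tibble(pop)
  if (!is.numeric(pop[[dens_col]]) || any(!is.finite(pop[[dens_col]])) ||
      any(pop[[dens_col]] < 0)) {
    abort("Densities must be finite and non-negative.")
  }

  one_group <- function(df) {
    df <- dplyr::arrange(df, .data$year)
    n <- nrow(df)
    if (n < 2) abort("A population series needs at least 2 years.")
    if (all(df[[dens_col]] == 0)) {
      abort("All densities are zero; growth rates are undefined.")
    }
    consecutive <- diff(df$year) == 1
    positive <- df[[dens_col]][-1] > 0 & df[[dens_col]][-n] > 0
    keep <- consecutive & positive
    n_zero <- sum(consecutive & !positive)
    if (n_zero > 0) {
      inform(paste0(
        "Skipped ", n_zero, " year pair(s) with a zero density; lambda is ",
        "undefined there."
      ))
    }
    if (!any(keep)) {
      abort("No consecutive year pair with positive densities; cannot compute growth rates.")
    }
    tibble::tibble(
      year = df$year[-1][keep],
      lambda = (log(df[[dens_col]][-1]) - log(df[[dens_col]][-n]))[keep]
    )
  }

  if (length(group_cols) == 0) {
    one_group(pop)
  } else {
    pop |>
      dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
      dplyr::group_modify(~ one_group(.x)) |>
      dplyr::ungroup()
  }
}

#' First differences of an annual series, aligned to a response year
#'
#' For lag 0 the difference attached to year t is value_t - value_{t-1}
#' (same-year change); for lag 1 it is value_{t-1} - value_{t-2} (the
#' previous year's change, the predictor of the lagged growth model).
#'
#' @param x Tibble with a `year` column and one value column (`temp_c`,
#'   `sha_km2`, or named via `value`).
#' @param lag Integer lag (0 or 1) applied when aligning to the response
#'   year.
#' @param value Name of the value column; guessed if omitted.
#' @return Tibble with `year` (the response year) and `delta`.
#' @export
#' @examples
#' idx <- tibble::tibble(year = 1992:1994, temp_c = c(24, 26, 25))
#' delta_series(idx)          # 1993: +2, 1994: -1
#' delta_series(idx, lag = 1) # 1994: +2
delta_series <- function(x, lag = 0, value = NULL) {
  if (!lag %in% c(0, 1)) abort("`lag` must be 0 or 1.")
  value <- value %||% guess_value_col(x)
  check_annual_series(x, value, arg = "x")
  x <- dplyr::arrange(x, .data$year)
  if (nrow(x) < 2) abort("Need at least 2 years to difference.")
  tibble::tibble(
    year = x$year[-1] + lag,
    delta = diff(x[[value]])
  )
}

guess_value_col <- function(x) {
  known <- intersect(c("temp_c", "sha_km2", "value", "delta"), names(x))
  if (length(known) > 0) return(known[1])
  num <- setdiff(names(x)[vapply(x, is.numeric, logical(1))], "year")
  if (length(num) == 0) abort("No numeric value column found.")
  num[1]
}

#' Regress annual growth rates on a temperature (or habitat) predictor
#'
#' Ordinary least-squares fit of lambda_t = alpha + beta * x_t + eps_t over
#' an analysis window, where x_t is by default the first difference of the
#' supplied annual series: same-year change for `"model1"` (heat stress
#' acting within the season), previous-year change for `"model2"` (diapause
#' disturbance carrying over), no predictor for `"null"`. `"custom"` takes
#' an explicit `lag`. `predictor_mode = "absolute"` regresses on the level
#' of the series (at the model's lag) instead of its difference.
#'
#' Errors are assumed independent between years; the Durbin-Watson
#' statistic on the time-ordered residuals (with the small-sample p-value
#' of [lmtest::dwtest()]) is reported so that assumption can be checked.
#' AIC uses the Gaussian log-likelihood with the error variance counted as
#' an estimated parameter (k = 3 for a one-predictor model, k = 2 for the
#' null), so values are comparable across fits on the same observations.
#'
#' The default window 1993-2004 drops later years in which the monitored
#' density had essentially bottomed out, where the density's lower bound
#' would bias growth rates upward.
#'
#' @param growth Tibble from [growth_rates()] (`year`, `lambda`); if it
#'   carries several species, filter first.
#' @param predictor Annual series tibble (`year` plus a value column), e.g.
#'   from [temp_index()] or [compute_sha()]. Optional for the null model
#'   (when given it fixes the observation set, keeping AICs comparable).
#' @param model `"model1"`, `"model2"`, `"null"` or `"custom"`.
#' @param lag Lag for `model = "custom"` (0 or 1).
#' @param window Analysis years (only endpoints are used); default
#'   `1993:2004`.
#' @param predictor_mode `"delta"` (default) or `"absolute"`.
#' @param covariates Optional tibble (`year` plus numeric columns) of
#'   additional regressors, e.g. regional insecticide use.
#' @param model_id Label stored on the fit; defaults to `model`.
#' @return A `growth_fit` object; see [tidy.growth_fit()],
#'   [glance.growth_fit()], [augment.growth_fit()] and
#'   [autoplot.growth_fit()].
#' @export
fit_growth_model <- function(growth, predictor = NULL,
                             model = c("model1", "model2", "null", "custom"),
                             lag = NULL, window = 1993:2004,
                             predictor_mode = c("delta", "absolute"),
                             covariates = NULL, model_id = NULL) {
  model <- match.arg(model)
  predictor_mode <- match.arg(predictor_mode)
  if (!is.data.frame(growth) || !all(c("year", "lambda") %in% names(growth))) {
    abort("`growth` must have columns `year` and `lambda` (see growth_rates()).")
  }
  if (any(c("species", "region") %in% names(growth))) {
    for (g in intersect(c("species", "region"), names(growth))) {
      if (dplyr::n_distinct(growth[[g]]) > 1) {
        abort(paste0("`growth` holds several ", g,
                     " series; filter to one before fitting."))
      }
    }
  }
  lag <- switch(model,
    model1 = 0L, model2 = 1L, null = 0L,
    custom = {
      if (is.null(lag)) abort("`model = \"custom\"` requires `lag`.")
      as.integer(lag)
    }
  )
  model_id <- model_id %||% model

  window <- range(window)
  resp <- growth |>
    dplyr::filter(.data$year >= window[1], .data$year <= window[2],
                  is.finite(.data$lambda)) |>
    dplyr::arrange(.data$year)
  if (nrow(resp) == 0) {
    abort(paste0("No growth-rate observations fall in the window ",
                 window[1], "-", window[2], "."))
  }

  dat <- tibble::tibble(year = resp$year, lambda = resp$lambda)
  rhs <- character(0)
  if (model != "null" || !is.null(predictor)) {
    if (is.null(predictor)) {
      abort("`predictor` is required for models with a temperature term.")
    }
    pred <- if (predictor_mode == "delta") {
      delta_series(predictor, lag = lag)
    } else {
      value <- guess_value_col(predictor)
      check_annual_series(predictor, value, arg = "predictor")
      tibble::tibble(year = predictor$year + lag,
                     delta = predictor[[value]])
    }
    dat <- dplyr::left_join(dat, pred, by = "year")
    if (anyNA(dat$delta)) {
      abort(paste0(
        "Predictor unavailable for response year(s) ",
        paste(dat$year[is.na(dat$delta)], collapse = ", "),
        "; the predictor series must cover every response year at lag ",
        lag, "."
      ))
    }
    names(dat)[names(dat) == "delta"] <- "predictor"
    if (model != "null") rhs <- "predictor"
  }
  if (!is.null(covariates)) {
    if (!is.data.frame(covariates) || !"year" %in% names(covariates)) {
      abort("`covariates` must be a data frame with a `year` column.")
    }
    cov_cols <- setdiff(names(covariates), "year")
    dat <- dplyr::left_join(dat, covariates, by = "year")
    if (anyNA(dat[cov_cols])) {
      abort("Covariates must cover every response year in the window.")
    }
    rhs <- c(rhs, cov_cols)
  }

  if (nrow(dat) < 3) {
    abort(paste0("Only ", nrow(dat), " paired observations; at least 3 are ",
                 "required to fit."))
  }
  if ("predictor" %in% names(dat) && var(dat$predictor) == 0) {
    abort("Predictor has zero variance over the window; the slope is unidentifiable.")
  }

  fml <- stats::as.formula(paste(
    "lambda ~", if (length(rhs) == 0) "1" else paste(rhs, collapse = " + ")
  ))
  lm_fit <- lm(fml, data = dat)

  res <- residuals(lm_fit)
  dw <- tryCatch(durbin_watson(res), error = function(e) NA_real_)
  dw_p <- if (is.na(dw)) {
    NA_real_
  } else {
    tryCatch(unname(lmtest::dwtest(lm_fit)$p.value),
             error = function(e) NA_real_)
  }

  structure(
    list(
      model_id = model_id,
      model = model,
      lag = lag,
      predictor_mode = predictor_mode,
      window = window,
      lm = lm_fit,
      data = dat,
      n_obs = nrow(dat),
      dw_statistic = dw,
      dw_p_value = dw_p
    ),
    class = "growth_fit"
  )
}

#' Durbin-Watson statistic of time-ordered residuals
#'
#' DW = sum((e_t - e_{t-1})^2) / sum(e_t^2), in \[0, 4\]; about 2 for
#' serially independent residuals.
#'
#' @param residuals Numeric vector of residuals in time order (>= 3 values,
#'   not all zero).
#' @return The statistic as a single number.
#' @export
#' @examples
#' durbin_watson(rep(c(1, -1), 5)) # 36/10 = 3.6
durbin_watson <- function(residuals) {
  if (!is.numeric(residuals) || length(residuals) < 3) {
    abort("`residuals` must be a numeric vector of at least 3 time-ordered values.")
  }
  if (all(residuals == 0)) {
    abort("Residuals are identically zero; the Durbin-Watson ratio is degenerate.")
  }
  sum(diff(residuals)^2) / sum(residuals^2)
}

#' Rank growth-model fits by AIC
#'
#' AIC comparison is only valid between models fitted to the same response
#' observations; the function verifies that and errors otherwise.
#'
#' @param ... `growth_fit` objects, or a single list of them.
#' @return Tibble sorted by AIC ascending (ties broken by `model_id`):
#'   `model_id`, `n_obs`, `r_squared`, `aic`, `delta_aic` (versus the best
#'   model) and, when a null fit is among them, `delta_aic_null`.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) &&
      !inherits(fits[[1]], "growth_fit")) {
    fits <- fits[[1]]
  }
  if (length(fits) < 2 || !all(vapply(fits, inherits, logical(1), "growth_fit"))) {
    abort("Supply at least two `growth_fit` objects.")
  }
  ref <- fits[[1]]$data[, c("year", "lambda")]
  for (f in fits[-1]) {
    cur <- f$data[, c("year", "lambda")]
    if (!isTRUE(all.equal(ref, cur, tolerance = 1e-9))) {
      abort("Fits use different response observations; AIC comparison is invalid.")
    }
  }
  out <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(
      model_id = f$model_id,
      n_obs = f$n_obs,
      r_squared = summary(f$lm)$r.squared,
      aic = AIC(f$lm)
    )
  })
  out <- dplyr::arrange(out, .data$aic, .data$model_id)
  out$delta_aic <- out$aic - out$aic[1]
  null_aic <- out$aic[out$model_id == "null"]
  if (length(null_aic) == 1) out$delta_aic_null <- out$aic - null_aic
  out
}

#' @export
print.growth_fit <- function(x, ...) {
  s <- summary(x$lm)
  cat("Growth-rate regression (", x$model_id, ")\n", sep = "")
  cat("  window: ", x$window[1], "-", x$window[2],
      ", n = ", x$n_obs, "\n", sep = "")
  if ("predictor" %in% names(coef(x$lm))) {
    ci <- confint(x$lm)["predictor", ]
    cat(sprintf("  beta = %.4f (95%% CI %.4f to %.4f), p = %.4g\n",
                coef(x$lm)[["predictor"]], ci[1], ci[2],
                s$coefficients["predictor", 4]))
  }
  cat(sprintf("  R^2 = %.3f, AIC = %.2f, Durbin-Watson = %.3f (p = %.3g)\n",
              s$r.squared, AIC(x$lm), x$dw_statistic, x$dw_p_value))
  invisible(x)
}

#' Coefficient-level summary of a growth-model fit
#'
#' @param x A `growth_fit`.
#' @param conf.level Confidence level for the slope interval; default 0.95.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high`.
#' @exportS3Method generics::tidy
tidy.growth_fit <- function(x, conf.level = 0.95, ...) {
  s <- summary(x$lm)$coefficients
  ci <- confint(x$lm, level = conf.level)
  tibble::tibble(
    term = rownames(s),
    estimate = s[, 1],
    std.error = s[, 2],
    statistic = s[, 3],
    p.value = s[, 4],
    conf.low = ci[, 1],
    conf.high = ci[, 2]
  )
}

#' Model-level summary of a growth-model fit
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return One-row tibble: `model_id`, `r.squared`, `adj.r.squared`,
#'   `sigma`, `p.value` (slope; `NA` for the null model), `aic`,
#'   `dw.statistic`, `dw.p.value`, `nobs`.
#' @exportS3Method generics::glance
glance.growth_fit <- function(x, ...) {
  s <- summary(x$lm)
  p_beta <- if ("predictor" %in% rownames(s$coefficients)) {
    s$coefficients["predictor", 4]
  } else {
    NA_real_
  }
  tibble::tibble(
    model_id = x$model_id,
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    p.value = p_beta,
    aic = AIC(x$lm),
    dw.statistic = x$dw_statistic,
    dw.p.value = x$dw_p_value,
    nobs = x$n_obs
  )
}

#' Observation-level values of a growth-model fit
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return The fitting data with `.fitted` and `.resid` columns.
#' @exportS3Method generics::augment
augment.growth_fit <- function(x, ...) {
  out <- x$data
  out$.fitted <- unname(fitted(x$lm))
  out$.resid <- unname(residuals(x$lm))
  out
}

#' @export
coef.growth_fit <- function(object, ...) coef(object$lm)

#' @export
residuals.growth_fit <- function(object, ...) residuals(object$lm)

# slope estimate and 95% CI, used by project_density()
slope_estimate <- function(fit, conf.level = 0.95) {
  stopifnot(inherits(fit, "growth_fit"))
  if (!"predictor" %in% names(coef(fit$lm))) {
    abort("The fit has no predictor term (null model); no slope to extract.")
  }
  ci <- confint(fit$lm, "predictor", level = conf.level)
  list(beta = unname(coef(fit$lm)[["predictor"]]),
       ci = c(ci[1, 1], ci[1, 2]))
}
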
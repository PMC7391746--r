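# climepop

Can summer warming explain the collapse of an annual wildlife monitoring
series? `climepop` packages the full analysis chain for that question,
built around the decline of red dragonflies (*Sympetrum frequens* and
*S. infuscatum*) monitored in Japanese prefectures: a summer-temperature
index computed from ~1-km² gridded daily data, decadal trend statistics,
growth-rate regressions with model comparison, temperature-only population
projections, and thermal habitat-area thresholding. A seeded
synthetic-data generator emulates both the gridded temperatures and
model-conformant population series, so every stage is testable end to end
with known parameters and no external downloads.

It is aimed at quantitative ecologists who have an annual abundance index
and gridded daily weather and want a defensible answer to "was it the
heat?".

## The model

**Temperature index.** For prefecture-like region *i* and year *t*, each
grid cell's 90th percentile of daily mean temperature over July 1 –
August 31 is computed, then averaged (unweighted) across cells:
*TEMP*. A centred 5-year moving average *TEMP^MA* smooths interannual
noise. Decadal change is summarised as

- *DIFF* = *TEMP^MA*(end) − *TEMP^MA*(start)  (°C)
- *RATE* = 100 · *DIFF* / *TEMP^MA*(start)  (%)
- *STDIFF* = *DIFF* / *SD*, where *SD* is the standard deviation of the
  *annual* index over the decade. |*STDIFF*| < 1 means the decadal shift
  lies within ordinary year-to-year fluctuation.

**Growth models.** With density index *N_t* (individuals/h) and
λ_t = ln *N_t* − ln *N_{t−1}*, ordinary least squares fits

- Model 1: λ_t = α + β ΔTEMP_t + ε_t (same-year heat stress),
- Model 2: λ_t = α + β ΔTEMP_{t−1} + ε_t (previous-year diapause
  disturbance),
- null: λ_t = α + ε_t,

where ΔTEMP_t = TEMP_t − TEMP_{t−1}, over a configurable window
(default 1993–2004). Fits report β with 95% CI, R², Gaussian AIC (error
variance counted as a parameter), and the Durbin–Watson statistic with
its small-sample p-value to check the independent-errors assumption.

**Projection.** Setting α = ε = 0, the temperature-only trajectory is
N_t / N_base = exp(β · (TEMP_t − TEMP_base)), with a band from the 95%
CI of β. Because the recursion telescopes, a path whose excursion from
the base year stays within ±2 °C can never push density below
exp(−0.464) ≈ 0.63 at β = −0.232 — which is how the method shows
mechanically that warming alone cannot produce a ~97% collapse.

**Habitat area.** SHA(threshold) is the total area of cells whose
July–August mean does not exceed the threshold (inclusive), swept over
21–25 °C around the 23 °C hypothesis.

## Worked example

```r
library(climepop)

sc   <- temperature_scenario(n_cells = 9, years = 1986:2006)
grid <- simulate_temperature_grid(sc, seed = 1)
idx  <- temp_index(grid) |> moving_average()

decadal_indices(idx, decade = "1990s")
#>   decade start_year end_year diff_c rate_pct  sd_c stdiff within_fluctuation
#> 1 1990s        1990     1999  0.436     1.76 0.870  0.502 TRUE
```

The synthetic 1990s warmed by 0.44 °C (1.8%), but the standardized
difference 0.50 is well under 1: the decadal change sits inside
interannual fluctuation, as in the monitored prefectures.

```r
pop <- simulate_population(idx, alpha = 0.1, beta = -0.232,
                           sigma_eps = 0.3, seed = 101)
gr  <- growth_rates(pop[, c("year", "density")])
f1  <- fit_growth_model(gr, idx, model = "model1")
f1
#> Growth-rate regression (model1)
#>   window: 1993-2004, n = 12
#>   beta = -0.2347 (95% CI -0.3706 to -0.0988), p = 0.003223
#>   R^2 = 0.597, AIC = 7.57, Durbin-Watson = 1.582 (p = 0.302)
```

The fitted slope recovers the generating β = −0.232 within its CI, and
the Durbin–Watson statistic near 2 supports independent errors.

```r
f2 <- fit_growth_model(gr, idx, model = "model2")
f0 <- fit_growth_model(gr, idx, model = "null")
compare_models(f1, f2, f0)
#>   model_id n_obs r_squared   aic delta_aic delta_aic_null
#> 1 model1      12     0.597  7.57      0             -8.90
#> 2 model2      12     0.392 12.5       4.93          -3.97
#> 3 null        12     0     16.5       8.90           0
```

Same-year temperature change (model 1) carries the information — it was
the generating model. Feeding the fit into the projection:

```r
project_density(idx, f1, base_year = 1993) |> tail(3)
#>    year relative_density band_lo band_hi
#> 1  2004            1.19    1.08    1.32
#> 2  2005            1.00    1.00    1.00
#> 3  2006            0.937   0.903   0.973
```

Relative density wanders around 1 because the temperature path wanders
around its base value — a temperature path bounded within ±2 °C cannot
generate an order-of-magnitude decline at this β. `tidy()`, `glance()`,
`augment()` and `autoplot()` work on every fit; `run_pipeline()` executes
the whole chain from a YAML or list configuration and writes the CSV
bundle plus a run log.

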
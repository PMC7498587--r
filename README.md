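# chltrends

Regional trend estimation for satellite-style ocean chlorophyll records with
a hierarchical Bayesian spatio-temporal model and climate-model-ensemble
priors.

Detecting trends in ocean colour chlorophyll-a is hard: the satellite record
is short (~20 years) relative to natural variability, and chlorophyll is
strongly correlated in space and autocorrelated in time, so naive per-pixel
regressions badly overstate confidence. `chltrends` addresses this for
analysts of gridded monthly chlorophyll fields by (i) modelling each region's
log-chlorophyll field jointly across space and time, "borrowing strength"
between neighbouring cells, and (ii) letting an ensemble of coupled
climate-model simulations supply an informative prior on the trend — a
"first guess" that the observations then update.

## Model

Within a region, observed log-chlorophyll at cell *n* and month *t* is

```
Z[n,t] = O[n,t] + eps[n,t],                 eps ~ N(0, sigma2_eps)      (data level)
O[n,t] = x[t]' beta + w[n,t]                                            (process level)
w[t]   = rho * w[t-1] + eta[t],             eta ~ N(0, sigma2_w * S)
S[ij]  = exp(-d[ij] / lambda)                                           (exponential spatial correlation)
```

with covariates `x[t] = (1, t_centred, cos(2*pi*(month - peak)/12))`: an
intercept, the time trend, and an annual harmonic whose phase is fixed
beforehand so the cycle peaks in the region's climatological peak month. The
spatial decay `lambda` defaults to 500 km, making correlation ~0.05 by
1,500 km. The trend coefficient `beta_trend` carries a normal prior — either
vague, N(0, 100), or built from a multi-model ensemble: per model run, a
GLS-AR(1) regression of the regional mean series; ensemble members averaged
within each model; the across-model mean and sample variance become the
prior. Each region is fitted independently by a Gibbs sampler
(forward-filtering backward-sampling for `w` in the eigenbasis of `S`, a
collapsed conjugate update for `beta` with `w` integrated out, inverse-gamma
variance updates, griddy-Gibbs for `rho`, and within-sweep imputation of
missing cells).

Trends are summarised by the kernel-density mode and 95% highest density
interval (HDI) of the posterior, converted to percent per year of
un-transformed chlorophyll via `pct = (exp(12*beta) - 1) * 100`; a trend is
significant when its HDI excludes zero. Regional modes combine into a global
trend weighted by mean chlorophyll times areal extent.

The package also ships a seeded synthetic-data generator producing gridded
fields (trend + annual cycle + spatially correlated AR(1) process + nugget,
with random missingness) and multi-model ensemble series with known ground
truth, used throughout the test suite for oracle and recovery checks.

## Worked example

```r
library(chltrends)

# synthetic study: two regions on an 8x8 one-degree grid, 120 months,
# true trends +1.5 and -1.0 % per year
mask  <- generate_region_layout(n_regions = 2, grid_shape = c(8, 8), seed = 1)
truth <- simulation_truth(region_trends = c(`1` = 1.5, `2` = -1.0), seed = 3)
field <- simulate_chl_field(truth, mask, n_months = 120)

# a 14-model ensemble (24 runs) over a 240-month prior period
runs   <- simulate_climate_ensemble(truth, n_models = 14,
            ensembles_per_model = c(1,1,1,1,1,1,3,4,4,1,1,3,1,1),
            n_months = 240, seed = 4)
priors <- build_region_priors(runs)
priors[["1"]]
#> <trend_prior> N(mean = 1.4013, var = 0.16375) [percent_per_year, ensemble, 14 models]

# fit region 1 under the vague and the ensemble prior
fit_v <- fit_st_model(field, mask, "1",
           config = st_config(n_iterations = 3000, n_burnin = 600, seed = 7))
fit_e <- fit_st_model(field, mask, "1",
           config = st_config(n_iterations = 3000, n_burnin = 600, seed = 7,
                              trend_prior = priors[["1"]]))
ests <- dplyr::bind_rows(summarize_trend(fit_v), summarize_trend(fit_e))
ests[, 1:6]
#>   region_id    prior mode_pct_yr hdi_low_pct_yr hdi_high_pct_yr hdi_width_pct_yr
#> 1         1    vague        1.52           0.37            2.55             2.18
#> 2         1 ensemble        1.45           0.82            2.08             1.25
scenarios_differ(ests[1, ], ests[2, ])
#> [1] FALSE
```

Both fits recover the true +1.5 % yr⁻¹ trend (the mode is the point
estimate; the HDI width is the reported uncertainty). The ensemble prior,
centred near the truth with variance 0.16, roughly halves the uncertainty
without materially moving the mode, and the two scenarios' HDIs overlap — the
estimates are not statistically different. `run_pipeline()` chains all of the
above (plus global weighting and an optional prior-sensitivity scan) from a
single config, writing CSV tables and a run manifest; `autoplot()` and
`plot_trend_estimates()` give standard posterior-density and forest plots.

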
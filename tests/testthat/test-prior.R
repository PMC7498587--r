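test_that("GLS-AR(1) recovers a noise-free line and reduces to OLS at rho 0", {
  t0 <- 0:59
  y <- 2 + 0.003 * t0
  fit <- fit_gls_ar1_trend(y, include_seasonal = FALSE)
  expect_equal(fit$slope, 0.003, tolerance = 1e-12)

  set.seed(42)
  y2 <- 1 + 0.002 * t0 + rnorm(60, sd = 0.1)
  ols <- unname(coef(lm(y2 ~ I(t0 - mean(t0))))[2])
  fixed0 <- fit_gls_ar1_trend(y2, include_seasonal = FALSE, rho = 0)
  expect_equal(fixed0$slope, ols, tolerance = 1e-12)
})

test_that("iterated GLS matches the dense AR(1)-covariance oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- c(30, 40, 50)[(seed %% 3) + 1]
    t0 <- 0:(n - 1)
    u <- as.numeric(arima.sim(list(ar = 0.5), n, sd = 0.1))
    y <- 0.5 + 0.004 * t0 + u
    fit <- fit_gls_ar1_trend(y, include_seasonal = FALSE)
    X <- cbind(1, t0 - mean(t0))
    oracle <- gls_dense_ar1(y, X, fit$rho)[2]
    expect_equal(fit$slope, oracle, tolerance = 1e-8)
  }
})

test_that("GLS slope is consistent with likelihood-based AR(1) regression", {
  set.seed(7)
  n <- 120
  t0 <- 0:(n - 1)
  y <- 1 + 0.003 * t0 + as.numeric(arima.sim(list(ar = 0.6), n, sd = 0.08))
  fit <- fit_gls_ar1_trend(y, include_seasonal = FALSE)
  g <- nlme::gls(y ~ tc, data = data.frame(y = y, tc = t0 - mean(t0)),
                 correlation = nlme::corAR1(form = ~1))
  # different estimators of rho, so slopes agree only statistically
  expect_equal(fit$slope, unname(coef(g)[2]), tolerance = 0.05)
})

test_that("ensemble averaging weights models, not members", {
  runs <- tibble::tibble(
    model_id = c("A", "A", "B"), ensemble_id = c("e1", "e2", "e1"),
    slope = c(1, 3, 2)
  )
  avg <- average_ensembles(runs)
  expect_equal(avg$slope[avg$model_id == "A"], 2)
  expect_equal(avg$slope[avg$model_id == "B"], 2)

  single <- tibble::tibble(model_id = "C", ensemble_id = "e1", slope = 5)
  expect_equal(average_ensembles(single)$slope, 5)

  # row order of members must not matter
  shuffled <- runs[c(3, 1, 2), ]
  expect_equal(dplyr::arrange(average_ensembles(shuffled), model_id),
               dplyr::arrange(avg, model_id))

  expect_error(average_ensembles(runs[0, ]), "non-empty")
})

test_that("multi-model prior is the across-model mean and sample variance", {
  p <- build_multimodel_prior(c(1, 2, 3))
  expect_equal(p$mean, 2)
  expect_equal(p$variance, 1)
  expect_equal(p$provenance, "ensemble")
  expect_equal(p$n_models, 3L)

  p2 <- build_multimodel_prior(c(-1, 1))
  expect_equal(p2$mean, 0)
  expect_equal(p2$variance, 2)

  expect_warning(pd <- build_multimodel_prior(c(2, 2, 2)), "floored")
  expect_equal(pd$variance, 1e-6)

  expect_error(build_multimodel_prior(3), "fewer than 2")
})

test_that("the vague prior is flat over plausible trends and round-trips", {
  v <- vague_prior()
  expect_equal(v$mean, 0)
  expect_equal(v$variance, 100)
  expect_equal(v$provenance, "vague")

  # N(0, 100) density varies by exp(-4/200) ~ 2% across +/-2 % yr^-1:
  # flat relative to any realistic likelihood
  dens <- dnorm(seq(-2, 2, length.out = 101), 0, sqrt(v$variance))
  expect_gt(min(dens) / max(dens), 0.98)

  back <- convert_prior_units(convert_prior_units(v, "log_per_month"),
                              "percent_per_year")
  expect_equal(back$mean, v$mean, tolerance = 1e-12)
  expect_equal(back$variance, v$variance, tolerance = 1e-12)
})

test_that("prior unit conversion uses the delta method at the mean", {
  p <- trend_prior(0, 100, "percent_per_year", "vague")
  q <- convert_prior_units(p, "log_per_month")
  expect_equal(q$mean, 0)
  expect_equal(q$variance, 100 / 1440000, tolerance = 1e-12)

  p1 <- trend_prior(1, 0.5, "percent_per_year", "ensemble", n_models = 5)
  q1 <- convert_prior_units(p1, "log_per_month")
  expect_equal(q1$mean, log(1.01) / 12, tolerance = 1e-12)
  rt <- convert_prior_units(q1, "percent_per_year")
  expect_equal(rt$mean, 1, tolerance = 1e-12)
  expect_equal(rt$variance, 0.5, tolerance = 1e-12)
  expect_equal(rt$n_models, 5L)
})

test_that("built priors recover the generating trend and model spread", {
  truth <- simulation_truth(c(`1` = 1), seed = 21)
  runs <- simulate_climate_ensemble(truth, n_models = 50,
                                    ensembles_per_model = 1, n_months = 240,
                                    model_trend_sd = 0.5, series_sd = 0.02,
                                    seed = 22)
  prior <- build_region_priors(runs)[["1"]]
  se_mean <- 0.5 / sqrt(50)
  expect_lt(abs(prior$mean - 1), 3 * se_mean)
  se_var <- 0.5^2 * sqrt(2 / 49)
  expect_lt(abs(prior$variance - 0.25), 3 * se_var)
  expect_equal(prior$n_models, 50L)
})
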
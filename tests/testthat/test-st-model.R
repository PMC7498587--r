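test_that("spatial correlation is exponential in distance", {
  expect_equal(spatial_correlation(0, 500), 1)
  expect_equal(spatial_correlation(1500, 500), exp(-3), tolerance = 1e-12)
  d <- seq(0, 3000, by = 100)
  expect_true(all(diff(spatial_correlation(d, 500)) < 0))
})

test_that("design matrix anchors the seasonal phase to the calendar", {
  d <- demo_region()
  des <- build_design(d$field, d$mask, "1", peak_month = 1)
  # record starts in January; peak month January -> seasonal 1 at t = 1, 13, ...
  expect_equal(des$seasonal[des$t %in% c(1, 13, 25)], rep(1, 3))
  expect_lt(abs(sum(des$time_c)), 1e-9)

  # same peak calendar month, different start month: seasonal values agree
  # wherever the calendar months match
  f2 <- simulate_chl_field(d$truth, d$mask, 120, start = c(2000L, 7L))
  des2 <- build_design(f2, d$mask, "1", peak_month = 3)
  des1 <- build_design(d$field, d$mask, "1", peak_month = 3)
  j <- dplyr::inner_join(des1, des2, by = c("year", "month"))
  expect_equal(j$seasonal.x, j$seasonal.y, tolerance = 1e-12)

  expect_error(build_design(d$field, d$mask, "zzz"), "unknown region")
})

test_that("with the process disabled the sampler matches the conjugate form", {
  mask <- generate_region_layout(1, c(4, 4), seed = 31)
  truth <- simulation_truth(c(`1` = 1), process_sd = 0, nugget_sd = 0.1,
                            missing_fraction = 0, seed = 31)
  fld <- simulate_chl_field(truth, mask, 48)
  cfg <- st_config(n_iterations = 2000, n_burnin = 200, seed = 32,
                   process = "off", fixed_nugget_variance = 0.01)
  fit <- fit_st_model(fld, mask, "1", config = cfg)

  des <- build_design(fld, mask, "1")
  Xt <- as.matrix(des[, c("intercept", "time_c", "seasonal")])
  X <- Xt[rep(seq_len(nrow(Xt)), each = 16), ]
  y <- dplyr::arrange(fld, t, lat, lon)$log_chl
  tp <- convert_prior_units(cfg$trend_prior, "log_per_month")
  prior_prec <- diag(c(1e-4, 1 / tp$variance, 1e-4))
  oracle <- conjugate_posterior(X, y, 0.01, c(0, tp$mean, 0), prior_prec)

  draws <- as.matrix(fit$draws[, 1:3])
  mc_se <- apply(draws, 2, sd) / sqrt(nrow(draws))
  expect_true(all(abs(colMeans(draws) - oracle$mean) < 3 * mc_se))
  # covariance, every entry (conjugate-limit equivalence for all covariates)
  C <- cov(draws)
  n <- nrow(draws)
  for (j in 1:3) for (k in 1:3) {
    se_jk <- sqrt((C[j, j] * C[k, k] + C[j, k]^2) / n)
    expect_lt(abs(C[j, k] - oracle$cov[j, k]), 4 * se_jk + 1e-12)
  }
})

test_that("marginalised coefficient update matches dense-covariance algebra", {
  # the collapsed beta step sums, per spatial eigencomponent, the GLS
  # sufficient statistics under Sigma_k = sig2e I + sig2w lam_k C(rho);
  # verify the tridiagonal route against dense matrix inversion
  set.seed(99)
  T_ <- 30; N <- 5
  X <- cbind(1, scale(1:T_, scale = FALSE), cos(2 * pi * (1:T_) / 12))
  Ytil <- matrix(rnorm(N * T_), N, T_)
  lam <- sort(runif(N, 0.1, 3), decreasing = TRUE)
  cvec <- rnorm(N)
  rho <- 0.55; s2w <- 0.3; s2e <- 0.8
  ss <- chltrends:::beta_marg_suffstats(X, Ytil, lam, cvec, rho, s2w, s2e)
  Ad <- matrix(0, 3, 3); bd <- numeric(3)
  Cmat <- rho^abs(outer(1:T_, 1:T_, `-`)) / (1 - rho^2)
  for (k in 1:N) {
    Si <- solve(s2e * diag(T_) + s2w * lam[k] * Cmat)
    Ad <- Ad + cvec[k]^2 * t(X) %*% Si %*% X
    bd <- bd + cvec[k] * t(X) %*% Si %*% Ytil[k, ]
  }
  expect_equal(ss$A, Ad, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(as.vector(ss$b), as.vector(bd), tolerance = 1e-10)
})

test_that("a near-degenerate trend prior pins the posterior at its mean", {
  mask <- generate_region_layout(1, c(4, 4), seed = 33)
  truth <- simulation_truth(c(`1` = 1.5), process_sd = 0.05,
                            nugget_sd = 0.05, missing_fraction = 0,
                            seed = 33)
  fld <- simulate_chl_field(truth, mask, 48)
  mu0 <- 0.001
  cfg <- st_config(n_iterations = 1000, n_burnin = 200, seed = 34,
                   trend_prior = trend_prior(mu0, 1e-10,
                                             unit_scale = "log_per_month",
                                             provenance = "ensemble",
                                             n_models = 2))
  fit <- fit_st_model(fld, mask, "1", config = cfg)
  expect_lt(abs(posterior_mode(fit$draws$beta_trend) - mu0), 1e-4)
})

test_that("chains are bit-reproducible given data, config and seed", {
  d <- demo_region()
  cfg <- st_config(n_iterations = 1000, n_burnin = 100, seed = 35)
  f1 <- fit_st_model(d$field, d$mask, "1", config = cfg)
  f2 <- fit_st_model(d$field, d$mask, "1", config = cfg)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_st_model(d$field, d$mask, "1",
                     config = st_config(n_iterations = 1000, n_burnin = 100,
                                        seed = 36))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("the sampler recovers generating parameters on synthetic data", {
  d <- demo_region()
  cfg <- st_config(n_iterations = 2000, n_burnin = 400, seed = 37)
  fit <- fit_st_model(d$field, d$mask, "1", config = cfg)
  est <- summarize_trend(fit)
  expect_gt(est$hdi_high_pct_yr, est$hdi_low_pct_yr)
  # true trend 1.2% per year within (a slightly widened) HDI
  expect_gt(1.2, est$hdi_low_pct_yr - 0.5)
  expect_lt(1.2, est$hdi_high_pct_yr + 0.5)
  # seasonal amplitude and autocorrelation land near truth
  td <- tidy(fit)
  expect_lt(abs(td$estimate[td$term == "beta_seasonal"] - 0.08), 0.06)
  expect_lt(abs(td$estimate[td$term == "rho"] - 0.5), 0.25)
  # trend significance mirrors the HDI rule
  expect_identical(est$significant,
                   is_significant(c(est$hdi_low_pct_yr, est$hdi_high_pct_yr)))
})

test_that("missing observations are imputed rather than dropped", {
  mask <- generate_region_layout(1, c(4, 4), seed = 38)
  truth <- simulation_truth(c(`1` = 1), missing_fraction = 0.3, seed = 38)
  fld <- simulate_chl_field(truth, mask, 48)
  cfg <- st_config(n_iterations = 1000, n_burnin = 200, seed = 39)
  fit <- fit_st_model(fld, mask, "1", config = cfg)
  expect_equal(nrow(fit$draws), 1000)
  expect_true(all(fit$draws$sigma2_nugget > 0))
  expect_true(all(abs(fit$draws$rho) < 1))
})
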
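test_that("region layouts partition the grid into contiguous regions", {
  one <- generate_region_layout(1, c(4, 4), seed = 1)
  expect_equal(nrow(one), 16)
  expect_true(all(one$region_id == "1"))

  m1 <- generate_region_layout(4, c(8, 8), seed = 1)
  m2 <- generate_region_layout(4, c(8, 8), seed = 1)
  expect_identical(m1, m2)

  expect_equal(nrow(m1), 64)
  expect_false(anyNA(m1$region_id))
  expect_setequal(unique(m1$region_id), as.character(1:4))

  # contiguity: each region's cells form one 4-connected component
  for (r in unique(m1$region_id)) {
    cells <- m1[m1$region_id == r, c("lat", "lon")]
    visited <- 1L
    frontier <- 1L
    repeat {
      nb <- which(vapply(seq_len(nrow(cells)), function(i) {
        any(abs(cells$lat[i] - cells$lat[frontier]) +
              abs(cells$lon[i] - cells$lon[frontier]) == 1)
      }, logical(1)))
      nxt <- setdiff(nb, visited)
      if (length(nxt) == 0) break
      visited <- c(visited, nxt)
      frontier <- nxt
    }
    expect_equal(length(visited), nrow(cells))
  }

  expect_error(generate_region_layout(65, c(8, 8)), "exceeds")
})

test_that("noise-free field equals the deterministic mean surface", {
  mask <- generate_region_layout(2, c(4, 4), seed = 2)
  truth <- simulation_truth(c(`1` = 1.5, `2` = -1), process_sd = 0,
                            nugget_sd = 0, missing_fraction = 0, seed = 5)
  fld <- simulate_chl_field(truth, mask, 36, start = c(2000L, 1L))
  beta <- from_percent_per_year(truth$region_trends)
  expected <- with(dplyr::inner_join(fld, mask[, c("lat", "lon", "region_id")],
                                     by = c("lat", "lon")), {
    truth$intercepts[region_id] + beta[region_id] * (t - 1) +
      truth$seasonal_amplitudes[region_id] *
        cos(2 * pi * (month - truth$seasonal_peak_months[region_id]) / 12)
  })
  expect_equal(fld$log_chl, unname(expected), tolerance = 1e-12)
})

test_that("simulated process recovers its AR(1) autocorrelation", {
  mask <- generate_region_layout(1, c(8, 8), seed = 3)
  truth <- simulation_truth(c(`1` = 0), seasonal_amplitudes = c(`1` = 0),
                            ar1_rho = 0.6, process_sd = 0.3, nugget_sd = 0,
                            missing_fraction = 0, seed = 7)
  fld <- simulate_chl_field(truth, mask, 100) # 6400 cell-months
  # mean surface is constant, so de-mean per cell and pool lag-1 products
  Z <- matrix(fld$log_chl, nrow = 64)
  Z <- Z - rowMeans(Z)
  rho_hat <- sum(Z[, -1] * Z[, -100]) / sum(Z[, -100]^2)
  expect_lt(abs(rho_hat - 0.6), 0.1)
})

test_that("spatial correlation of the field decays with distance", {
  mask <- generate_region_layout(1, c(10, 10), seed = 4)
  truth <- simulation_truth(c(`1` = 0), seasonal_amplitudes = c(`1` = 0),
                            spatial_decay_km = 200, ar1_rho = 0.3,
                            process_sd = 0.3, nugget_sd = 0,
                            missing_fraction = 0, seed = 8)
  fld <- simulate_chl_field(truth, mask, 120)
  Z <- matrix(fld$log_chl, nrow = 100)
  Z <- Z - rowMeans(Z)
  C <- cor(t(Z))
  D <- chltrends:::distance_matrix_km(dplyr::arrange(mask, lat, lon))
  near <- D > 0 & D < 200
  far <- D >= 600 # 3 e-folding lengths
  expect_gt(mean(C[near]), mean(C[far]))
  expect_lt(abs(mean(C[far])), 0.15)
})

test_that("climate ensemble layout, degenerate limit and determinism", {
  truth <- simulation_truth(c(`1` = 0.8), seed = 1)
  counts <- c(1, 1, 1, 1, 1, 1, 3, 4, 4, 1, 1, 3, 1, 1)
  runs <- simulate_climate_ensemble(truth, n_models = 14,
                                    ensembles_per_model = counts,
                                    n_months = 60, model_trend_sd = 0.3,
                                    seed = 2)
  n_runs <- dplyr::n_distinct(paste(runs$model_id, runs$ensemble_id))
  expect_equal(n_runs, 24)
  expect_equal(dplyr::n_distinct(runs$model_id), 14)

  # no model spread, no noise: every run's GLS trend is the true trend
  exact <- simulate_climate_ensemble(truth, n_models = 3,
                                     ensembles_per_model = 1, n_months = 60,
                                     model_trend_sd = 0, series_sd = 0,
                                     seed = 3)
  slopes <- exact |>
    dplyr::group_by(model_id, ensemble_id) |>
    dplyr::group_map(~ fit_gls_ar1_trend(.x)$slope)
  expect_equal(unlist(slopes),
               rep(from_percent_per_year(0.8), 3), tolerance = 1e-9)

  again <- simulate_climate_ensemble(truth, n_models = 14,
                                     ensembles_per_model = counts,
                                     n_months = 60, model_trend_sd = 0.3,
                                     seed = 2)
  expect_identical(runs, again)
})

test_that("field generation is deterministic and respects missingness", {
  mask <- generate_region_layout(2, c(6, 6), seed = 5)
  truth <- simulation_truth(c(`1` = 1, `2` = -1), missing_fraction = 0.2,
                            seed = 9)
  f1 <- simulate_chl_field(truth, mask, 48)
  f2 <- simulate_chl_field(truth, mask, 48)
  expect_identical(f1$log_chl, f2$log_chl)
  n_vals <- length(f1$log_chl)
  expect_equal(sum(is.na(f1$log_chl)), floor(0.2 * n_vals))
  expect_true(all(is.finite(f1$log_chl[!is.na(f1$log_chl)])))
})

test_that("truth validation rejects out-of-range parameters", {
  expect_error(simulation_truth(c(`1` = 0), ar1_rho = 1))
  expect_error(simulation_truth(c(`1` = 0), missing_fraction = 1))
  expect_error(simulation_truth(c(`1` = 0), process_sd = -1))
  expect_error(simulation_truth(c(`1` = 0), seasonal_peak_months = 13))
})
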
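# Independent oracles used across the suite.

# Dense-matrix GLS under the explicit AR(1) correlation matrix rho^|i-j|
# (the stationary scale factor cancels in the estimator).
gls_dense_ar1 <- function(y, X, rho) {
  n <- length(y)
  Sig <- rho^abs(outer(seq_len(n), seq_len(n), `-`))
  Si <- solve(Sig)
  solve(t(X) %*% Si %*% X, t(X) %*% Si %*% y)[, 1]
}

# Closed-form conjugate Bayesian linear regression posterior: y ~ N(Xb, s2 I),
# b ~ N(m0, solve(P0)). Returns mean and covariance.
conjugate_posterior <- function(X, y, sigma2, prior_mean, prior_prec) {
  A <- crossprod(X) / sigma2 + prior_prec
  b <- crossprod(X, y) / sigma2 + prior_prec %*% prior_mean
  V <- solve(A)
  list(mean = as.vector(V %*% b), cov = V)
}

# Small two-region mask with hand-set areas for weighting examples.
tiny_mask <- function(areas = c(1, 1), lat = c(0.5, 1.5)) {
  out <- tibble::tibble(
    lat = lat, lon = rep(0.5, length(lat)),
    region_id = as.character(seq_along(lat)),
    area_km2 = areas
  )
  class(out) <- c("region_mask", class(out))
  attr(out, "cell_size") <- 1
  out
}

# Deterministic chl_field from an explicit cells x months matrix.
field_from_matrix <- function(Z, lat, lon, start = c(2000L, 1L),
                              cell_size = 1) {
  n_cells <- length(lat)
  n_months <- ncol(Z)
  tt <- rep(seq_len(n_months), each = n_cells)
  k <- (start[2] - 1) + (tt - 1)
  df <- tibble::tibble(
    lat = rep(lat, times = n_months), lon = rep(lon, times = n_months),
    year = start[1] + k %/% 12, month = (k %% 12) + 1,
    t = tt, log_chl = as.vector(Z)
  )
  chltrends:::new_chl_field(df, start = start, n_months = n_months,
                            cell_size = cell_size)
}

# One-region demo data shared by the model tests (computed once per run).
demo_cache <- new.env()
demo_region <- function() {
  if (is.null(demo_cache$field)) {
    demo_cache$mask <- generate_region_layout(1, c(8, 8), seed = 11)
    demo_cache$truth <- simulation_truth(c(`1` = 1.2), ar1_rho = 0.5,
                                         process_sd = 0.08, nugget_sd = 0.08,
                                         missing_fraction = 0.05, seed = 11)
    demo_cache$field <- simulate_chl_field(demo_cache$truth, demo_cache$mask,
                                           n_months = 120)
  }
  demo_cache
}
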
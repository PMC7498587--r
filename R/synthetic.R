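# Synthetic-data generator: seeded observations and climate-ensemble series
# with the statistical structure the analysis assumes (linear trend + annual
# harmonic + spatially correlated AR(1) process + white nugget), carrying
# ground truth for recovery tests.

#' Ground truth for a synthetic study
#'
#' Bundles the per-region generative parameters used by
#' [simulate_chl_field()] and [simulate_climate_ensemble()]: true trends
#' (% year^-1), mean log-chl intercepts, seasonal amplitude and peak month,
#' plus the shared spatial/temporal noise structure.
#'
#' @param region_trends Named numeric vector, region id -> trend in % year^-1.
#' @param intercepts Named numeric, region id -> mean log-chl (log mg m^-3).
#'   Default -0.5 everywhere (~0.6 mg m^-3).
#' @param seasonal_amplitudes Named numeric, log units. Default 0.15.
#' @param seasonal_peak_months Named integer in 1..12. Default 3 (a spring
#'   bloom).
#' @param spatial_decay_km e-folding length of the exponential spatial
#'   correlation; default 500 km, making correlation ~0.05 by 1500 km.
#' @param ar1_rho Temporal autocorrelation of the process, strictly in (-1, 1).
#' @param process_sd Innovation s.d. of the spatial process (log units).
#' @param nugget_sd Measurement-error s.d. (log units).
#' @param missing_fraction Fraction of cell-months masked at random, in [0, 1).
#' @param seed Integer seed.
#' @return A `simulation_truth` list.
#' @export
simulation_truth <- function(region_trends,
                             intercepts = NULL,
                             seasonal_amplitudes = NULL,
                             seasonal_peak_months = NULL,
                             spatial_decay_km = 500,
                             ar1_rho = 0.6,
                             process_sd = 0.1,
                             nugget_sd = 0.1,
                             missing_fraction = 0.1,
                             seed = 1L) {
  ids <- names(region_trends)
  if (is.null(ids)) {
    ids <- as.character(seq_along(region_trends))
    names(region_trends) <- ids
  }
  fill <- function(x, default) {
    if (is.null(x)) return(setNames(rep(default, length(ids)), ids))
    if (is.null(names(x)) && length(x) == length(ids)) names(x) <- ids
    stopifnot(all(ids %in% names(x)))
    x[ids]
  }
  truth <- structure(list(
    region_trends = region_trends,
    intercepts = fill(intercepts, -0.5),
    seasonal_amplitudes = fill(seasonal_amplitudes, 0.15),
    seasonal_peak_months = vapply(fill(seasonal_peak_months, 3L),
                                  as.integer, integer(1)),
    spatial_decay_km = spatial_decay_km,
    ar1_rho = ar1_rho,
    process_sd = process_sd,
    nugget_sd = nugget_sd,
    missing_fraction = missing_fraction,
    seed = as.integer(seed)
  ), class = "simulation_truth")
  validate_truth(truth)
  truth
}

validate_truth <- function(truth) {
  stopifnot(
    abs(truth$ar1_rho) < 1,
    truth$process_sd >= 0, truth$nugget_sd >= 0,
    truth$missing_fraction >= 0, truth$missing_fraction < 1,
    truth$spatial_decay_km > 0,
    all(truth$seasonal_peak_months %in% 1:12)
  )
  invisible(truth)
}

new_chl_field <- function(df, start, n_months, cell_size) {
  out <- tibble::as_tibble(df)
  attr(out, "start") <- as.integer(start)
  attr(out, "n_months") <- as.integer(n_months)
  attr(out, "cell_size") <- cell_size
  class(out) <- c("chl_field", class(out))
  out
}

# calendar (year, month) for month indices t = 1..n starting at `start`
calendar_of <- function(t, start) {
  k <- (start[2] - 1) + (t - 1)
  list(year = start[1] + k %/% 12, month = (k %% 12) + 1)
}

#' Generate a contiguous random partition of a grid into regions
#'
#' A stand-in for biogeochemical-province masks: seeds `n_regions` cells at
#' random and grows them by breadth-first search over the 4-neighbourhood
#' until the grid is exhausted, so every region is spatially contiguous and
#' the regions partition the grid. Cell areas follow the spherical-zone
#' formula at each cell's latitude.
#'
#' @param n_regions Number of regions (<= number of cells).
#' @param grid_shape Integer `c(rows, cols)` = (latitudes, longitudes).
#' @param seed Integer seed; the layout is deterministic given the seed.
#' @param lat_centers,lon_centers Optional cell-centre coordinates; default a
#'   1-degree grid straddling the equator at half-degree centres.
#' @param cell_size Cell size in degrees (default 1).
#' @return A `region_mask` tibble with columns `lat`, `lon`, `region_id`
#'   (character), `area_km2`, and attributes `region_ids`, `grid_shape`,
#'   `cell_size`.
#' @export
generate_region_layout <- function(n_regions, grid_shape, seed = 1L,
                                   lat_centers = NULL, lon_centers = NULL,
                                   cell_size = 1) {
  rows <- grid_shape[1]; cols <- grid_shape[2]
  if (n_regions > rows * cols) {
    stop("n_regions exceeds the number of grid cells", call. = FALSE)
  }
  stopifnot(n_regions >= 1)
  if (is.null(lat_centers)) {
    lat_centers <- (seq_len(rows) - (rows + 1) / 2) * cell_size
  }
  if (is.null(lon_centers)) {
    lon_centers <- (seq_len(cols) - 1 / 2) * cell_size
  }
  stopifnot(length(lat_centers) == rows, length(lon_centers) == cols)

  assign <- matrix(NA_integer_, rows, cols)
  set.seed(seed)
  seeds <- sample(rows * cols, n_regions)
  frontiers <- vector("list", n_regions)
  for (r in seq_len(n_regions)) {
    assign[seeds[r]] <- r
    frontiers[[r]] <- seeds[r]
  }
  n_assigned <- n_regions
  total <- rows * cols
  while (n_assigned < total) {
    progressed <- FALSE
    for (r in seq_len(n_regions)) {
      fr <- frontiers[[r]]
      while (length(fr) > 0) {
        cell <- fr[1]
        i <- ((cell - 1) %% rows) + 1
        j <- ((cell - 1) %/% rows) + 1
        nb <- c(
          if (i > 1) cell - 1, if (i < rows) cell + 1,
          if (j > 1) cell - rows, if (j < cols) cell + rows
        )
        nb <- nb[is.na(assign[nb])]
        if (length(nb) > 0) {
          pick <- nb[sample.int(length(nb), 1)]
          assign[pick] <- r
          fr <- c(fr, pick)
          n_assigned <- n_assigned + 1
          progressed <- TRUE
          break
        } else {
          fr <- fr[-1] # interior cell, drop from frontier
        }
      }
      frontiers[[r]] <- fr
      if (n_assigned == total) break
    }
    if (!progressed && n_assigned < total) {
      stop("region growth stalled; grid not connected?", call. = FALSE)
    }
  }

  grid <- tidyr::expand_grid(lon = lon_centers, lat = lat_centers) |>
    dplyr::arrange(.data$lat, .data$lon)
  # assign is rows x cols indexed [lat, lon]
  grid$region_id <- as.character(assign[cbind(
    match(grid$lat, lat_centers), match(grid$lon, lon_centers))])
  grid$area_km2 <- cell_area_km2(grid$lat, cell_size)
  out <- tibble::as_tibble(grid[, c("lat", "lon", "region_id", "area_km2")])
  attr(out, "region_ids") <- as.character(seq_len(n_regions))
  attr(out, "grid_shape") <- as.integer(grid_shape)
  attr(out, "cell_size") <- cell_size
  class(out) <- c("region_mask", class(out))
  out
}

#' Simulate a gridded monthly log-chlorophyll field
#'
#' Generates, per cell and month, `intercept + beta_trend * (t - 1) +
#' amplitude * cos(2 pi (month_of_year - peak) / 12) + w + e`, where
#' `beta_trend` is the region's true trend converted from % year^-1 to
#' log-units per month, `w` is a spatially correlated AR(1) process
#' (`w_t = rho w_{t-1} + eta_t`, `eta ~ N(0, process_sd^2 *
#' exp(-d/spatial_decay_km))`, started from its stationary distribution)
#' and `e` is iid nugget noise. A fraction of cell-months is then masked
#' completely at random. Deterministic given `truth$seed`.
#'
#' @param truth A [simulation_truth()] object.
#' @param mask A `region_mask` from [generate_region_layout()].
#' @param n_months Record length in months (>= 24).
#' @param start Calendar `c(year, month)` of the first record month.
#' @return A `chl_field` tibble with columns `lat`, `lon`, `year`, `month`,
#'   `t`, `log_chl` (NA where masked) and attributes `start`, `n_months`,
#'   `cell_size`, `truth`.
#' @export
simulate_chl_field <- function(truth, mask, n_months, start = c(2000L, 1L)) {
  validate_truth(truth)
  stopifnot(n_months >= 24)
  cells <- dplyr::filter(mask, !is.na(.data$region_id)) |>
    dplyr::arrange(.data$lat, .data$lon)
  n_cells <- nrow(cells)
  missing_ids <- setdiff(unique(cells$region_id), names(truth$region_trends))
  if (length(missing_ids) > 0) {
    stop("truth lacks parameters for region(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }

  D <- distance_matrix_km(cells)
  if (any(D[upper.tri(D)] < 1e-9)) {
    stop("duplicate cell coordinates give a degenerate spatial covariance",
         call. = FALSE)
  }
  S <- exp(-D / truth$spatial_decay_km)

  set.seed(truth$seed)
  tt <- seq_len(n_months)
  cal <- calendar_of(tt, start)
  rid <- cells$region_id
  beta_m <- from_percent_per_year(truth$region_trends)[rid]  # per cell
  icpt <- truth$intercepts[rid]
  amp <- truth$seasonal_amplitudes[rid]
  peak <- truth$seasonal_peak_months[rid]

  # deterministic mean surface, cells x months
  mu <- outer(icpt, rep(1, n_months)) +
    outer(beta_m, tt - 1) +
    amp * cos(2 * pi * outer(peak, cal$month, `-`) / 12)

  W <- matrix(0, n_cells, n_months)
  if (truth$process_sd > 0) {
    L <- t(chol(S))
    rho <- truth$ar1_rho
    W[, 1] <- (truth$process_sd / sqrt(1 - rho^2)) * (L %*% rnorm(n_cells))
    for (t in 2:n_months) {
      W[, t] <- rho * W[, t - 1] + truth$process_sd * (L %*% rnorm(n_cells))
    }
  }
  E <- if (truth$nugget_sd > 0) {
    matrix(rnorm(n_cells * n_months, sd = truth$nugget_sd), n_cells, n_months)
  } else matrix(0, n_cells, n_months)

  Z <- mu + W + E
  if (truth$missing_fraction > 0) {
    n_mask <- floor(truth$missing_fraction * length(Z))
    Z[sample(length(Z), n_mask)] <- NA_real_
  }

  out <- tibble::tibble(
    lat = rep(cells$lat, times = n_months),
    lon = rep(cells$lon, times = n_months),
    t = rep(tt, each = n_cells),
    log_chl = as.vector(Z)
  )
  out$year <- calendar_of(out$t, start)$year
  out$month <- calendar_of(out$t, start)$month
  out <- out[, c("lat", "lon", "year", "month", "t", "log_chl")]
  fld <- new_chl_field(out, start = start, n_months = n_months,
                       cell_size = attr(mask, "cell_size") %||% 1)
  attr(fld, "truth") <- truth
  fld
}

#' Simulate a multi-model climate ensemble of regional chlorophyll series
#'
#' Emulates the structure of a coupled-model archive: each of `n_models`
#' models draws a model-level trend around each region's true trend with
#' spread `model_trend_sd` (% year^-1), and each ensemble member of a model
#' adds AR(1) noise around its model's trend line (intercept and seasonal
#' cycle from the truth). The prior period is typically about twice the
#' observational record.
#'
#' @param truth A [simulation_truth()] object.
#' @param n_models Number of models (>= 2, else the across-model prior
#'   variance is undefined).
#' @param ensembles_per_model Integer vector of ensemble counts, recycled to
#'   `n_models`.
#' @param n_months Series length (>= 24).
#' @param model_trend_sd Across-model trend spread, % year^-1.
#' @param seed Integer seed.
#' @param series_ar1,series_sd AR(1) coefficient and innovation s.d. of the
#'   within-run monthly noise (log units).
#' @param start Calendar `c(year, month)` of the first month.
#' @return A tibble with columns `model_id`, `ensemble_id`, `region_id`,
#'   `year`, `month`, `t`, `log_chl`; one row per run-region-month.
#' @export
simulate_climate_ensemble <- function(truth, n_models, ensembles_per_model,
                                      n_months, model_trend_sd = 0.3,
                                      seed = 1L, series_ar1 = 0.3,
                                      series_sd = 0.05,
                                      start = c(1997L, 9L)) {
  validate_truth(truth)
  if (n_models < 2) {
    stop("need at least 2 models for an across-model prior variance",
         call. = FALSE)
  }
  stopifnot(n_months >= 24)
  n_ens <- rep_len(as.integer(ensembles_per_model), n_models)
  set.seed(seed)
  tt <- seq_len(n_months)
  cal <- calendar_of(tt, start)
  regions <- names(truth$region_trends)

  runs <- purrr::map_dfr(regions, function(r) {
    seas <- truth$seasonal_amplitudes[[r]] *
      cos(2 * pi * (cal$month - truth$seasonal_peak_months[[r]]) / 12)
    purrr::map_dfr(seq_len(n_models), function(m) {
      trend_pct <- truth$region_trends[[r]] + rnorm(1, 0, model_trend_sd)
      beta_m <- from_percent_per_year(trend_pct)
      purrr::map_dfr(seq_len(n_ens[m]), function(e) {
        noise <- if (series_sd > 0) {
          as.numeric(arima_sim_ar1(n_months, series_ar1, series_sd))
        } else rep(0, n_months)
        tibble::tibble(
          model_id = sprintf("model%02d", m),
          ensemble_id = sprintf("ens%d", e),
          region_id = r,
          year = cal$year, month = cal$month, t = tt,
          log_chl = truth$intercepts[[r]] + beta_m * (tt - 1) + seas + noise
        )
      })
    })
  })
  runs
}

# stationary AR(1) sample path of length n, innovation sd `sd`
arima_sim_ar1 <- function(n, rho, sd) {
  x <- numeric(n)
  x[1] <- rnorm(1, sd = sd / sqrt(1 - rho^2))
  if (n > 1) {
    eps <- rnorm(n - 1, sd = sd)
    for (i in 2:n) x[i] <- rho * x[i - 1] + eps[i - 1]
  }
  x
}
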
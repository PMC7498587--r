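# Trend priors: per-run GLS-AR(1) fits on regional ensemble series,
# ensemble-then-model averaging, the multi-model normal prior, and the vague
# N(0, 100) prior.

#' Construct a normal prior for the trend coefficient
#'
#' @param mean,variance Prior mean and variance on `unit_scale`.
#' @param unit_scale `"percent_per_year"` or `"log_per_month"`.
#' @param provenance `"vague"` or `"ensemble"`.
#' @param n_models Number of climate models behind an ensemble prior (0 for
#'   vague).
#' @return A `trend_prior` object.
#' @export
trend_prior <- function(mean, variance,
                        unit_scale = c("percent_per_year", "log_per_month"),
                        provenance = c("vague", "ensemble"),
                        n_models = 0L) {
  unit_scale <- match.arg(unit_scale)
  provenance <- match.arg(provenance)
  stopifnot(is.numeric(mean), is.numeric(variance), variance > 0)
  structure(
    list(mean = mean, variance = variance, unit_scale = unit_scale,
         provenance = provenance, n_models = as.integer(n_models)),
    class = "trend_prior"
  )
}

#' @export
print.trend_prior <- function(x, ...) {
  cat(sprintf("<trend_prior> N(mean = %g, var = %g) [%s, %s%s]\n",
              x$mean, x$variance, x$unit_scale, x$provenance,
              if (x$n_models > 0) paste0(", ", x$n_models, " models") else ""))
  invisible(x)
}

#' @export
tidy.trend_prior <- function(x, ...) {
  tibble::tibble(mean = x$mean, variance = x$variance,
                 unit_scale = x$unit_scale, provenance = x$provenance,
                 n_models = x$n_models)
}

#' The vague trend prior
#'
#' Normal with mean 0 and variance 100 — effectively flat over any plausible
#' trend range, representing no prior knowledge about sign or magnitude.
#' By default it lives on the percent-per-year reporting scale and is
#' converted inward when a model is fitted.
#'
#' @param unit_scale Scale the `(0, 100)` pair is expressed on.
#' @return A `trend_prior`.
#' @export
vague_prior <- function(unit_scale = "percent_per_year") {
  trend_prior(0, 100, unit_scale = unit_scale, provenance = "vague")
}

#' Convert a trend prior between unit scales
#'
#' The mean maps through the exact monotone transform
#' (`m_log = log(1 + m_pct/100)/12` and its inverse); the variance maps by
#' the delta method, `v_log = v_pct * (dm_log/dm_pct)^2` evaluated at the
#' mean. At mean 0 the derivative is `1/1200`, so a percent-per-year
#' variance of 100 becomes `100/1,440,000` on the log-month scale.
#'
#' @param prior A `trend_prior`.
#' @param target_scale `"percent_per_year"` or `"log_per_month"`.
#' @return A `trend_prior` on `target_scale`.
#' @export
convert_prior_units <- function(prior,
                                target_scale = c("log_per_month",
                                                 "percent_per_year")) {
  target_scale <- match.arg(target_scale)
  if (prior$unit_scale == target_scale) return(prior)
  if (target_scale == "log_per_month") {
    m_pct <- prior$mean
    if (m_pct <= -100) stop("prior mean <= -100% per year", call. = FALSE)
    m_log <- from_percent_per_year(m_pct)
    deriv <- 1 / (1200 * (1 + m_pct / 100))  # d m_log / d m_pct
    v_log <- prior$variance * deriv^2
    out <- trend_prior(m_log, v_log, "log_per_month",
                       provenance = prior$provenance,
                       n_models = prior$n_models)
  } else {
    m_log <- prior$mean
    m_pct <- to_percent_per_year(m_log)
    deriv <- 1200 * exp(12 * m_log)          # d m_pct / d m_log
    v_pct <- prior$variance * deriv^2
    out <- trend_prior(m_pct, v_pct, "percent_per_year",
                       provenance = prior$provenance,
                       n_models = prior$n_models)
  }
  out
}

#' GLS trend fit with AR(1) errors
#'
#' Fits `y_t = b0 + b1 * t [+ b2 * cos(2 pi (month - peak)/12)] + u_t` with
#' `u_t` an AR(1) process, by iterated feasible GLS: OLS, then the AR(1)
#' coefficient from the residual lag-1 autocorrelation, then GLS via the
#' Prais-Winsten transform (keeping the first observation), iterated to a
#' 1e-8 change in rho or 50 iterations. The slope is in log units per month.
#'
#' @param series A numeric vector of consecutive monthly values, or a tibble
#'   with `log_chl` (and `month` when `include_seasonal`) columns.
#' @param include_seasonal Add a fixed-phase annual cosine covariate, with the
#'   phase set by [climatology_peak_month()] of the series (default `TRUE`
#'   when calendar months are available).
#' @param start_month Calendar month of the first value (vector input only).
#' @param rho Optionally fix the AR(1) coefficient instead of estimating it
#'   (`rho = 0` reduces the fit to OLS exactly).
#' @return A `gls_ar1_fit` list with `slope` (log/month), `intercept`, `rho`,
#'   `converged`, `iterations`, `coefficients`.
#' @export
fit_gls_ar1_trend <- function(series, include_seasonal = NULL,
                              start_month = 1L, rho = NULL) {
  if (is.data.frame(series)) {
    y <- series$log_chl
    moy <- series$month
  } else {
    y <- as.numeric(series)
    moy <- ((start_month - 1 + seq_along(y) - 1) %% 12) + 1
  }
  if (anyNA(y)) {
    stop("series contains missing months; GLS-AR(1) requires a complete series",
         call. = FALSE)
  }
  n <- length(y)
  if (n < 24) stop("need >= 24 months for a trend fit", call. = FALSE)
  if (is.null(include_seasonal)) include_seasonal <- TRUE

  tt <- seq_len(n) - 1
  X <- cbind(intercept = 1, time = tt - mean(tt))
  if (include_seasonal) {
    peak <- climatology_peak_month(y, start_month = moy[1])
    X <- cbind(X, seasonal = cos(2 * pi * (moy - peak) / 12))
  }

  pw <- function(M, rho) {
    out <- M
    out[1, ] <- sqrt(1 - rho^2) * M[1, , drop = FALSE]
    out[-1, ] <- M[-1, , drop = FALSE] - rho * M[-n, , drop = FALSE]
    out
  }
  lag1 <- function(r) {
    ss <- sum(r^2)
    if (ss < 1e-20 * n) return(0)  # numerically perfect fit
    rr <- sum(r[-1] * r[-n]) / ss
    if (abs(rr) >= 1) {
      warning("estimated AR(1) coefficient clipped to +/-0.99")
      rr <- sign(rr) * 0.99
    }
    rr
  }

  if (!is.null(rho)) { # fixed-rho GLS, no iteration
    stopifnot(abs(rho) < 1)
    beta <- qr.coef(qr(pw(X, rho)), pw(matrix(y, ncol = 1), rho))[, 1]
    return(structure(
      list(slope = unname(beta["time"]), intercept = unname(beta["intercept"]),
           rho = rho, converged = TRUE, iterations = 0L,
           coefficients = beta, n = n),
      class = "gls_ar1_fit"
    ))
  }

  beta <- qr.coef(qr(X), y)
  rho <- lag1(y - X %*% beta)
  converged <- FALSE
  iter <- 0L
  while (iter < 50L) {
    iter <- iter + 1L
    ys <- pw(matrix(y, ncol = 1), rho)
    Xs <- pw(X, rho)
    beta <- qr.coef(qr(Xs), ys)[, 1]
    rho_new <- lag1(y - X %*% beta)
    if (abs(rho_new - rho) < 1e-8) {
      rho <- rho_new
      converged <- TRUE
      break
    }
    rho <- rho_new
  }
  if (!converged) {
    warning("GLS-AR(1) iteration did not converge in 50 iterations; ",
            "returning last iterate")
  }
  structure(
    list(slope = unname(beta["time"]), intercept = unname(beta["intercept"]),
         rho = rho, converged = converged, iterations = iter,
         coefficients = beta, n = n),
    class = "gls_ar1_fit"
  )
}

#' @export
tidy.gls_ar1_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @export
glance.gls_ar1_fit <- function(x, ...) {
  tibble::tibble(rho = x$rho, n = x$n, iterations = x$iterations,
                 converged = x$converged)
}

#' Average ensemble-member trends within each climate model
#'
#' Each model contributes one trend regardless of how many ensemble members
#' it ran: members are averaged (unweighted) within their model before the
#' across-model statistics are taken, so multi-member models get no extra
#' weight.
#'
#' @param run_trends A tibble with columns `model_id`, `ensemble_id`, `slope`.
#' @return A tibble `model_id`, `slope` with one row per model.
#' @export
average_ensembles <- function(run_trends) {
  if (!is.data.frame(run_trends) || nrow(run_trends) == 0) {
    stop("run_trends must be a non-empty data frame", call. = FALSE)
  }
  run_trends |>
    dplyr::group_by(.data$model_id) |>
    dplyr::summarise(slope = mean(.data$slope), .groups = "drop")
}

#' Build the multi-model trend prior
#'
#' The prior mean is the across-model mean of per-model trends and the prior
#' variance their sample variance (denominator n - 1). A spread below 1e-8 is
#' floored at 1e-6 (percent-per-year scale) with a warning, since a
#' zero-variance prior would collapse the posterior to a point.
#'
#' @param model_trends Named numeric vector or tibble (`model_id`, `slope`)
#'   of per-model trends on `unit_scale`.
#' @param unit_scale Scale of the supplied trends.
#' @return A `trend_prior` with `provenance = "ensemble"`.
#' @export
build_multimodel_prior <- function(model_trends,
                                   unit_scale = "percent_per_year") {
  if (is.data.frame(model_trends)) model_trends <- model_trends$slope
  n <- length(model_trends)
  if (n < 2) {
    stop("across-model variance undefined with fewer than 2 models",
         call. = FALSE)
  }
  m <- mean(model_trends)
  v <- var(model_trends)
  floor_v <- if (unit_scale == "percent_per_year") 1e-6 else
    1e-6 / 1200^2
  if (v < 1e-8 * (if (unit_scale == "percent_per_year") 1 else 1 / 1200^2)) {
    warning("degenerate across-model spread; prior variance floored")
    v <- floor_v
  }
  trend_prior(m, v, unit_scale = unit_scale, provenance = "ensemble",
              n_models = n)
}

#' Build per-region ensemble priors from climate-run series
#'
#' Runs the whole prior pipeline on a tidy collection of climate-model
#' regional mean series (as produced by [simulate_climate_ensemble()] or read
#' from CSV): per run, a GLS-AR(1) trend fit; slopes converted to
#' % year^-1; ensembles averaged within model; across-model mean and
#' sample variance per region.
#'
#' @param runs Tibble with columns `model_id`, `ensemble_id`, `region_id`,
#'   `year`, `month`, `log_chl` (monthly rows in time order).
#' @param include_seasonal Include the fixed-phase annual cosine in each GLS
#'   fit (default `TRUE`; the series are monthly and seasonal).
#' @return A named list of `trend_prior` objects, one per region, on the
#'   percent-per-year scale.
#' @export
build_region_priors <- function(runs, include_seasonal = TRUE) {
  stopifnot(all(c("model_id", "ensemble_id", "region_id", "log_chl")
                %in% names(runs)))
  per_run <- runs |>
    dplyr::group_by(.data$region_id, .data$model_id, .data$ensemble_id) |>
    dplyr::arrange(.data$year, .data$month, .by_group = TRUE) |>
    dplyr::summarise(
      slope = to_percent_per_year(
        fit_gls_ar1_trend(dplyr::pick(dplyr::everything()),
                          include_seasonal = include_seasonal)$slope),
      .groups = "drop"
    )
  per_run |>
    split(per_run$region_id) |>
    purrr::map(function(d) {
      build_multimodel_prior(average_ensembles(d),
                             unit_scale = "percent_per_year")
    })
}

#' Tabulate per-region priors
#'
#' @param priors Named list of `trend_prior` objects (see
#'   [build_region_priors()]).
#' @return Tibble `region_id`, `prior_mean_pct_yr`, `prior_var`, `n_models`,
#'   `provenance`.
#' @export
prior_table <- function(priors) {
  purrr::imap_dfr(priors, function(p, id) {
    p <- convert_prior_units(p, "percent_per_year")
    tibble::tibble(region_id = id, prior_mean_pct_yr = p$mean,
                   prior_var = p$variance, n_models = p$n_models,
                   provenance = p$provenance)
  })
}
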
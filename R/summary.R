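# Posterior summaries: KDE mode, 95% highest density interval, significance
# and prior-scenario comparison, all reported in % year^-1.

#' Mode of a posterior sample
#'
#' Kernel-density mode: a Gaussian-kernel density with Silverman's
#' rule-of-thumb bandwidth is evaluated on a 512-point grid spanning the
#' draw range, and the grid point of maximal density is returned. Stable on
#' MCMC draws where a histogram mode would be bin-sensitive.
#'
#' @param draws Numeric vector of at least 500 posterior draws.
#' @param bw Bandwidth rule, passed to [stats::density()] (default `"nrd0"`,
#'   Silverman).
#' @return The mode (numeric scalar).
#' @export
posterior_mode <- function(draws, bw = "nrd0") {
  check_draws(draws)
  if (max(draws) - min(draws) < .Machine$double.eps * 100) {
    return(draws[1]) # point mass
  }
  d <- density(draws, bw = bw, kernel = "gaussian", n = 512,
               from = min(draws), to = max(draws))
  d$x[which.max(d$y)]
}

check_draws <- function(draws, min_n = 500) {
  if (length(draws) < min_n) {
    stop("need at least ", min_n, " draws, got ", length(draws),
         call. = FALSE)
  }
  invisible(draws)
}

#' Highest density interval of a sample
#'
#' The shortest interval containing `ceiling(mass * n)` of the sorted draws —
#' for a unimodal posterior, the 95% HDI the analysis reports as the trend
#' uncertainty (its width being the "uncertainty" attached to each regional
#' trend).
#'
#' @param draws Numeric vector of at least 500 draws.
#' @param mass Probability mass in (0, 1); default 0.95.
#' @return Named numeric `c(lower, upper)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  if (!(mass > 0 && mass < 1)) stop("mass must be in (0, 1)", call. = FALSE)
  check_draws(draws)
  x <- sort(draws)
  n <- length(x)
  k <- ceiling(mass * n)
  if (k >= n) k <- n
  widths <- x[k:n] - x[1:(n - k + 1)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k - 1])
}

#' Significance of a trend estimate
#'
#' A trend is significant iff its 95% HDI excludes zero strictly: an HDI
#' with an endpoint exactly at zero counts as overlapping zero (conservative
#' tie rule).
#'
#' @param estimate A `trend_estimate` row (see [summarize_trend()]) or a
#'   numeric `c(lower, upper)` interval.
#' @return Logical.
#' @export
is_significant <- function(estimate) {
  if (is.data.frame(estimate)) {
    lo <- estimate$hdi_low_pct_yr; hi <- estimate$hdi_high_pct_yr
  } else {
    lo <- estimate[1]; hi <- estimate[2]
  }
  if (any(hi < lo)) stop("invalid HDI: upper < lower", call. = FALSE)
  unname(lo > 0 | hi < 0)
}

#' Do two prior scenarios give different trends?
#'
#' Scenarios for the same region are deemed different iff their 95% HDIs are
#' disjoint; touching intervals (shared endpoint) count as overlapping.
#'
#' @param a,b `trend_estimate` rows for the same region.
#' @return Logical: `TRUE` iff the HDIs are disjoint.
#' @export
scenarios_differ <- function(a, b) {
  if (!identical(as.character(a$region_id), as.character(b$region_id))) {
    stop("trend estimates are for different regions", call. = FALSE)
  }
  a$hdi_low_pct_yr > b$hdi_high_pct_yr | b$hdi_low_pct_yr > a$hdi_high_pct_yr
}

#' Summarise a fitted spatio-temporal model into a trend estimate
#'
#' Extracts the trend coefficient draws, converts them draw-wise to
#' % year^-1 (a monotone map, so HDI endpoints transform endpoint-wise),
#' and reports the KDE posterior mode, 95% HDI bounds, width and half-width,
#' and the significance flag.
#'
#' @param fit A `chltrends_fit` from [fit_st_model()].
#' @param mass HDI mass (default 0.95).
#' @return A one-row `trend_estimate` tibble with columns `region_id`,
#'   `prior`, `mode_pct_yr`, `hdi_low_pct_yr`, `hdi_high_pct_yr`,
#'   `hdi_width_pct_yr`, `hdi_halfwidth_pct_yr`, `significant`.
#' @export
summarize_trend <- function(fit, mass = 0.95) {
  pct <- to_percent_per_year(fit$draws$beta_trend)
  h <- hdi(pct, mass)
  mode <- posterior_mode(pct)
  tibble::tibble(
    region_id = fit$region_id,
    prior = fit$prior$provenance,
    mode_pct_yr = mode,
    hdi_low_pct_yr = h[["lower"]],
    hdi_high_pct_yr = h[["upper"]],
    hdi_width_pct_yr = h[["upper"]] - h[["lower"]],
    hdi_halfwidth_pct_yr = (h[["upper"]] - h[["lower"]]) / 2,
    significant = h[["lower"]] > 0 | h[["upper"]] < 0
  )
}
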
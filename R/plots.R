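# ggplot2 views of fits, per-region estimates and sensitivity scans.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Posterior density of the trend for one fitted region
#'
#' Density of the trend draws in % year^-1 with the 95% HDI bounds and zero
#' marked.
#'
#' @param object A `chltrends_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.chltrends_fit <- function(object, ...) {
  pct <- to_percent_per_year(object$draws$beta_trend)
  h <- hdi(pct)
  ggplot2::ggplot(tibble::tibble(trend = pct), ggplot2::aes(x = .data$trend)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_vline(xintercept = h, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::labs(
      x = expression(trend ~ ("%" ~ year^-1)), y = "posterior density",
      title = sprintf("Region %s (%s prior)", object$region_id,
                      object$prior$provenance)
    ) +
    ggplot2::theme_minimal()
}

#' Forest plot of per-region trend estimates
#'
#' Modes with 95% HDI whiskers per region, dodged by prior scenario;
#' non-significant estimates are hollow.
#'
#' @param estimates A `trend_estimate` tibble (rows from
#'   [summarize_trend()]).
#' @return A ggplot.
#' @export
plot_trend_estimates <- function(estimates) {
  ggplot2::ggplot(
    estimates,
    ggplot2::aes(x = .data$region_id, y = .data$mode_pct_yr,
                 colour = .data$prior, shape = .data$significant)
  ) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$hdi_low_pct_yr, ymax = .data$hdi_high_pct_yr),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::labs(x = "region", y = expression(trend ~ ("%" ~ year^-1))) +
    ggplot2::theme_minimal()
}

#' Sensitivity of the posterior trend to the prior
#'
#' Trend mode against prior variance (log scale), one line per prior mean.
#'
#' @param object A `sensitivity_result` from [sensitivity_scan()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sensitivity_result <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$prior_var, y = .data$mode_pct_yr,
                 colour = factor(.data$prior_mean_pct_yr))
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "prior variance (log scale)",
                  y = expression(posterior ~ mode ~ ("%" ~ year^-1)),
                  colour = "prior mean") +
    ggplot2::theme_minimal()
}
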
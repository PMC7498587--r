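#' Convert trend coefficients between log-chl per month and percent per year
#'
#' The spatio-temporal model regresses natural-log chlorophyll on time in
#' months, so its trend coefficient `beta` is a log difference per month.
#' Reported trends are percentage changes of un-transformed chlorophyll per
#' year: `pct = (exp(12 * beta) - 1) * 100`. The map is monotone, so interval
#' endpoints (e.g. HDI bounds) transform endpoint-wise.
#'
#' @param beta Trend in log-chl units per month.
#' @param pct Trend in percent per year; must exceed -100 (a chlorophyll
#'   concentration cannot lose more than all of itself in a year).
#' @return The converted trend (numeric, vectorised).
#' @examples
#' to_percent_per_year(log(1.01) / 12) # exactly 1% per year
#' from_percent_per_year(to_percent_per_year(0.003))
#' @export
to_percent_per_year <- function(beta) {
  (exp(12 * beta) - 1) * 100
}

#' @rdname to_percent_per_year
#' @export
from_percent_per_year <- function(pct) {
  if (any(pct <= -100, na.rm = TRUE)) {
    stop("percent-per-year trend must be > -100", call. = FALSE)
  }
  log(1 + pct / 100) / 12
}
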
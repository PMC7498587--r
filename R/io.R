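# Plain-text round-trips for fields, masks, ensemble runs, priors and truth.
# Gridded objects are stored long-form (one row per cell-month) so every
# artifact in a run directory is diffable text.

#' Write / read a gridded chlorophyll field as CSV
#'
#' Long format: `lat, lon, year, month, t, log_chl` with empty cells for
#' missing values; grid metadata (`start`, `n_months`, `cell_size`) travels
#' in a `<path>.json` sidecar.
#'
#' @param field A `chl_field`.
#' @param path Output CSV path.
#' @return `write_chl_field()` the path, invisibly; `read_chl_field()` a
#'   `chl_field` tibble.
#' @export
write_chl_field <- function(field, path) {
  readr::write_csv(as.data.frame(field), path, na = "")
  meta <- list(start = attr(field, "start"),
               n_months = attr(field, "n_months"),
               cell_size = attr(field, "cell_size"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_chl_field
#' @export
read_chl_field <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_chl_field(df, start = meta$start, n_months = meta$n_months,
                cell_size = meta$cell_size)
}

#' Write / read a region mask as CSV plus a JSON region registry
#'
#' @param mask A `region_mask`.
#' @param path Output CSV path (`lat, lon, region_id, area_km2`); the ordered
#'   region registry and grid metadata go to `<path>.json`.
#' @export
write_region_mask <- function(mask, path) {
  readr::write_csv(as.data.frame(mask), path, na = "")
  meta <- list(region_ids = attr(mask, "region_ids"),
               grid_shape = attr(mask, "grid_shape"),
               cell_size = attr(mask, "cell_size"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_region_mask
#' @export
read_region_mask <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(region_id = "c"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  out <- tibble::as_tibble(df)
  attr(out, "region_ids") <- meta$region_ids
  attr(out, "grid_shape") <- meta$grid_shape
  attr(out, "cell_size") <- meta$cell_size
  class(out) <- c("region_mask", class(out))
  out
}

#' Serialise simulation truth to JSON
#'
#' @param truth A [simulation_truth()].
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  simulation_truth(
    region_trends = x$region_trends,
    intercepts = x$intercepts,
    seasonal_amplitudes = x$seasonal_amplitudes,
    seasonal_peak_months = x$seasonal_peak_months,
    spatial_decay_km = x$spatial_decay_km,
    ar1_rho = x$ar1_rho,
    process_sd = x$process_sd,
    nugget_sd = x$nugget_sd,
    missing_fraction = x$missing_fraction,
    seed = x$seed
  )
}
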
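#' Area of a latitude-longitude grid cell
#'
#' Spherical-zone area of a cell of width `cell_size` degrees centred at
#' `lat_center`: `R^2 * dlambda * (sin(lat + h) - sin(lat - h))` with
#' `R = 6371` km and `h` the half cell size. Used for area-weighted regional
#' means and for the chlorophyll-times-area global weighting.
#'
#' @param lat_center Latitude of the cell centre, degrees north (vectorised).
#' @param cell_size Cell edge length in degrees (same in lat and lon).
#' @return Cell area in km^2.
#' @examples
#' cell_area_km2(0, 1)    # ~12364 km^2 at the equator
#' cell_area_km2(60, 1)   # roughly half of the equatorial area
#' @export
cell_area_km2 <- function(lat_center, cell_size = 1) {
  h <- cell_size / 2
  if (any(abs(lat_center) + h > 90 + 1e-9)) {
    stop("cell extends beyond a pole: |lat_center| + cell_size/2 must be <= 90",
         call. = FALSE)
  }
  dlam <- cell_size * pi / 180
  EARTH_RADIUS_KM^2 * dlam *
    (sin((lat_center + h) * pi / 180) - sin((lat_center - h) * pi / 180))
}

# Great-circle distance matrix (km) between cell centres, haversine on
# R = 6371 km. `coords` is a data frame with lon, lat columns.
distance_matrix_km <- function(coords) {
  m <- geosphere::distm(cbind(coords$lon, coords$lat),
                        fun = function(p1, p2) {
                          geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM * 1000)
                        })
  m / 1000
}

#' Downscale a gridded chlorophyll field by box averaging
#'
#' Averages fine-resolution cells within coarse boxes of `target_resolution`
#' degrees, mirroring the standard preprocessing of satellite chlorophyll to a
#' 1-degree analysis grid. The average is taken over non-missing fine cells
#' only; a coarse cell is missing iff every fine cell inside it is missing.
#' The fine grid must nest: `target_resolution` must be an integer multiple of
#' the fine cell size.
#'
#' @param field A `chl_field` tibble (see [simulate_chl_field()]).
#' @param target_resolution Coarse cell size in degrees (default 1).
#' @return A `chl_field` tibble on the coarse grid; coarse cell centres are
#'   the mean of member fine-cell centres.
#' @export
downscale_to_one_degree <- function(field, target_resolution = 1) {
  fine <- attr(field, "cell_size") %||% infer_cell_size(field)
  ratio <- target_resolution / fine
  if (abs(ratio - round(ratio)) > 1e-8) {
    stop("fine grid does not nest in the target resolution (ratio ",
         format(ratio), " not an integer)", call. = FALSE)
  }
  out <- field |>
    dplyr::mutate(
      .box_lat = floor(.data$lat / target_resolution),
      .box_lon = floor(.data$lon / target_resolution)
    ) |>
    dplyr::group_by(.data$.box_lat, .data$.box_lon, .data$year, .data$month,
                    .data$t) |>
    dplyr::summarise(
      log_chl = if (all(is.na(.data$log_chl))) NA_real_ else
        mean(.data$log_chl, na.rm = TRUE),
      lat = mean(.data$lat),
      lon = mean(.data$lon),
      .groups = "drop"
    ) |>
    dplyr::select("lat", "lon", "year", "month", "t", "log_chl") |>
    dplyr::arrange(.data$t, .data$lat, .data$lon)
  new_chl_field(out,
                start = attr(field, "start"),
                n_months = attr(field, "n_months"),
                cell_size = target_resolution)
}

infer_cell_size <- function(field) {
  lats <- sort(unique(field$lat))
  if (length(lats) < 2) return(1)
  min(diff(lats))
}

#' Area-weighted regional mean time series
#'
#' Collapses a gridded field to one monthly series per region: for each month,
#' the (optionally area-weighted) mean of the region's non-missing cells. A
#' month is missing iff no member cell has data that month.
#'
#' @param field A `chl_field` tibble.
#' @param mask A `region_mask` tibble with `lat`, `lon`, `region_id`,
#'   `area_km2` columns (see [generate_region_layout()]).
#' @param region_id Region to extract.
#' @param area_weighted Use cell areas as weights (default `TRUE`); with
#'   `FALSE` every cell counts equally.
#' @return A tibble with columns `year`, `month`, `t`, `log_chl`, `n_cells`,
#'   ordered by `t`, carrying the field's `start` attribute.
#' @export
regional_mean_series <- function(field, mask, region_id, area_weighted = TRUE) {
  stopifnot(is.data.frame(mask))
  cells <- dplyr::filter(mask, .data$region_id == !!region_id)
  if (nrow(cells) == 0) {
    stop("unknown region id: ", region_id, call. = FALSE)
  }
  joined <- dplyr::inner_join(field, cells[, c("lat", "lon", "area_km2")],
                              by = c("lat", "lon"))
  if (nrow(joined) == 0) {
    stop("region ", region_id, " has no cells in the field", call. = FALSE)
  }
  if (!area_weighted) joined$area_km2 <- 1
  out <- joined |>
    dplyr::group_by(.data$year, .data$month, .data$t) |>
    dplyr::summarise(
      n_cells = sum(!is.na(.data$log_chl)),
      log_chl = {
        ok <- !is.na(.data$log_chl)
        if (!any(ok)) NA_real_ else
          sum(.data$log_chl[ok] * .data$area_km2[ok]) / sum(.data$area_km2[ok])
      },
      .groups = "drop"
    ) |>
    dplyr::select("year", "month", "t", "log_chl", "n_cells") |>
    dplyr::arrange(.data$t)
  attr(out, "start") <- attr(field, "start")
  out
}

#' Calendar month of climatological peak chlorophyll
#'
#' Averages the series by calendar month across years and returns the month
#' (1-12) with the maximal mean; ties break to the earliest month. This fixes
#' the phase of the annual harmonic so its peak lands on the climatological
#' peak month. No detrending is applied before averaging.
#'
#' @param series Either a tibble with `month` and `log_chl` columns (as
#'   returned by [regional_mean_series()]) or a numeric vector of consecutive
#'   monthly values.
#' @param start_month Calendar month (1-12) of the first value; only used for
#'   numeric-vector input.
#' @return Integer month of year in 1..12.
#' @export
climatology_peak_month <- function(series, start_month = 1) {
  if (is.data.frame(series)) {
    moy <- series$month
    val <- series$log_chl
  } else {
    val <- as.numeric(series)
    moy <- ((start_month - 1 + seq_along(val) - 1) %% 12) + 1
  }
  if (sum(!is.na(val)) < 12) {
    stop("need at least 12 months with data for a climatology", call. = FALSE)
  }
  clim <- tapply(val, factor(moy, levels = 1:12), mean, na.rm = TRUE)
  clim[is.nan(clim)] <- NA_real_
  if (any(is.na(clim))) {
    stop("calendar month(s) with no data in any year: ",
         paste(which(is.na(clim)), collapse = ", "), call. = FALSE)
  }
  as.integer(which.max(clim)) # which.max takes the first (earliest) maximum
}

#' Per-region mean chlorophyll and area table for global weighting
#'
#' Computes, per region, the mean un-logged chlorophyll (mg m^-3) over all
#' non-missing cell-months (area-weighted) and the total region area in km^2.
#' These feed the chlorophyll-times-area weights of the global trend.
#'
#' @inheritParams regional_mean_series
#' @return A tibble with columns `region_id`, `mean_chl`, `area_km2`.
#' @export
region_weights_table <- function(field, mask) {
  cells <- dplyr::filter(mask, !is.na(.data$region_id))
  joined <- dplyr::inner_join(field, cells[, c("lat", "lon", "region_id",
                                               "area_km2")],
                              by = c("lat", "lon"))
  joined |>
    dplyr::filter(!is.na(.data$log_chl)) |>
    dplyr::group_by(.data$region_id) |>
    dplyr::summarise(
      mean_chl = sum(exp(.data$log_chl) * .data$area_km2) / sum(.data$area_km2),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      cells |>
        dplyr::group_by(.data$region_id) |>
        dplyr::summarise(area_km2 = sum(.data$area_km2), .groups = "drop"),
      by = "region_id"
    )
}
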
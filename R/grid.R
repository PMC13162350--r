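#' Define a regular latitude-longitude grid
#'
#' All rasters in one analysis share a single grid: a regular lat/lon lattice
#' (WGS84), cell-center registered, with row 1 the northernmost row and
#' longitudes increasing with column index.
#'
#' @param n_rows,n_cols Number of rows (latitude) and columns (longitude).
#' @param lat_min,lat_max Southern and northern *edges* of the grid, degrees.
#' @param lon_min,lon_max Western and eastern *edges* of the grid, degrees.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(50, 50, -30, 30, -60, 60)
#' head(grid_lat(g))
#' @export
grid_spec <- function(n_rows, n_cols, lat_min, lat_max, lon_min, lon_max) {
  stopifnot(
    is.numeric(n_rows), is.numeric(n_cols),
    n_rows >= 1, n_cols >= 1,
    n_rows == as.integer(n_rows), n_cols == as.integer(n_cols),
    is.finite(lat_min), is.finite(lat_max), lat_max > lat_min,
    is.finite(lon_min), is.finite(lon_max), lon_max > lon_min,
    lat_min >= -90, lat_max <= 90
  )
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      lat_min = lat_min, lat_max = lat_max,
      lon_min = lon_min, lon_max = lon_max
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "grid_spec: %d x %d cells, lat [%g, %g], lon [%g, %g], res %g x %g deg\n",
    x$n_rows, x$n_cols, x$lat_min, x$lat_max, x$lon_min, x$lon_max,
    grid_res(x)["dlat"], grid_res(x)["dlon"]
  ))
  invisible(x)
}

#' Grid resolution in degrees
#' @param spec A `grid_spec`.
#' @return Named numeric vector `c(dlat, dlon)`.
#' @export
grid_res <- function(spec) {
  c(
    dlat = (spec$lat_max - spec$lat_min) / spec$n_rows,
    dlon = (spec$lon_max - spec$lon_min) / spec$n_cols
  )
}

#' Cell-center latitudes (row 1 = northernmost) and longitudes
#' @param spec A `grid_spec`.
#' @return Numeric vector of cell-center coordinates.
#' @export
grid_lat <- function(spec) {
  dlat <- grid_res(spec)["dlat"]
  spec$lat_max - dlat * (seq_len(spec$n_rows) - 0.5)
}

#' @rdname grid_lat
#' @export
grid_lon <- function(spec) {
  dlon <- grid_res(spec)["dlon"]
  spec$lon_min + dlon * (seq_len(spec$n_cols) - 0.5)
}

same_grid <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$lat_min - b$lat_min) < tol && abs(a$lat_max - b$lat_max) < tol &&
    abs(a$lon_min - b$lon_min) < tol && abs(a$lon_max - b$lon_max) < tol
}

stop_if_grid_mismatch <- function(a, b, what = "rasters") {
  if (!same_grid(a, b)) stop(what, " do not share a grid_spec", call. = FALSE)
  invisible(TRUE)
}

#' Attach a grid to a raster matrix
#'
#' Rasters are plain numeric matrices (`NA` = nodata) with the grid carried as
#' an attribute; row order matches the grid (row 1 northernmost).
#'
#' @param values Numeric matrix of `n_rows x n_cols` values.
#' @param spec The `grid_spec` the values live on.
#' @return The matrix with attribute `grid` set.
#' @export
raster_layer <- function(values, spec) {
  stopifnot(is.matrix(values))
  if (nrow(values) != spec$n_rows || ncol(values) != spec$n_cols) {
    stop("values dimensions do not match grid_spec", call. = FALSE)
  }
  attr(values, "grid") <- spec
  values
}

#' Retrieve the grid attached to a raster
#' @param x A raster matrix created with [raster_layer()].
#' @return The `grid_spec`.
#' @export
grid_of <- function(x) {
  g <- attr(x, "grid")
  if (is.null(g)) stop("raster carries no grid_spec attribute", call. = FALSE)
  g
}

#' Spherical cell areas for a grid
#'
#' Area of the cell in row i, column j is the spherical-cap band slice
#' `R^2 * dlon * (sin(lat_top) - sin(lat_bottom))` with `R = 6371` km, so
#' areas are constant along a row and shrink toward the poles. Over a
#' full-globe grid the areas sum to `4 * pi * R^2`.
#'
#' @param spec A `grid_spec`.
#' @param radius_km Sphere radius, km (authalic Earth radius by default).
#' @return Raster matrix of cell areas in km^2.
#' @examples
#' a <- cell_areas(grid_spec(18, 36, -90, 90, -180, 180))
#' sum(a) / (4 * pi * 6371^2) # 1
#' @export
cell_areas <- function(spec, radius_km = 6371) {
  dlat <- grid_res(spec)["dlat"]
  dlon_rad <- grid_res(spec)["dlon"] * pi / 180
  lat_top <- spec$lat_max - dlat * (seq_len(spec$n_rows) - 1)
  lat_bot <- lat_top - dlat
  band <- radius_km^2 * dlon_rad * (sin(lat_top * pi / 180) - sin(lat_bot * pi / 180))
  raster_layer(matrix(band, spec$n_rows, spec$n_cols), spec)
}

#' Region masks
#'
#' `tropics_mask()` marks cells whose center latitude satisfies
#' `|lat| <= lat_limit` (default 23.5 degrees, the tropics). `region_mask()`
#' marks a lat/lon box; regions used for exposure reporting are ordinary
#' logical rasters, so any user-supplied mask works.
#'
#' @param spec A `grid_spec`.
#' @param lat_limit Absolute latitude bound, degrees.
#' @return Logical raster matrix.
#' @export
tropics_mask <- function(spec, lat_limit = 23.5) {
  lat <- grid_lat(spec)
  raster_layer(
    matrix(abs(lat) <= lat_limit, spec$n_rows, spec$n_cols),
    spec
  )
}

#' @rdname tropics_mask
#' @param lat_range,lon_range Length-2 numeric `c(min, max)` bounds on the
#'   cell-center coordinates.
#' @export
region_mask <- function(spec, lat_range = c(-90, 90), lon_range = c(-180, 360)) {
  lat <- grid_lat(spec)
  lon <- grid_lon(spec)
  m <- outer(
    lat >= lat_range[1] & lat <= lat_range[2],
    lon >= lon_range[1] & lon <= lon_range[2],
    `&`
  )
  raster_layer(m, spec)
}
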
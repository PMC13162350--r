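#' Monthly climate cube
#'
#' A climate cube holds 12 monthly mean-temperature layers (degrees C) and 12
#' monthly precipitation-total layers (mm/month) on one grid, tagged with its
#' source (baseline, or model x scenario x period). Projection archives often
#' carry only monthly maximum and minimum temperature; passing `tmax`/`tmin`
#' instead of `tavg` derives the mean via
#' [mean_temperature_from_extremes()].
#'
#' @param spec A `grid_spec`.
#' @param tavg Numeric array `n_rows x n_cols x 12`, monthly mean temperature.
#' @param prec Numeric array `n_rows x n_cols x 12`, monthly precipitation
#'   totals; must be `>= 0` or `NA`.
#' @param tmax,tmin Alternative to `tavg`: monthly extreme-temperature arrays.
#' @param source Free-form tag, e.g. `"baseline"` or
#'   `list(model = "m01", scenario = "2C", period = "2041-2060")`.
#' @return An object of class `climate_cube`.
#' @export
climate_cube <- function(spec, tavg = NULL, prec, tmax = NULL, tmin = NULL,
                         source = "baseline") {
  if (is.null(tavg)) {
    if (is.null(tmax) || is.null(tmin)) {
      stop("supply tavg, or both tmax and tmin", call. = FALSE)
    }
    tavg <- mean_temperature_from_extremes(tmax, tmin)
  }
  check_monthly <- function(a, nm) {
    if (!(is.array(a) && length(dim(a)) == 3 && dim(a)[3] == 12)) {
      stop(nm, " must be an n_rows x n_cols x 12 array", call. = FALSE)
    }
    if (dim(a)[1] != spec$n_rows || dim(a)[2] != spec$n_cols) {
      stop(nm, " dimensions do not match grid_spec", call. = FALSE)
    }
  }
  check_monthly(tavg, "tavg")
  check_monthly(prec, "prec")
  if (any(prec < 0, na.rm = TRUE)) {
    stop("prec has negative values", call. = FALSE)
  }
  structure(
    list(spec = spec, tavg = tavg, prec = prec, source = source),
    class = "climate_cube"
  )
}

#' @export
print.climate_cube <- function(x, ...) {
  src <- if (is.list(x$source)) {
    paste(unlist(x$source), collapse = " / ")
  } else {
    as.character(x$source)
  }
  cat(sprintf(
    "climate_cube [%s]: %d x %d x 12 months, Tavg %.1f..%.1f degC, P %.0f..%.0f mm/mo\n",
    src, x$spec$n_rows, x$spec$n_cols,
    min(x$tavg, na.rm = TRUE), max(x$tavg, na.rm = TRUE),
    min(x$prec, na.rm = TRUE), max(x$prec, na.rm = TRUE)
  ))
  invisible(x)
}

#' Monthly mean temperature from extremes
#'
#' `tavg = (tmax + tmin) / 2`, element-wise. Cells where `tmax < tmin` are
#' flagged with a warning (and still computed) since inverted extremes usually
#' indicate mis-stacked inputs.
#'
#' @param tmax,tmin Arrays or matrices of the same shape, degrees C.
#' @return Array of the same shape.
#' @export
mean_temperature_from_extremes <- function(tmax, tmin) {
  if (!identical(dim(tmax), dim(tmin))) {
    stop("tmax and tmin shapes differ", call. = FALSE)
  }
  n_bad <- sum(tmax < tmin, na.rm = TRUE)
  if (n_bad > 0) {
    warning(sprintf("tmax < tmin in %d cell-months; computed anyway", n_bad))
  }
  (tmax + tmin) / 2
}

#' Aggregate a monthly cube to annual climate
#'
#' Annual mean temperature is the unweighted mean of the 12 monthly means;
#' annual precipitation is the sum of the 12 monthly totals. A cell that is
#' nodata in any contributing month is nodata in the output.
#'
#' @param cube A [climate_cube()].
#' @return An object of class `annual_climate`: list with `spec`, `t_ann`
#'   (degC) and `p_ann` (mm/yr) raster matrices.
#' @export
annual_aggregate <- function(cube) {
  stopifnot(inherits(cube, "climate_cube"))
  t_ann <- apply(cube$tavg, c(1, 2), function(v) mean(v))   # NA if any month NA
  p_ann <- apply(cube$prec, c(1, 2), function(v) sum(v))
  structure(
    list(
      spec = cube$spec,
      t_ann = raster_layer(t_ann, cube$spec),
      p_ann = raster_layer(p_ann, cube$spec),
      source = cube$source
    ),
    class = "annual_climate"
  )
}

#' @export
print.annual_climate <- function(x, ...) {
  cat(sprintf(
    "annual_climate: %d x %d cells, T_ann %.1f..%.1f degC, P_ann %.0f..%.0f mm/yr\n",
    x$spec$n_rows, x$spec$n_cols,
    min(x$t_ann, na.rm = TRUE), max(x$t_ann, na.rm = TRUE),
    min(x$p_ann, na.rm = TRUE), max(x$p_ann, na.rm = TRUE)
  ))
  invisible(x)
}

#' Multimodel ensemble mean of climate cubes
#'
#' Unweighted per-cell, per-month mean across ensemble members. A cell-month
#' is nodata in the output iff it is nodata in *any* member, which keeps the
#' effective model count identical across cells.
#'
#' @param cubes A list of [climate_cube()] objects sharing one grid (and,
#'   conventionally, one scenario and period).
#' @param source Source tag for the returned cube.
#' @return A [climate_cube()].
#' @export
ensemble_mean <- function(cubes, source = "ensemble-mean") {
  if (length(cubes) == 0) stop("empty ensemble", call. = FALSE)
  spec <- cubes[[1]]$spec
  for (cb in cubes) {
    stopifnot(inherits(cb, "climate_cube"))
    stop_if_grid_mismatch(spec, cb$spec, "ensemble members")
  }
  n <- length(cubes)
  tavg <- Reduce(`+`, lapply(cubes, `[[`, "tavg")) / n
  prec <- Reduce(`+`, lapply(cubes, `[[`, "prec")) / n
  climate_cube(spec, tavg = tavg, prec = prec, source = source)
}

# Holdridge-style class edges (log2-spaced axes)
.biotemp_edges <- c(1.5, 3, 6, 12, 24)
.precip_edges <- c(62.5, 125, 250, 500, 1000, 2000, 4000, 8000)

#' Holdridge life-zone classification
#'
#' Biotemperature is the mean of the 12 monthly temperatures after clamping
#' each month to `[0, 30]` degC (months below freezing and above 30 do not add
#' biological activity). Biotemperature is binned on log2-spaced class
#' boundaries `{1.5, 3, 6, 12, 24}` degC and annual precipitation on
#' `{62.5, 125, 250, 500, 1000, 2000, 4000, 8000}` mm. Intervals are half-open
#' `(low, high]`: a value exactly on a boundary falls in the lower class. The
#' zone code enumerates the (biotemperature class, precipitation class) pair.
#'
#' @param cube A [climate_cube()] (monthly temperatures are needed for the
#'   clamped biotemperature).
#' @return A list of class `life_zone_raster`: `spec`, `zone_code` (integer
#'   raster), `biotemp` (degC raster), `legend` (data.frame mapping codes to
#'   class labels).
#' @export
holdridge_classify <- function(cube) {
  stopifnot(inherits(cube, "climate_cube"))
  spec <- cube$spec
  clamped <- pmin(pmax(cube$tavg, 0), 30)
  biotemp <- apply(clamped, c(1, 2), function(v) mean(v))
  p_ann <- apply(cube$prec, c(1, 2), function(v) sum(v))

  bt_class <- matrix(
    findInterval(biotemp, .biotemp_edges, left.open = FALSE) + 1L,
    spec$n_rows, spec$n_cols
  )
  # findInterval counts edges <= x; the (low, high] convention needs edges < x,
  # i.e. values exactly on an edge go to the lower class
  on_edge <- !is.na(biotemp) & biotemp %in% .biotemp_edges
  bt_class[on_edge] <- bt_class[on_edge] - 1L
  p_class <- matrix(
    findInterval(p_ann, .precip_edges, left.open = FALSE) + 1L,
    spec$n_rows, spec$n_cols
  )
  on_edge <- !is.na(p_ann) & p_ann %in% .precip_edges
  p_class[on_edge] <- p_class[on_edge] - 1L

  n_p <- length(.precip_edges) + 1L
  zone <- (bt_class - 1L) * n_p + p_class
  zone[is.na(biotemp) | is.na(p_ann)] <- NA_integer_

  bt_lab <- c(
    "[0,1.5]", "(1.5,3]", "(3,6]", "(6,12]", "(12,24]", "(24,30]"
  )
  p_lab <- c(
    "[0,62.5]", "(62.5,125]", "(125,250]", "(250,500]", "(500,1000]",
    "(1000,2000]", "(2000,4000]", "(4000,8000]", ">8000"
  )
  legend <- expand.grid(
    precip_class = seq_len(n_p), biotemp_class = seq_along(bt_lab)
  )
  legend <- data.frame(
    zone_code = (legend$biotemp_class - 1L) * n_p + legend$precip_class,
    biotemp = bt_lab[legend$biotemp_class],
    precip_mm = p_lab[legend$precip_class]
  )
  structure(
    list(
      spec = spec,
      zone_code = raster_layer(zone, spec),
      biotemp = raster_layer(biotemp, spec),
      legend = legend[order(legend$zone_code), ]
    ),
    class = "life_zone_raster"
  )
}
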
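#' Rescale a raster to percent of its maximum
#'
#' `out = 100 * value / max(value)` over non-nodata cells, so layers with
#' different units (biomass carbon, species richness, potential) become
#' comparable on a common 0-100 scale. Idempotent. Fails on all-nodata or
#' non-positive-maximum input.
#'
#' @param x Raster matrix.
#' @return Raster matrix in `[0, 100]` (values below 0 are possible only if
#'   the input had negative cells; the maximum maps to 100).
#' @export
rescale_percent_of_max <- function(x) {
  m <- suppressWarnings(max(x, na.rm = TRUE))
  if (!is.finite(m) || m <= 0) {
    stop("rescale needs at least one positive non-missing value", call. = FALSE)
  }
  out <- 100 * x / m
  if (!is.null(attr(x, "grid"))) out <- raster_layer(out, grid_of(x))
  out
}

#' Three-category percentile classification
#'
#' Classifies cells as low / medium / high around the 25th and 75th
#' percentiles (the printed convention "low < p25, high > p75" leaves the
#' middle half as medium, i.e. 25/50/25 rather than equal thirds;
#' `terciles = TRUE` switches to 33.3/66.7 cut points for a true
#' equal-frequency split). Percentiles use the package's left-continuous
#' weighted-quantile convention; values exactly at a threshold are medium.
#' Optional weights (e.g. [cell_areas()]) make the percentiles area-weighted.
#'
#' @param x Raster matrix.
#' @param weights Optional non-negative weight raster.
#' @param terciles Use 1/3 and 2/3 cut points instead of 25/75.
#' @return An object of class `class_raster`: `spec`, `cls` (integer raster,
#'   0 = low, 1 = medium, 2 = high, `NA` = nodata), `thresholds`.
#' @export
classify_three_bins <- function(x, weights = NULL, terciles = FALSE) {
  spec <- grid_of(x)
  vals <- x[!is.na(x)]
  if (length(vals) == 0) stop("all cells are nodata", call. = FALSE)
  if (length(unique(vals)) < 4) {
    warning("fewer than 4 distinct values; classes may be degenerate")
  }
  w <- if (is.null(weights)) rep(1, length(vals)) else weights[!is.na(x)]
  probs <- if (terciles) c(1 / 3, 2 / 3) else c(0.25, 0.75)
  thr <- weighted_quantile(vals, w, probs)
  cls <- matrix(1L, spec$n_rows, spec$n_cols)
  cls[x < thr[1]] <- 0L
  cls[x > thr[2]] <- 2L
  cls[is.na(x)] <- NA_integer_
  structure(
    list(
      spec = spec,
      cls = raster_layer(cls, spec),
      thresholds = c(lower = thr[1], upper = thr[2]),
      labels = c("low", "medium", "high")
    ),
    class = "class_raster"
  )
}

#' @export
print.class_raster <- function(x, ...) {
  tb <- table(factor(x$cls, levels = 0:2, labels = x$labels))
  cat(sprintf(
    "class_raster: thresholds (%.4g, %.4g); low %d, medium %d, high %d cells\n",
    x$thresholds[1], x$thresholds[2], tb[1], tb[2], tb[3]
  ))
  invisible(x)
}

#' Bivariate 3x3 classification
#'
#' Pairs two three-class rasters into the nine-code joint classification used
#' for bivariate trade-off maps (e.g. biomass carbon vs species richness). A
#' cell gets a code iff both inputs are non-nodata. Codes enumerate
#' `(cls_a, cls_b)` as `3 * cls_a + cls_b` in `0..8`; the legend spells out
#' the pair labels.
#'
#' @param a,b `class_raster` objects on one grid.
#' @return An object of class `bivariate_raster`: `spec`, `code` (integer
#'   raster), `legend` (data.frame code / cls_a / cls_b / label).
#' @export
bivariate_classify <- function(a, b) {
  stopifnot(inherits(a, "class_raster"), inherits(b, "class_raster"))
  stop_if_grid_mismatch(a$spec, b$spec, "class rasters")
  code <- 3L * a$cls + b$cls
  code[is.na(a$cls) | is.na(b$cls)] <- NA_integer_
  legend <- expand.grid(cls_b = 0:2, cls_a = 0:2)
  legend <- data.frame(
    code = 3L * legend$cls_a + legend$cls_b,
    cls_a = legend$cls_a,
    cls_b = legend$cls_b,
    label = paste(a$labels[legend$cls_a + 1], b$labels[legend$cls_b + 1],
      sep = " / "
    )
  )
  structure(
    list(
      spec = a$spec,
      code = raster_layer(code, a$spec),
      legend = legend[order(legend$code), ]
    ),
    class = "bivariate_raster"
  )
}

#' Stock density per 100 km^2
#'
#' Area-weighted regional density:
#' `(sum of stock over region / sum of cell area over region) x 100`, e.g.
#' Tg C per 100 km^2 for biomass carbon. Nodata stock cells are excluded from
#' both sums.
#'
#' @param stock Raster of per-cell stock (e.g. Tg C per cell).
#' @param areas [cell_areas()] raster, km^2.
#' @param region Optional logical region raster (default: whole grid).
#' @return Single number: stock per 100 km^2.
#' @export
per_area_density <- function(stock, areas, region = NULL) {
  spec <- grid_of(stock)
  stop_if_grid_mismatch(spec, grid_of(areas), "stock and areas")
  if (is.null(region)) region <- raster_layer(matrix(TRUE, spec$n_rows, spec$n_cols), spec)
  use <- region & !is.na(region) & !is.na(stock)
  a <- sum(areas[use])
  if (a <= 0) stop("zero region area", call. = FALSE)
  sum(stock[use]) / a * 100
}

#' Intact-forest overlap summaries by region
#'
#' For each region: intact area (sum of cell areas under the intact mask),
#' its share of the global intact total, and area-weighted mean aboveground
#' biomass carbon and vertebrate species richness per 100 km^2 over the
#' region. Regions are ordinary logical rasters; disjoint regions give
#' additive areas.
#'
#' @param intact Logical raster of intact-forest cells.
#' @param agb Raster of aboveground biomass carbon, Tg C per cell.
#' @param richness Raster of species richness (count per cell).
#' @param areas [cell_areas()] raster.
#' @param regions Named list of logical region rasters.
#' @return data.frame: `region`, `intact_area_km2`,
#'   `intact_share_of_total_intact`, `mean_agb_per_100km2`,
#'   `mean_richness_per_100km2`.
#' @export
intact_overlap <- function(intact, agb, richness, areas, regions) {
  spec <- grid_of(intact)
  total_intact <- sum(areas[intact & !is.na(intact)])
  rows <- lapply(names(regions), function(rg) {
    m <- regions[[rg]]
    stop_if_grid_mismatch(spec, grid_of(m), "intact mask and region")
    in_rg <- m & !is.na(m)
    if (!any(in_rg)) warning(sprintf("region '%s' is empty", rg))
    ia <- sum(areas[in_rg & intact & !is.na(intact)])
    data.frame(
      region = rg,
      intact_area_km2 = ia,
      intact_share_of_total_intact = if (total_intact > 0) ia / total_intact else NA_real_,
      mean_agb_per_100km2 = per_area_density(agb, areas, in_rg),
      mean_richness_per_100km2 = per_area_density(richness, areas, in_rg),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
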
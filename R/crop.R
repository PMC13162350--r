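#' Per-crop production layer
#'
#' Gridded rainfed production (tonnes per cell) for one crop. The analysis
#' targets the eight rainfed crops commonly grown as first-generation
#' bioenergy feedstocks (maize, cassava, oil palm, millet, rice, sorghum,
#' soybean, sugarcane), but any crop name is accepted.
#'
#' @param production Numeric raster matrix, tonnes per cell (`NA` = nodata);
#'   must be non-negative with at least one positive cell.
#' @param crop_name Crop identifier.
#' @param spec The `grid_spec`; taken from `production`'s attribute if absent.
#' @return An object of class `crop_layer`.
#' @export
crop_layer <- function(production, crop_name, spec = grid_of(production)) {
  stopifnot(is.matrix(production), is.character(crop_name), length(crop_name) == 1)
  if (any(production < 0, na.rm = TRUE)) {
    stop("production has negative cells", call. = FALSE)
  }
  if (!any(production > 0, na.rm = TRUE)) {
    stop("production has no positive cells", call. = FALSE)
  }
  structure(
    list(
      spec = spec,
      production = raster_layer(production, spec),
      crop_name = crop_name
    ),
    class = "crop_layer"
  )
}

#' @export
print.crop_layer <- function(x, ...) {
  cat(sprintf(
    "crop_layer [%s]: %d producing cells, total %.4g t\n",
    x$crop_name, sum(x$production > 0, na.rm = TRUE),
    sum(x$production, na.rm = TRUE)
  ))
  invisible(x)
}
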
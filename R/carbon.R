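#' Crop carbon-accounting fractions
#'
#' Fractions converting fresh harvested production into fixed carbon:
#' dry-matter fraction of fresh mass, shoot fraction of biomass, carbon
#' fraction of dry biomass, and a capture efficiency for negative-emission
#' accounting (1 by default, so "potential" equals crop carbon uptake; any
#' life-cycle discount is user-supplied).
#'
#' @param crop_name Crop identifier.
#' @param f_dry,f_shoot,f_carbon Fractions in `(0, 1]`.
#' @param capture_efficiency Fraction in `(0, 1]`.
#' @return An object of class `crop_carbon_params`.
#' @export
crop_carbon_params <- function(crop_name, f_dry, f_shoot, f_carbon,
                               capture_efficiency = 1) {
  for (v in list(f_dry, f_shoot, f_carbon, capture_efficiency)) {
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0 || v > 1) {
      stop("carbon fractions must be single values in (0, 1]", call. = FALSE)
    }
  }
  structure(
    list(
      crop_name = crop_name, f_dry = f_dry, f_shoot = f_shoot,
      f_carbon = f_carbon, capture_efficiency = capture_efficiency
    ),
    class = "crop_carbon_params"
  )
}

#' Cropland net primary production
#'
#' Per-cell cropland NPP is the product of total production, the fraction of
#' dry biomass, the fraction of biomass in shoots, and the carbon fraction of
#' dry biomass, converted from tonnes C to Tg C (x 1e-6). With
#' `shoot_as_divisor = TRUE` the shoot fraction divides instead of
#' multiplies, i.e. harvested shoots are scaled up to whole-plant biomass as
#' in harvest-index accounting; the default multiplies, counting shoot carbon
#' only.
#'
#' @param crop A [crop_layer()].
#' @param params A [crop_carbon_params()] for that crop.
#' @param shoot_as_divisor Logical; see Details.
#' @return Raster matrix of cropland NPP, Tg C per cell per year, with
#'   attribute `kind = "cropland_npp"`.
#' @export
cropland_npp <- function(crop, params, shoot_as_divisor = FALSE) {
  stopifnot(inherits(crop, "crop_layer"))
  if (!inherits(params, "crop_carbon_params")) {
    stop(sprintf("missing carbon params for crop '%s'", crop$crop_name),
      call. = FALSE
    )
  }
  shoot <- if (shoot_as_divisor) 1 / params$f_shoot else params$f_shoot
  npp <- crop$production * params$f_dry * shoot * params$f_carbon * 1e-6
  npp <- raster_layer(npp, crop$spec)
  attr(npp, "kind") <- "cropland_npp"
  attr(npp, "units") <- "Tg C / cell / yr"
  npp
}

#' Natural-vegetation NPP residual
#'
#' On cells holding any of the analyzed crops, subtracts total cropland NPP
#' from total NPP to isolate the natural-vegetation contribution; elsewhere
#' the residual equals total NPP. Because the two rasters are estimated
#' independently, the difference can go negative; negative residuals are
#' clipped to 0 and the clip count is recorded in attribute `n_clipped` so
#' the loss is visible.
#'
#' @param total_npp Raster of total NPP (Tg C / cell / yr).
#' @param cropland Raster of cropland NPP summed over all crops, same grid.
#' @return Raster of natural NPP with attributes `kind = "natural_npp"` and
#'   `n_clipped`.
#' @export
natural_npp_residual <- function(total_npp, cropland) {
  stop_if_grid_mismatch(grid_of(total_npp), grid_of(cropland),
    "total and cropland NPP"
  )
  has_crop <- !is.na(cropland) & cropland > 0
  residual <- total_npp
  residual[has_crop] <- total_npp[has_crop] - cropland[has_crop]
  clipped <- !is.na(residual) & residual < 0
  residual[clipped] <- 0
  residual <- raster_layer(residual, grid_of(total_npp))
  attr(residual, "kind") <- "natural_npp"
  attr(residual, "n_clipped") <- sum(clipped)
  residual
}

#' Negative-emission potential of bioenergy cropping
#'
#' Per-crop potential is cropland NPP times the crop's capture efficiency; in
#' cells where several crops are present the combined potential is the mean
#' over the crops present there. Per-crop distribution summaries report the
#' 5th, 25th, 50th, 75th and 95th percentiles of cell-level potential over
#' producing cells.
#'
#' @param crops Named list of [crop_layer()].
#' @param params Named list of [crop_carbon_params()], one per crop.
#' @param shoot_as_divisor Passed to [cropland_npp()].
#' @return List: `potential` (combined raster, Tg C / cell / yr), `per_crop`
#'   (list of per-crop rasters), `summaries` (data.frame of per-crop
#'   quantiles).
#' @export
negative_emission_potential <- function(crops, params, shoot_as_divisor = FALSE) {
  stopifnot(length(crops) >= 1)
  spec <- crops[[1]]$spec
  per_crop <- list()
  acc <- matrix(0, spec$n_rows, spec$n_cols)
  n_present <- matrix(0L, spec$n_rows, spec$n_cols)
  summaries <- list()
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  for (nm in names(crops)) {
    cp <- crops[[nm]]
    stop_if_grid_mismatch(spec, cp$spec, "crop layers")
    pot <- cropland_npp(cp, params[[nm]], shoot_as_divisor) *
      params[[nm]]$capture_efficiency
    per_crop[[nm]] <- raster_layer(pot, spec)
    present <- !is.na(cp$production) & cp$production > 0
    acc[present] <- acc[present] + pot[present]
    n_present[present] <- n_present[present] + 1L
    qv <- stats::quantile(pot[present], qs, names = FALSE)
    summaries[[nm]] <- data.frame(
      crop = nm, q05 = qv[1], q25 = qv[2], q50 = qv[3], q75 = qv[4],
      q95 = qv[5], stringsAsFactors = FALSE
    )
  }
  combined <- matrix(NA_real_, spec$n_rows, spec$n_cols)
  any_crop <- n_present > 0
  combined[any_crop] <- acc[any_crop] / n_present[any_crop]
  combined <- raster_layer(combined, spec)
  attr(combined, "kind") <- "nep_potential"
  list(
    potential = combined,
    per_crop = per_crop,
    summaries = do.call(rbind, summaries)
  )
}

#' Remaining negative-emission potential under future climate
#'
#' For each scenario x period mask, the fraction of regional potential that
#' stays inside the SCS: `remaining = sum(potential over region cells inside)
#' / sum(potential over region cells)`, and `reduction = 1 - remaining`.
#' Cells with an undefined mask (nodata future climate) are excluded from
#' both sums. A zero regional potential is flagged with `NA` rather than
#' reported as 0.
#'
#' @param potential Raster of potential (e.g. a per-crop layer from
#'   [negative_emission_potential()]).
#' @param masks Nested named list `masks[[scenario]][[period]]` of `scs_mask`.
#' @param region Logical region raster (default tropics).
#' @return data.frame: `crop`, `scenario`, `period`, `remaining`, `reduction`.
#' @export
future_potential_change <- function(potential, masks, region = NULL) {
  spec <- grid_of(potential)
  if (is.null(region)) region <- tropics_mask(spec)
  pot <- potential
  pot[is.na(pot)] <- 0
  in_region <- region & !is.na(region)
  rows <- list()
  for (scn in names(masks)) {
    for (per in names(masks[[scn]])) {
      mask <- masks[[scn]][[per]]
      stopifnot(inherits(mask, "scs_mask"))
      stop_if_grid_mismatch(spec, mask$spec, "potential and mask")
      defined <- in_region & !is.na(mask$inside)
      denom <- sum(pot[defined])
      remaining <- if (denom > 0) {
        sum(pot[defined & mask$inside]) / denom
      } else {
        warning("zero regional potential; remaining fraction undefined")
        NA_real_
      }
      rows[[length(rows) + 1]] <- data.frame(
        crop = mask$crop_name, scenario = scn, period = per,
        remaining = remaining, reduction = 1 - remaining,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
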
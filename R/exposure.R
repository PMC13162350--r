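#' Production-weighted exposure outside the safe climate space
#'
#' Given an SCS classification mask and a crop's production layer, computes
#' the share of regional production occurring in cells classified outside the
#' envelope: `share_outside = production_outside / production_total`, both
#' sums taken over region cells with a defined (non-nodata) mask. The default
#' region is the tropics (`|lat| <= 23.5` deg). Cells with production but an
#' undefined mask (nodata future climate) are excluded from both sums and
#' their mass is reported in the `excluded` column. A region with zero total
#' production yields `share_outside = NA` with a warning rather than a silent
#' zero.
#'
#' @param mask An `scs_mask` from [classify_cells()].
#' @param crop A [crop_layer()] on the same grid.
#' @param region Logical region raster (default: [tropics_mask()] of the
#'   grid).
#' @param region_name Label recorded in the output.
#' @return One-row data.frame: `crop`, `region`, `scenario`, `period`,
#'   `production_total`, `production_outside`, `share_outside`, `excluded`.
#' @export
exposure_share <- function(mask, crop, region = NULL, region_name = "tropics") {
  stopifnot(inherits(mask, "scs_mask"), inherits(crop, "crop_layer"))
  stop_if_grid_mismatch(mask$spec, crop$spec, "mask and crop")
  if (is.null(region)) {
    region <- tropics_mask(mask$spec)
  } else {
    stop_if_grid_mismatch(mask$spec, grid_of(region), "mask and region")
  }
  prod <- crop$production
  prod[is.na(prod)] <- 0
  in_region <- region & !is.na(region)
  defined <- in_region & !is.na(mask$inside)
  total <- sum(prod[defined])
  outside <- sum(prod[defined & !mask$inside])
  excluded <- sum(prod[in_region & is.na(mask$inside)])
  share <- if (total > 0) {
    outside / total
  } else {
    warning(sprintf(
      "zero production for crop '%s' in region '%s'; share undefined",
      crop$crop_name, region_name
    ))
    NA_real_
  }
  data.frame(
    crop = crop$crop_name,
    region = region_name,
    scenario = mask$scenario,
    period = mask$period,
    production_total = total,
    production_outside = outside,
    share_outside = share,
    excluded = excluded,
    stringsAsFactors = FALSE
  )
}

#' Exposure table over crops, regions, scenarios and periods
#'
#' For every scenario x period, takes the multimodel [ensemble_mean()] of the
#' member cubes, aggregates to annual climate, classifies each crop's cells
#' against its fitted envelope, and accumulates [exposure_share()] rows per
#' region. Ensemble averaging precedes annual aggregation (both are linear,
#' but the order is fixed for reproducibility). Missing periods are an error,
#' never interpolated.
#'
#' @param envelopes Named list of `scs_envelope`, one per crop.
#' @param ensembles Nested named list: `ensembles[[scenario]][[period]]` is a
#'   list of [climate_cube()] ensemble members (a single cube is accepted).
#' @param crops Named list of [crop_layer()], names matching `envelopes`.
#' @param regions Named list of logical region rasters (default: tropics
#'   only).
#' @return Long-form data.frame sorted by crop, region, scenario, period.
#' @export
exposure_timeseries <- function(envelopes, ensembles, crops, regions = NULL) {
  stopifnot(length(envelopes) > 0, length(ensembles) > 0)
  if (!setequal(names(envelopes), names(crops))) {
    stop("envelopes and crops must cover the same crop names", call. = FALSE)
  }
  spec <- crops[[1]]$spec
  if (is.null(regions)) regions <- list(tropics = tropics_mask(spec))

  rows <- list()
  for (scn in names(ensembles)) {
    periods <- ensembles[[scn]]
    if (length(periods) == 0) {
      stop(sprintf("scenario '%s' has no periods", scn), call. = FALSE)
    }
    for (per in names(periods)) {
      members <- periods[[per]]
      if (inherits(members, "climate_cube")) members <- list(members)
      if (length(members) == 0) {
        stop(sprintf("missing ensemble for %s / %s", scn, per), call. = FALSE)
      }
      ann <- annual_aggregate(
        ensemble_mean(members, source = list(scenario = scn, period = per))
      )
      for (cp in names(envelopes)) {
        mask <- classify_cells(envelopes[[cp]], ann, scenario = scn, period = per)
        for (rg in names(regions)) {
          rows[[length(rows) + 1]] <-
            exposure_share(mask, crops[[cp]], regions[[rg]], region_name = rg)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$crop, out$region, out$scenario, out$period), ]
  rownames(out) <- NULL
  out
}
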
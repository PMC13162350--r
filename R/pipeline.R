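#' Default pipeline configuration
#'
#' A complete configuration for a fully synthetic run at desk scale: a 50 x 50
#' cell grid spanning 30S-30N (so tropics masking and latitude-dependent cell
#' areas are exercised), three crops with distinct true climate envelopes, a
#' 14-member ensemble under two warming scenarios ("2C" and "2.5C") with four
#' 20-year periods, placeholder crop carbon fractions, and the ecology stack.
#' Every field can be overridden; configurations round-trip losslessly
#' through YAML ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @return Named list of class `pipeline_config`.
#' @export
default_pipeline_config <- function() {
  periods <- c("2021-2040", "2041-2060", "2061-2080", "2081-2100")
  cfg <- list(
    grid = list(
      n_rows = 50, n_cols = 50,
      lat_min = -30, lat_max = 30, lon_min = -60, lon_max = 60
    ),
    coverage_target = 0.95,
    envelope_mode = "rectangular",
    regions = list(
      tropics = list(lat = c(-23.5, 23.5), lon = c(-180, 360))
    ),
    climate = list(
      t_equator = 27, t_per_deg_lat = 0.35, seasonal_amplitude = 6,
      p_equator_mm = 2400, p_lat_scale = 25,
      noise_sd = 1, p_noise_frac = 0.15, noise_range_cells = 3,
      ocean_fraction = 0.2
    ),
    ensemble = list(
      n_models = 14, inter_model_sd = 0.3, precip_sd = 0.05,
      scenarios = list(
        "2C" = list(
          periods = periods,
          delta_t = c(1.0, 1.5, 1.8, 2.0),
          precip_scale = c(1.01, 1.02, 1.03, 1.03)
        ),
        "2.5C" = list(
          periods = periods,
          delta_t = c(1.2, 1.8, 2.2, 2.5),
          precip_scale = c(1.01, 1.03, 1.04, 1.05)
        )
      )
    ),
    crops = list(
      maize = list(
        bounds = c(t_low = 18, t_high = 27, p_low = 1100, p_high = 2300),
        total_production = 1e6, concentration = 2, frac_outside = 0.05
      ),
      oil_palm = list(
        bounds = c(t_low = 24, t_high = 28.5, p_low = 1700, p_high = 2700),
        total_production = 4e5, concentration = 2, frac_outside = 0.05
      ),
      soybean = list(
        bounds = c(t_low = 17, t_high = 25, p_low = 1000, p_high = 2200),
        total_production = 8e5, concentration = 2, frac_outside = 0.05
      )
    ),
    # placeholder carbon-accounting fractions; supply crop-specific values
    # from the literature for real analyses
    carbon = list(
      maize = list(f_dry = 0.85, f_shoot = 0.5, f_carbon = 0.45, capture_efficiency = 1),
      oil_palm = list(f_dry = 0.55, f_shoot = 0.6, f_carbon = 0.47, capture_efficiency = 1),
      soybean = list(f_dry = 0.9, f_shoot = 0.45, f_carbon = 0.45, capture_efficiency = 1)
    ),
    shoot_as_divisor = FALSE,
    ecology = list(
      agb_range = c(0.01, 0.9), richness_range = c(50, 800),
      npp_range = c(0.005, 0.25), intact_fraction = 0.2,
      n_ecoregions = 5, agb_richness_cor = 0.6, noise_range_cells = 4
    ),
    terciles = FALSE,
    planted_exposure = NULL
  )
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read / write a pipeline configuration (YAML)
#' @param cfg A `pipeline_config` list.
#' @param path File path.
#' @return `read_pipeline_config()` returns the validated `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  out <- unclass(cfg)
  # YAML drops names on atomic vectors; store named vectors as maps
  for (cp in names(out$crops)) {
    out$crops[[cp]]$bounds <- as.list(out$crops[[cp]]$bounds)
  }
  if (!is.null(out$planted_exposure)) {
    out$planted_exposure$fractions <- as.list(out$planted_exposure$fractions)
  }
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # yaml drops names on named numeric vectors read back as lists; normalize
  for (cp in names(cfg$crops)) {
    cfg$crops[[cp]]$bounds <- unlist(cfg$crops[[cp]]$bounds)
  }
  cfg$planted_exposure <- if (!is.null(cfg$planted_exposure)) {
    list(
      fractions = unlist(cfg$planted_exposure$fractions),
      t_margin = cfg$planted_exposure$t_margin %||% 3
    )
  }
  class(cfg) <- c("pipeline_config", "list")
  validate_pipeline_config(cfg)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a pipeline configuration (fail fast)
#'
#' Checks grid validity, scenario/period consistency, per-crop envelope
#' bounds, and that carbon fractions exist for every crop, before any stage
#' runs, so an invalid configuration produces no partial outputs.
#'
#' @param cfg A `pipeline_config`.
#' @return `cfg`, invisibly, or an error naming the offending field.
#' @export
validate_pipeline_config <- function(cfg) {
  req <- c("grid", "coverage_target", "crops", "carbon", "ensemble", "climate")
  missing <- setdiff(req, names(cfg))
  if (length(missing) > 0) {
    stop("config lacks fields: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  do.call(grid_spec, cfg$grid) # validates
  if (cfg$coverage_target <= 0 || cfg$coverage_target > 1) {
    stop("coverage_target must lie in (0, 1]", call. = FALSE)
  }
  if (length(cfg$crops) == 0) stop("no crops configured", call. = FALSE)
  for (cp in names(cfg$crops)) {
    b <- cfg$crops[[cp]]$bounds
    if (is.null(b) || b["t_low"] >= b["t_high"] || b["p_low"] >= b["p_high"]) {
      stop("crop '", cp, "' has invalid envelope bounds", call. = FALSE)
    }
    if (is.null(cfg$carbon[[cp]])) {
      stop("no carbon params for crop '", cp, "'", call. = FALSE)
    }
  }
  if (is.null(cfg$planted_exposure)) {
    for (scn in names(cfg$ensemble$scenarios)) {
      sc <- cfg$ensemble$scenarios[[scn]]
      if (length(sc$delta_t) != length(sc$periods)) {
        stop("scenario '", scn, "': delta_t and periods differ in length",
          call. = FALSE
        )
      }
    }
  }
  invisible(cfg)
}

region_masks_from_config <- function(cfg, spec) {
  if (is.null(cfg$regions)) {
    return(list(tropics = tropics_mask(spec)))
  }
  out <- lapply(cfg$regions, function(r) {
    region_mask(spec,
      lat_range = unlist(r$lat) %||% c(-90, 90),
      lon_range = unlist(r$lon) %||% c(-180, 360)
    )
  })
  names(out) <- names(cfg$regions)
  out
}

#' Run the full analysis pipeline
#'
#' Executes the end-to-end chain on synthetic inputs: simulate baseline
#' climate, crops and ecology layers; fit one SCS envelope per crop; build
#' the future ensemble (or planted-exposure futures); classify each
#' scenario x period ensemble mean; accumulate the exposure table; compute
#' cropland NPP, the natural-NPP residual and negative-emission potential and
#' its projected change; and classify the carbon/biodiversity trade-off
#' layers. All tables are written as CSV, rasters as `.asc`, envelopes as
#' JSON, plus a run manifest (config hash, seed, package version, per-stage
#' accounting). Reruns with identical config and seed reproduce every output
#' byte-identically.
#'
#' @param cfg A `pipeline_config` (default [default_pipeline_config()]).
#' @param out_dir Output directory, created if needed.
#' @param seed Master seed; every stage derives its own stream from it.
#' @return Invisibly, a list with the in-memory results (`exposure`,
#'   `envelopes`, `carbon_change`, `regional_summary`, `truths`, paths).
#' @export
run_pipeline <- function(cfg = default_pipeline_config(), out_dir, seed = 1L) {
  validate_pipeline_config(cfg)
  spec <- do.call(grid_spec, cfg$grid)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  note <- function(...) {
    log[[length(log) + 1]] <<- sprintf(...)
  }

  # --- simulate ------------------------------------------------------------
  baseline <- do.call(generate_climate_baseline, c(
    list(spec = spec, seed = sub_seed(seed, "baseline")), cfg$climate
  ))
  base_ann <- annual_aggregate(baseline)
  land <- raster_layer(!is.na(base_ann$t_ann), spec)
  note("simulate: %d land cells of %d", sum(land), length(land))

  crops <- list()
  truths <- list()
  for (cp in names(cfg$crops)) {
    cc <- cfg$crops[[cp]]
    g <- generate_crop_production(
      spec, base_ann,
      crop_name = cp,
      envelope_bounds_true = cc$bounds,
      total_production = cc$total_production %||% 1e6,
      concentration = cc$concentration %||% 2,
      frac_outside_baseline = cc$frac_outside %||% 0.05,
      seed = sub_seed(seed, paste0("crop-", cp))
    )
    crops[[cp]] <- g$crop
    truths[[cp]] <- g$truth
  }
  eco <- do.call(generate_ecology_layers, c(
    list(spec = spec, land_mask = land, seed = sub_seed(seed, "ecology")),
    cfg$ecology
  ))

  # --- envelopes -----------------------------------------------------------
  envelopes <- list()
  for (cp in names(crops)) {
    envelopes[[cp]] <- fit_envelope(
      base_ann, crops[[cp]],
      coverage_target = cfg$coverage_target,
      mode = cfg$envelope_mode %||% "rectangular"
    )
    write_envelope(envelopes[[cp]], file.path(out_dir, paste0("envelope_", cp, ".json")))
    note(
      "envelope %s: coverage %.4f, excluded mass %.4g t",
      cp, envelopes[[cp]]$achieved_coverage, envelopes[[cp]]$excluded_mass
    )
  }

  # --- future climates -----------------------------------------------------
  regions <- region_masks_from_config(cfg, spec)
  planted <- !is.null(cfg$planted_exposure)
  if (planted) {
    # per-crop deterministic futures with an exactly planted outside share
    exposure <- list()
    masks <- list()
    planted_truth <- list()
    for (cp in names(crops)) {
      pe <- generate_future_with_exposure(
        baseline, coef(envelopes[[cp]]), crops[[cp]],
        fractions = cfg$planted_exposure$fractions,
        t_margin = cfg$planted_exposure$t_margin %||% 3,
        seed = sub_seed(seed, paste0("planted-", cp))
      )
      planted_truth[[cp]] <- cbind(crop = cp, pe$truth)
      ens <- list(planted = pe$cubes)
      exposure[[cp]] <- exposure_timeseries(
        envelopes[cp], ens, crops[cp], regions
      )
      masks[[cp]] <- lapply(pe$cubes, function(cb) {
        classify_cells(envelopes[[cp]], annual_aggregate(cb),
          scenario = "planted", period = cb$source$period
        )
      })
    }
    exposure <- do.call(rbind, exposure)
    exposure <- exposure[order(exposure$crop, exposure$region, exposure$scenario, exposure$period), ]
    rownames(exposure) <- NULL
    truth_tab <- do.call(rbind, planted_truth)
  } else {
    ensembles <- generate_future_ensemble(
      baseline, cfg$ensemble$scenarios,
      n_models = cfg$ensemble$n_models %||% 14,
      inter_model_sd = cfg$ensemble$inter_model_sd %||% 0.3,
      precip_sd = cfg$ensemble$precip_sd %||% 0.05,
      seed = sub_seed(seed, "ensemble")
    )
    exposure <- exposure_timeseries(envelopes, ensembles, crops, regions)
    masks <- list()
    for (cp in names(crops)) {
      masks[[cp]] <- list()
      for (scn in names(ensembles)) {
        for (per in names(ensembles[[scn]])) {
          ann <- annual_aggregate(ensemble_mean(ensembles[[scn]][[per]]))
          masks[[cp]][[paste(scn, per, sep = "|")]] <-
            classify_cells(envelopes[[cp]], ann, scenario = scn, period = per)
        }
      }
    }
    truth_tab <- NULL
  }
  write.csv(
    exposure[, c(
      "crop", "region", "scenario", "period",
      "production_total", "production_outside", "share_outside"
    )],
    file.path(out_dir, "exposure.csv"),
    row.names = FALSE
  )

  # --- carbon --------------------------------------------------------------
  params <- lapply(names(cfg$carbon), function(cp) {
    do.call(crop_carbon_params, c(list(crop_name = cp), cfg$carbon[[cp]]))
  })
  names(params) <- names(cfg$carbon)
  nep <- negative_emission_potential(
    crops, params,
    shoot_as_divisor = isTRUE(cfg$shoot_as_divisor)
  )
  cropland_total <- Reduce(`+`, lapply(names(crops), function(cp) {
    n <- cropland_npp(crops[[cp]], params[[cp]], isTRUE(cfg$shoot_as_divisor))
    n[is.na(n)] <- 0
    n
  }))
  cropland_total <- raster_layer(cropland_total, spec)
  natural <- natural_npp_residual(eco$total_npp, cropland_total)
  note("carbon: %d residual cells clipped at 0", attr(natural, "n_clipped"))

  change <- list()
  for (cp in names(crops)) {
    mlist <- masks[[cp]]
    nested <- split(mlist, vapply(mlist, function(m) {
      if (is.na(m$scenario)) "planted" else m$scenario
    }, character(1)))
    nested <- lapply(nested, function(l) {
      names(l) <- vapply(l, `[[`, character(1), "period")
      l
    })
    change[[cp]] <- future_potential_change(
      nep$per_crop[[cp]], nested,
      region = regions[[1]]
    )
  }
  carbon_change <- do.call(rbind, change)
  rownames(carbon_change) <- NULL
  write.csv(carbon_change, file.path(out_dir, "carbon_change.csv"), row.names = FALSE)
  write.csv(nep$summaries, file.path(out_dir, "potential_quantiles.csv"), row.names = FALSE)
  write_raster(nep$potential, file.path(out_dir, "nep_potential.asc"))
  write_raster(natural, file.path(out_dir, "natural_npp.asc"))

  # --- trade-offs ----------------------------------------------------------
  areas <- cell_areas(spec)
  pot_for_class <- nep$potential
  agb_cls <- classify_three_bins(
    rescale_percent_of_max(eco$agb),
    terciles = isTRUE(cfg$terciles)
  )
  rich_cls <- classify_three_bins(
    rescale_percent_of_max(eco$richness),
    terciles = isTRUE(cfg$terciles)
  )
  bivar <- bivariate_classify(agb_cls, rich_cls)
  rs <- intact_overlap(eco$intact_mask, eco$agb, eco$richness, areas, regions)
  write.csv(rs, file.path(out_dir, "regional_summary.csv"), row.names = FALSE)
  write_raster(bivar$code, file.path(out_dir, "bivariate_agb_richness.asc"))
  jsonlite::write_json(bivar$legend, file.path(out_dir, "bivariate_legend.json"))
  write_raster(agb_cls$cls, file.path(out_dir, "agb_class.asc"))
  write_raster(rich_cls$cls, file.path(out_dir, "richness_class.asc"))
  lz <- holdridge_classify(baseline)
  write_raster(lz$zone_code, file.path(out_dir, "life_zones.asc"))
  write.csv(lz$legend, file.path(out_dir, "life_zone_legend.csv"), row.names = FALSE)

  # --- manifest ------------------------------------------------------------
  cfg_yaml <- yaml::as.yaml(unclass(cfg), precision = 15)
  manifest <- list(
    config_hash = fnv1a_hex(cfg_yaml),
    seed = seed,
    package_version = as.character(utils::packageVersion("scsbec")),
    stages = unlist(log),
    synthetic_truth = lapply(truths, function(tr) {
      list(
        crop_name = tr$crop_name,
        envelope_bounds_true = as.list(tr$envelope_bounds_true),
        planted_outside_fraction = tr$planted_outside_fraction,
        seed = tr$seed
      )
    }),
    planted_exposure_truth = truth_tab
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows"
  )

  invisible(list(
    exposure = exposure,
    envelopes = envelopes,
    carbon_change = carbon_change,
    potential = nep$potential,
    natural_npp = natural,
    regional_summary = rs,
    truths = truths,
    planted_truth = truth_tab,
    masks = masks,
    out_dir = out_dir
  ))
}
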
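#' Spatially autocorrelated standard noise field
#'
#' The package's random fields are smoothed white noise: an i.i.d. standard
#' normal matrix (drawn column-major) is convolved along rows and then columns
#' with a normalized Gaussian kernel of standard deviation `range_cells`
#' (truncated at 3 sd) using replicated-edge padding, and the result is
#' standardized to zero mean and unit variance. This is the documented recipe
#' every generator uses, so tests can re-draw it independently.
#'
#' @param n_rows,n_cols Field dimensions.
#' @param range_cells Kernel standard deviation in cells; 0 gives white noise.
#' @return Matrix with sample mean 0 and sample sd 1 (all-zero if the grid
#'   has a single cell).
#' @export
smooth_noise_field <- function(n_rows, n_cols, range_cells = 3) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (range_cells > 0) {
    z <- smooth_matrix(z, range_cells)
  }
  s <- stats::sd(z)
  if (!is.finite(s) || s == 0) {
    return(matrix(0, n_rows, n_cols))
  }
  (z - mean(z)) / s
}

# replicated-edge Gaussian moving average along both axes
smooth_matrix <- function(z, range_cells) {
  half <- ceiling(3 * range_cells)
  k <- stats::dnorm(-half:half, sd = range_cells)
  k <- k / sum(k)
  smooth_axis <- function(n) {
    s <- matrix(0, n, n)
    for (i in seq_len(n)) {
      idx <- pmin(pmax(i + (-half:half), 1), n)
      for (j in seq_along(idx)) s[i, idx[j]] <- s[i, idx[j]] + k[j]
    }
    s
  }
  sr <- smooth_axis(nrow(z))
  sc <- smooth_axis(ncol(z))
  sr %*% z %*% t(sc)
}

#' Generate a synthetic baseline climate cube
#'
#' Emulates a gridded 30-year baseline climatology: monthly mean temperature
#' follows a latitudinal gradient with a hemispherically opposed seasonal
#' cycle plus smooth spatial noise, and monthly precipitation follows a
#' Gaussian-in-latitude wet belt with multiplicative smooth noise, clamped at
#' zero. An optional contiguous "ocean" share of cells is nodata in every
#' layer. Identical `(seed, params)` give bit-identical cubes.
#'
#' The deterministic parts of the recipe, for cell latitude `lat` and month
#' `m`:
#' \deqn{T_m(lat) = t_{eq} - g |lat| + A (lat/45) \cos(2\pi (m - 7)/12)}
#' \deqn{P_m(lat) = (p_{eq}/12) \exp(-lat^2 / (2 s^2))}
#' with noise `noise_sd * F_m` added to each monthly temperature and factor
#' `max(0, 1 + p_noise_frac * G_m)` applied to each monthly precipitation,
#' where `F_1..F_12, G_1..G_12` are [smooth_noise_field()] draws taken in that
#' order (after the single ocean-field draw).
#'
#' @param spec A `grid_spec`.
#' @param t_equator Annual-mean temperature at the equator, degC.
#' @param t_per_deg_lat Cooling per degree of absolute latitude, degC/deg.
#' @param seasonal_amplitude Seasonal half-range at 45 deg latitude, degC.
#' @param p_equator_mm Annual precipitation at the equator, mm/yr.
#' @param p_lat_scale Gaussian latitude scale of the wet belt, degrees.
#' @param noise_sd Temperature noise standard deviation, degC (>= 0).
#' @param p_noise_frac Relative precipitation noise amplitude (>= 0).
#' @param noise_range_cells Autocorrelation range of the noise, cells.
#' @param ocean_fraction Fraction of cells set to nodata everywhere.
#' @param seed RNG seed.
#' @return A [climate_cube()] tagged `"baseline"`.
#' @export
generate_climate_baseline <- function(spec,
                                      t_equator = 27,
                                      t_per_deg_lat = 0.35,
                                      seasonal_amplitude = 6,
                                      p_equator_mm = 2400,
                                      p_lat_scale = 25,
                                      noise_sd = 1,
                                      p_noise_frac = 0.15,
                                      noise_range_cells = 3,
                                      ocean_fraction = 0.2,
                                      seed = 1L) {
  stopifnot(
    is.finite(noise_sd), noise_sd >= 0,
    is.finite(p_noise_frac), p_noise_frac >= 0,
    is.finite(t_equator), is.finite(t_per_deg_lat),
    is.finite(p_equator_mm), p_equator_mm >= 0,
    ocean_fraction >= 0, ocean_fraction < 1
  )
  lat <- grid_lat(spec)
  nr <- spec$n_rows
  nc <- spec$n_cols
  with_seed(seed, {
    ocean <- matrix(FALSE, nr, nc)
    if (ocean_fraction > 0) {
      f <- smooth_noise_field(nr, nc, noise_range_cells * 2)
      n_ocean <- round(ocean_fraction * nr * nc)
      if (n_ocean > 0) {
        ocean[order(f, decreasing = TRUE)[seq_len(n_ocean)]] <- TRUE
      }
    }
    tavg <- array(NA_real_, c(nr, nc, 12))
    prec <- array(NA_real_, c(nr, nc, 12))
    t_base <- t_equator - t_per_deg_lat * abs(lat)
    amp <- seasonal_amplitude * lat / 45
    p_month <- p_equator_mm / 12 * exp(-lat^2 / (2 * p_lat_scale^2))
    for (m in 1:12) {
      tm <- matrix(t_base + amp * cos(2 * pi * (m - 7) / 12), nr, nc)
      if (noise_sd > 0) {
        tm <- tm + noise_sd * smooth_noise_field(nr, nc, noise_range_cells)
      }
      tavg[, , m] <- tm
    }
    for (m in 1:12) {
      pm <- matrix(p_month, nr, nc)
      if (p_noise_frac > 0) {
        pm <- pm * pmax(0, 1 + p_noise_frac *
          smooth_noise_field(nr, nc, noise_range_cells))
      }
      prec[, , m] <- pm
    }
    for (m in 1:12) {
      tm <- tavg[, , m]
      tm[ocean] <- NA
      tavg[, , m] <- tm
      pm <- prec[, , m]
      pm[ocean] <- NA
      prec[, , m] <- pm
    }
    climate_cube(spec, tavg = tavg, prec = prec, source = "baseline")
  })
}

#' Generate a synthetic multimodel future ensemble
#'
#' Each ensemble member is the baseline cube plus a scenario- and
#' period-specific warming offset and a model-specific perturbation:
#' temperature gains `delta_t + eps_T` (degC, uniform in space and month) and
#' precipitation is multiplied by `precip_scale * max(0, 1 + eps_P)`, with
#' `eps_T ~ N(0, inter_model_sd)` and `eps_P ~ N(0, precip_sd)` drawn once
#' per (scenario, period, model), in scenario-period-model order (eps_T then
#' eps_P). With `inter_model_sd = 0` every member's temperature is exactly
#' `baseline + delta_t`.
#'
#' @param baseline A baseline [climate_cube()].
#' @param scenarios Named list; each element has `periods` (character),
#'   `delta_t` (degC per period) and optionally `precip_scale` (per period,
#'   default 1).
#' @param n_models Number of ensemble members (>= 1).
#' @param inter_model_sd Model spread of the temperature offset, degC.
#' @param precip_sd Model spread of the relative precipitation factor.
#' @param seed RNG seed.
#' @return Nested named list: `out[[scenario]][[period]]` is a list of
#'   `n_models` [climate_cube()] objects.
#' @export
generate_future_ensemble <- function(baseline, scenarios, n_models = 14,
                                     inter_model_sd = 0.3, precip_sd = 0.05,
                                     seed = 1L) {
  stopifnot(inherits(baseline, "climate_cube"), n_models >= 1)
  out <- list()
  with_seed(seed, {
    for (scn in names(scenarios)) {
      sc <- scenarios[[scn]]
      periods <- sc$periods
      stopifnot(length(sc$delta_t) == length(periods))
      pscale <- if (is.null(sc$precip_scale)) rep(1, length(periods)) else sc$precip_scale
      stopifnot(length(pscale) == length(periods))
      out[[scn]] <- list()
      for (i in seq_along(periods)) {
        members <- vector("list", n_models)
        for (k in seq_len(n_models)) {
          eps_t <- if (inter_model_sd > 0) stats::rnorm(1, 0, inter_model_sd) else 0
          eps_p <- if (precip_sd > 0) stats::rnorm(1, 0, precip_sd) else 0
          members[[k]] <- climate_cube(
            baseline$spec,
            tavg = baseline$tavg + sc$delta_t[i] + eps_t,
            prec = baseline$prec * pscale[i] * max(0, 1 + eps_p),
            source = list(
              model = sprintf("m%02d", k), scenario = scn, period = periods[i]
            )
          )
        }
        out[[scn]][[periods[i]]] <- members
      }
    }
  })
  out
}

#' Generate synthetic crop production with planted envelope truth
#'
#' Places production mass preferentially in cells whose baseline annual
#' climate lies inside a prescribed true envelope: inside cells get a
#' Gaussian concentration kernel in standardized envelope coordinates times
#' lognormal lumpiness, and exactly `frac_outside_baseline` of the total mass
#' goes to cells just outside the envelope (weights decay with the
#' standardized distance beyond the bounds, emulating marginal cultivation).
#' Both groups are renormalized so the raster sums to `total_production`
#' exactly and the outside mass fraction is exact.
#'
#' @param spec A `grid_spec`.
#' @param baseline_annual An `annual_climate` on `spec` (its nodata cells are
#'   excluded, e.g. ocean).
#' @param crop_name Crop identifier.
#' @param envelope_bounds_true Named numeric `(t_low, t_high, p_low, p_high)`.
#' @param total_production Total tonnes to distribute (> 0).
#' @param concentration Kernel decay rate in squared standardized envelope
#'   units; larger concentrates mass at the envelope center.
#' @param frac_outside_baseline Fraction of mass planted outside the true
#'   envelope, in `[0, 1)`.
#' @param lump_sd Lognormal sd of the cell-level lumpiness.
#' @param seed RNG seed.
#' @return List: `crop` (a [crop_layer()]) and `truth` (class
#'   `synthetic_truth`: true bounds, exact outside fraction, seed).
#' @export
generate_crop_production <- function(spec, baseline_annual,
                                     crop_name = "maize",
                                     envelope_bounds_true = c(
                                       t_low = 20, t_high = 28,
                                       p_low = 1200, p_high = 2400
                                     ),
                                     total_production = 1e6,
                                     concentration = 2,
                                     frac_outside_baseline = 0.05,
                                     lump_sd = 0.5,
                                     seed = 1L) {
  b <- envelope_bounds_true
  stopifnot(
    b["t_low"] < b["t_high"], b["p_low"] < b["p_high"],
    total_production > 0,
    frac_outside_baseline >= 0, frac_outside_baseline < 1
  )
  t <- baseline_annual$t_ann
  p <- baseline_annual$p_ann
  ok <- !is.na(t) & !is.na(p)
  inside <- ok & t >= b["t_low"] & t <= b["t_high"] &
    p >= b["p_low"] & p <= b["p_high"]
  if (!any(inside)) {
    stop("no cells fall inside envelope_bounds_true", call. = FALSE)
  }
  outside <- ok & !inside
  if (frac_outside_baseline > 0 && !any(outside)) {
    stop("no cells available outside envelope_bounds_true", call. = FALSE)
  }

  ct <- (b["t_low"] + b["t_high"]) / 2
  cp <- (b["p_low"] + b["p_high"]) / 2
  ht <- (b["t_high"] - b["t_low"]) / 2
  hp <- (b["p_high"] - b["p_low"]) / 2
  u <- (t - ct) / ht
  v <- (p - cp) / hp

  prod <- matrix(0, spec$n_rows, spec$n_cols)
  with_seed(seed, {
    w_in <- exp(-concentration * (u[inside]^2 + v[inside]^2)) *
      exp(stats::rnorm(sum(inside), 0, lump_sd))
    prod[inside] <- w_in / sum(w_in) *
      total_production * (1 - frac_outside_baseline)
    if (frac_outside_baseline > 0) {
      # distance beyond the envelope in standardized units
      d <- pmax(abs(u[outside]) - 1, 0) + pmax(abs(v[outside]) - 1, 0)
      w_out <- exp(-4 * d) * exp(stats::rnorm(sum(outside), 0, lump_sd))
      prod[outside] <- w_out / sum(w_out) *
        total_production * frac_outside_baseline
    }
  })
  prod[!ok] <- NA
  crop <- crop_layer(prod, crop_name, spec)
  achieved <- sum(prod[outside]) / sum(prod[ok])
  truth <- structure(
    list(
      crop_name = crop_name,
      envelope_bounds_true = b,
      planted_outside_fraction = achieved,
      seed = seed
    ),
    class = "synthetic_truth"
  )
  list(crop = crop, truth = truth)
}

#' Generate synthetic ecology layers
#'
#' Produces the ecological stack the trade-off analysis consumes: aboveground
#' biomass carbon (AGB) and vertebrate species richness as spatially
#' autocorrelated fields with an exactly planted sample correlation
#' (richness is built as `rho * AGB_std + sqrt(1 - rho^2) * resid`, with the
#' residual field sample-orthogonalized against AGB, so `cor(agb, richness)`
#' equals `agb_richness_cor` exactly on land cells), total NPP as another
#' smooth field, an intact-forest mask covering a planted share of land cells
#' (top cells of a smooth field, so the mask is contiguous), and ecoregion
#' classes that partition the land cells into equal-count slices of a smooth
#' field.
#'
#' @param spec A `grid_spec`.
#' @param agb_range,richness_range,npp_range Length-2 output ranges (min-max
#'   rescaling targets): AGB in Tg C per cell, richness in species, NPP in
#'   Tg C per cell per year.
#' @param intact_fraction Share of land cells in the intact mask, `[0, 1]`.
#' @param n_ecoregions Number of ecoregion classes (>= 1).
#' @param agb_richness_cor Planted AGB-richness correlation in `[0, 1]`.
#' @param noise_range_cells Autocorrelation range, cells.
#' @param land_mask Logical raster of land cells (default: all cells).
#' @param seed RNG seed.
#' @return List of rasters: `agb`, `richness`, `total_npp`, `intact_mask`
#'   (logical), `ecoregion` (integer classes, `NA` off land).
#' @export
generate_ecology_layers <- function(spec,
                                    agb_range = c(0.01, 0.9),
                                    richness_range = c(50, 800),
                                    npp_range = c(0.005, 0.25),
                                    intact_fraction = 0.2,
                                    n_ecoregions = 5,
                                    agb_richness_cor = 0.6,
                                    noise_range_cells = 4,
                                    land_mask = NULL,
                                    seed = 1L) {
  stopifnot(
    agb_range[1] < agb_range[2], richness_range[1] < richness_range[2],
    npp_range[1] < npp_range[2],
    intact_fraction >= 0, intact_fraction <= 1,
    n_ecoregions >= 1, agb_richness_cor >= 0, agb_richness_cor <= 1
  )
  nr <- spec$n_rows
  nc <- spec$n_cols
  if (is.null(land_mask)) land_mask <- matrix(TRUE, nr, nc)
  land <- which(land_mask & !is.na(land_mask))
  if (length(land) < 2) stop("need at least two land cells", call. = FALSE)

  rescale_to <- function(v, rng) {
    if (max(v) == min(v)) {
      return(rep(mean(rng), length(v)))
    }
    rng[1] + (v - min(v)) / (max(v) - min(v)) * (rng[2] - rng[1])
  }
  std <- function(v) (v - mean(v)) / stats::sd(v)

  with_seed(seed, {
    f_agb <- smooth_noise_field(nr, nc, noise_range_cells)[land]
    f_res <- smooth_noise_field(nr, nc, noise_range_cells)[land]
    f_intact <- smooth_noise_field(nr, nc, noise_range_cells)[land]
    f_eco <- smooth_noise_field(nr, nc, noise_range_cells)[land]
    f_npp <- smooth_noise_field(nr, nc, noise_range_cells)[land]

    a <- std(f_agb)
    # sample-orthogonalize the residual field against the AGB field
    r <- f_res - a * sum(a * f_res) / sum(a * a)
    r <- if (stats::sd(r) > 0) std(r) else r
    rich <- agb_richness_cor * a + sqrt(1 - agb_richness_cor^2) * r

    mk <- function(vals) {
      m <- matrix(NA_real_, nr, nc)
      m[land] <- vals
      raster_layer(m, spec)
    }
    agb <- mk(rescale_to(a, agb_range))
    richness <- mk(rescale_to(rich, richness_range))
    total_npp <- mk(rescale_to(std(f_npp), npp_range))

    intact <- matrix(FALSE, nr, nc)
    n_intact <- round(intact_fraction * length(land))
    if (n_intact > 0) {
      intact[land[order(f_intact, decreasing = TRUE)[seq_len(n_intact)]]] <- TRUE
    }
    intact[-land] <- NA

    eco <- matrix(NA_integer_, nr, nc)
    qs <- stats::quantile(f_eco, probs = seq(0, 1, length.out = n_ecoregions + 1))
    cls <- findInterval(f_eco, qs[-c(1, length(qs))]) + 1L
    eco[land] <- cls

    list(
      agb = agb, richness = richness, total_npp = total_npp,
      intact_mask = raster_layer(intact, spec),
      ecoregion = raster_layer(eco, spec)
    )
  })
}

#' Plant an exact exposure fraction into future climates
#'
#' Builds one deterministic future climate cube per period in which a known
#' fraction of a crop's production mass sits outside a given envelope: every
#' producing cell that starts outside the rectangular bounds has its monthly
#' climate moved to the envelope center (so the baseline exposure is zero),
#' then producing cells are visited in seeded random order and pushed past
#' the upper temperature limit (`t_high + t_margin`, uniform across months)
#' until the accumulated production mass best approximates the requested
#' fraction. The achieved fraction is recorded exactly, cell granularity
#' included.
#'
#' @param baseline A baseline [climate_cube()].
#' @param bounds Named rectangular limits `(t_low, t_high, p_low, p_high)`,
#'   typically `coef()` of a fitted envelope.
#' @param crop A [crop_layer()] on the same grid.
#' @param fractions Named numeric vector: requested outside fraction per
#'   period label.
#' @param t_margin Warming margin beyond `t_high`, degC.
#' @param seed RNG seed.
#' @return List: `cubes` (named list of [climate_cube()], one per period) and
#'   `truth` (data.frame: period, requested, planted_outside_fraction).
#' @export
generate_future_with_exposure <- function(baseline, bounds, crop, fractions,
                                          t_margin = 3, seed = 1L) {
  stopifnot(inherits(baseline, "climate_cube"), inherits(crop, "crop_layer"))
  stop_if_grid_mismatch(baseline$spec, crop$spec, "baseline and crop")
  stopifnot(!is.null(names(fractions)), all(fractions >= 0 & fractions < 1))
  b <- bounds
  ann <- annual_aggregate(baseline)
  prod <- crop$production
  producing <- which(!is.na(prod) & prod > 0)
  total <- sum(prod[producing])
  ct <- (b["t_low"] + b["t_high"]) / 2
  cp <- (b["p_low"] + b["p_high"]) / 2
  start_outside <- producing[
    !(ann$t_ann[producing] >= b["t_low"] & ann$t_ann[producing] <= b["t_high"] &
      ann$p_ann[producing] >= b["p_low"] & ann$p_ann[producing] <= b["p_high"])
  ]

  cubes <- list()
  truth <- list()
  for (i in seq_along(fractions)) {
    per <- names(fractions)[i]
    f <- fractions[[i]]
    tavg <- baseline$tavg
    prec <- baseline$prec
    set_cells <- function(cells, t_val, p_val_annual) {
      for (m in 1:12) {
        tm <- tavg[, , m]
        tm[cells] <- t_val
        tavg[, , m] <<- tm
        if (!is.null(p_val_annual)) {
          pm <- prec[, , m]
          pm[cells] <- p_val_annual / 12
          prec[, , m] <<- pm
        }
      }
    }
    # neutralize baseline exposure, then plant the requested fraction
    if (length(start_outside) > 0) set_cells(start_outside, ct, cp)
    pushed <- integer(0)
    if (f > 0) {
      ord <- with_seed(sub_seed(seed, paste0("push-", per)), sample(producing))
      cum <- 0
      for (cell in ord) {
        w <- prod[cell]
        if (abs(cum + w - f * total) <= abs(cum - f * total)) {
          pushed <- c(pushed, cell)
          cum <- cum + w
          if (cum >= f * total) break
        }
      }
      if (length(pushed) > 0) set_cells(pushed, b["t_high"] + t_margin, NULL)
    }
    cubes[[per]] <- climate_cube(
      baseline$spec,
      tavg = tavg, prec = prec,
      source = list(scenario = "planted", period = per)
    )
    truth[[per]] <- data.frame(
      period = per,
      requested = f,
      planted_outside_fraction = sum(prod[pushed]) / total,
      stringsAsFactors = FALSE
    )
  }
  list(cubes = cubes, truth = do.call(rbind, truth))
}
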
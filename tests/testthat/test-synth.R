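# The synthetic generators: determinism, conservation, and recipe oracles.

test_that("the zero-noise baseline equals the prescribed deterministic field", {
  g <- tiny_grid(8)
  cube <- generate_climate_baseline(g,
    noise_sd = 0, p_noise_frac = 0, ocean_fraction = 0, seed = 5
  )
  lat <- grid_lat(g)
  for (m in c(1, 7, 12)) {
    t_expect <- 27 - 0.35 * abs(lat) + 6 * lat / 45 * cos(2 * pi * (m - 7) / 12)
    expect_equal(cube$tavg[, , m], matrix(t_expect, 8, 8))
    p_expect <- 2400 / 12 * exp(-lat^2 / (2 * 25^2))
    expect_equal(cube$prec[, , m], matrix(p_expect, 8, 8))
  }
  expect_true(all(cube$prec >= 0))
})

test_that("generators are bit-identical under a repeated seed", {
  g <- tiny_grid(8)
  a <- generate_climate_baseline(g, seed = 42)
  b <- generate_climate_baseline(g, seed = 42)
  expect_identical(a, b)
  c <- generate_climate_baseline(g, seed = 43)
  expect_false(identical(a$tavg, c$tavg))

  ann <- annual_aggregate(a)
  p1 <- generate_crop_production(g, ann, seed = 7)
  p2 <- generate_crop_production(g, ann, seed = 7)
  expect_identical(p1, p2)

  e1 <- generate_ecology_layers(g, seed = 7)
  e2 <- generate_ecology_layers(g, seed = 7)
  expect_identical(e1, e2)

  # seeded draws do not disturb the caller's RNG stream
  set.seed(1)
  before <- rnorm(1)
  set.seed(1)
  invisible(generate_climate_baseline(g, seed = 9))
  expect_identical(rnorm(1), before)
})

test_that("noisy baseline matches an independent re-draw of the documented recipe", {
  g <- grid_spec(10, 10, -30, 30, 0, 60)
  cube <- generate_climate_baseline(g,
    noise_sd = 1, p_noise_frac = 0.15, noise_range_cells = 2,
    ocean_fraction = 0, seed = 77
  )
  lat <- grid_lat(g)
  set.seed(77)
  t_noise <- lapply(1:12, function(m) oracle_noise_field(10, 10, 2))
  p_noise <- lapply(1:12, function(m) oracle_noise_field(10, 10, 2))
  for (m in 1:12) {
    t_det <- matrix(27 - 0.35 * abs(lat) + 6 * lat / 45 * cos(2 * pi * (m - 7) / 12), 10, 10)
    expect_equal(cube$tavg[, , m], t_det + t_noise[[m]], tolerance = 1e-12)
    p_det <- matrix(2400 / 12 * exp(-lat^2 / (2 * 25^2)), 10, 10)
    expect_equal(cube$prec[, , m], p_det * pmax(0, 1 + 0.15 * p_noise[[m]]), tolerance = 1e-12)
  }
})

test_that("future ensembles shift the baseline by the planted offsets", {
  g <- tiny_grid(6)
  base <- generate_climate_baseline(g, ocean_fraction = 0, seed = 2)
  scen <- list("2C" = list(periods = c("a", "b"), delta_t = c(2, 3)))

  # degenerate ensemble: every member is exactly baseline + delta
  ens0 <- generate_future_ensemble(base, scen, n_models = 3, inter_model_sd = 0, precip_sd = 0, seed = 2)
  for (k in 1:3) {
    expect_equal(ens0[["2C"]][["a"]][[k]]$tavg, base$tavg + 2)
    expect_equal(ens0[["2C"]][["b"]][[k]]$tavg, base$tavg + 3)
    expect_equal(ens0[["2C"]][["a"]][[k]]$prec, base$prec)
  }

  # single model: ensemble mean equals the member
  ens1 <- generate_future_ensemble(base, scen, n_models = 1, inter_model_sd = 0.3, seed = 2)
  em <- ensemble_mean(ens1[["2C"]][["a"]])
  expect_equal(em$tavg, ens1[["2C"]][["a"]][[1]]$tavg)

  # 14 members, sd 0.3: mean offset within 3 * 0.3 / sqrt(14) of the target
  ens14 <- generate_future_ensemble(base, scen, n_models = 14, inter_model_sd = 0.3, precip_sd = 0, seed = 3)
  em14 <- ensemble_mean(ens14[["2C"]][["a"]])
  dev <- abs(em14$tavg - (base$tavg + 2))
  expect_true(all(dev <= 3 * 0.3 / sqrt(14)))

  other <- generate_climate_baseline(grid_spec(5, 5, 0, 30, 0, 30), seed = 1)
  expect_error(ensemble_mean(list(base, other)), "grid_spec")
})

test_that("crop production conserves totals and plants the outside fraction exactly", {
  g <- grid_spec(30, 30, -30, 30, 0, 60)
  base <- generate_climate_baseline(g, seed = 21)
  ann <- annual_aggregate(base)
  b <- c(t_low = 18, t_high = 27, p_low = 1100, p_high = 2400)

  out <- generate_crop_production(g, ann,
    envelope_bounds_true = b,
    total_production = 100, frac_outside_baseline = 0.05, seed = 21
  )
  expect_equal(sum(out$crop$production, na.rm = TRUE), 100, tolerance = 1e-9)

  # direct weighted recount of the outside fraction
  t <- ann$t_ann
  p <- ann$p_ann
  inside <- t >= b[1] & t <= b[2] & p >= b[3] & p <= b[4]
  w <- out$crop$production
  recount <- sum(w[!inside & !is.na(w)]) / sum(w, na.rm = TRUE)
  expect_equal(recount, 0.05, tolerance = 1e-9)
  expect_equal(out$truth$planted_outside_fraction, recount, tolerance = 1e-12)

  # boundary case: zero outside fraction puts every producing cell inside
  out0 <- generate_crop_production(g, ann,
    envelope_bounds_true = b, frac_outside_baseline = 0, seed = 22
  )
  prod0 <- out0$crop$production
  expect_true(all(inside[!is.na(prod0) & prod0 > 0]))

  # unsatisfiable envelope fails loudly
  expect_error(
    generate_crop_production(g, ann,
      envelope_bounds_true = c(t_low = 90, t_high = 95, p_low = 0, p_high = 10)
    ),
    "no cells"
  )
})

test_that("ecology layers plant the AGB-richness correlation and partition land", {
  g <- grid_spec(50, 50, -30, 30, 0, 60)
  eco <- generate_ecology_layers(g, agb_richness_cor = 0.6, seed = 31)
  land <- !is.na(eco$agb)
  r <- cor(eco$agb[land], eco$richness[land])
  expect_equal(r, 0.6, tolerance = 1e-10)

  # perfect correlation: richness is an affine transform of AGB
  eco1 <- generate_ecology_layers(g, agb_richness_cor = 1, seed = 31)
  expect_equal(cor(eco1$agb[land], eco1$richness[land]), 1, tolerance = 1e-12)
  slope <- diff(range(eco1$richness[land])) / diff(range(eco1$agb[land]))
  affine <- eco1$richness[land][1] + slope * (eco1$agb[land] - eco1$agb[land][1])
  expect_equal(affine, eco1$richness[land], tolerance = 1e-9)

  # intact fraction and its empty boundary case
  expect_equal(sum(eco$intact_mask, na.rm = TRUE), round(0.2 * sum(land)))
  eco0 <- generate_ecology_layers(g, intact_fraction = 0, seed = 31)
  expect_equal(sum(eco0$intact_mask, na.rm = TRUE), 0)

  # ecoregions partition all land cells
  expect_true(all(!is.na(eco$ecoregion[land])))
  expect_true(all(is.na(eco$ecoregion[!land])))
  expect_equal(sort(unique(as.vector(eco$ecoregion[land]))), 1:5)

  # ranges respected
  expect_gte(min(eco$agb, na.rm = TRUE), 0.01)
  expect_lte(max(eco$agb, na.rm = TRUE), 0.9)
})

test_that("planted-exposure futures record the achieved fraction exactly", {
  g <- grid_spec(40, 40, -30, 30, 0, 60)
  base <- generate_climate_baseline(g, seed = 15)
  ann <- annual_aggregate(base)
  crop <- generate_crop_production(g, ann,
    envelope_bounds_true = c(t_low = 18, t_high = 27, p_low = 1100, p_high = 2400),
    seed = 15
  )$crop
  env <- fit_envelope(ann, crop)
  pe <- generate_future_with_exposure(base, coef(env), crop,
    fractions = c(p1 = 0.1, p5 = 0.5), seed = 16
  )
  expect_equal(pe$truth$period, c("p1", "p5"))
  expect_lt(max(abs(pe$truth$planted_outside_fraction - pe$truth$requested)), 0.02)
  # determinism of the planted futures
  pe2 <- generate_future_with_exposure(base, coef(env), crop,
    fractions = c(p1 = 0.1, p5 = 0.5), seed = 16
  )
  expect_identical(pe$cubes, pe2$cubes)
})
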
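# Cropland NPP accounting and negative-emission potential change.

test_that("cropland NPP is the four-factor product with tonnes-to-Tg conversion", {
  g <- grid_spec(1, 1, 0, 1, 0, 1)
  crop <- crop_layer(matrix(100), "maize", g)
  par <- crop_carbon_params("maize", f_dry = 0.5, f_shoot = 0.8, f_carbon = 0.45)
  npp <- cropland_npp(crop, par)
  expect_equal(npp[1, 1], 1.8e-5) # 18 t C

  # harvest-index alternative: shoot fraction divides instead of multiplies
  npp_div <- cropland_npp(crop, par, shoot_as_divisor = TRUE)
  expect_equal(npp_div[1, 1], 100 * 0.5 / 0.8 * 0.45 * 1e-6)

  set.seed(2)
  g2 <- tiny_grid(6)
  prod <- matrix(rexp(36, 1 / 100), 6)
  crop2 <- crop_layer(prod, "maize", g2)
  got <- cropland_npp(crop2, par)
  oracle <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) oracle[i, j] <- prod[i, j] * 0.5 * 0.8 * 0.45 * 1e-6
  expect_equal(unclass(got)[1:36], oracle[1:36])

  expect_error(cropland_npp(crop, list(f_dry = 0.5)), "missing carbon params")
  expect_error(crop_carbon_params("x", 0.5, 0, 0.45), "0, 1")
})

test_that("natural NPP residual conserves carbon and clips negatives visibly", {
  g <- tiny_grid(4)
  total <- raster_layer(matrix(10, 4, 4), g)
  cropland <- raster_layer(matrix(0, 4, 4), g)
  cropland[1, 1] <- 4
  cropland[2, 2] <- 10
  cropland[3, 3] <- 12 # exceeds total: clipped

  res <- natural_npp_residual(total, cropland)
  expect_equal(res[1, 1], 6)
  expect_equal(res[2, 2], 0)
  expect_equal(res[3, 3], 0)
  expect_equal(res[4, 4], 10) # no crops: residual = total
  expect_equal(attr(res, "n_clipped"), 1)

  # conservation on unclipped crop cells: residual + cropland = total exactly
  unclipped <- cropland > 0 & cropland <= total
  expect_equal(res[unclipped] + cropland[unclipped], total[unclipped])

  # no crops anywhere: identity
  res0 <- natural_npp_residual(total, raster_layer(matrix(0, 4, 4), g))
  expect_equal(unclass(res0)[1:16], rep(10, 16))
})

test_that("combined potential is the mean over crops present in a cell", {
  g <- grid_spec(1, 3, 0, 1, 0, 3)
  # crop A produces in cells 1-2, crop B in cells 2-3
  a <- crop_layer(matrix(c(2, 2, 0), 1), "a", g)
  b <- crop_layer(matrix(c(0, 4, 4), 1), "b", g)
  # unit-product params scaled so potential equals production (x 1e-6 Tg)
  par <- crop_carbon_params("any", 1, 1, 1)
  nep <- negative_emission_potential(list(a = a, b = b), list(a = par, b = par))
  expect_equal(nep$potential[1, 1], 2e-6) # only crop a
  expect_equal(nep$potential[1, 2], 3e-6) # mean of 2 and 4
  expect_equal(nep$potential[1, 3], 4e-6) # only crop b
  expect_equal(nrow(nep$summaries), 2)

  # capture efficiency scales the potential
  par2 <- crop_carbon_params("any", 1, 1, 1, capture_efficiency = 0.5)
  nep2 <- negative_emission_potential(list(a = a), list(a = par2))
  expect_equal(nep2$potential[1, 1], 1e-6)
})

test_that("potential reduction is the outside-mass fraction of potential", {
  g <- grid_spec(1, 4, 0, 1, 0, 4)
  pot <- raster_layer(matrix(c(1, 2, 3, 4), 1), g)
  msk <- function(inside) {
    structure(
      list(
        spec = g, inside = raster_layer(matrix(inside, 1), g),
        crop_name = "x", scenario = "2C", period = "p"
      ),
      class = "scs_mask"
    )
  }
  all_reg <- region_mask(g)

  tab <- future_potential_change(
    pot, list("2C" = list(p = msk(c(TRUE, TRUE, FALSE, FALSE)))),
    region = all_reg
  )
  expect_equal(tab$reduction, 0.7) # cells 3 and 4 outside: 7/10

  expect_equal(
    future_potential_change(pot, list("2C" = list(p = msk(rep(TRUE, 4)))), all_reg)$reduction, 0
  )
  expect_equal(
    future_potential_change(pot, list("2C" = list(p = msk(rep(FALSE, 4)))), all_reg)$reduction, 1
  )

  # nested outside-sets: growing the outside set cannot reduce the reduction
  r1 <- future_potential_change(pot, list("2C" = list(p = msk(c(TRUE, TRUE, TRUE, FALSE)))), all_reg)$reduction
  r2 <- future_potential_change(pot, list("2C" = list(p = msk(c(TRUE, FALSE, TRUE, FALSE)))), all_reg)$reduction
  expect_lte(r1, r2)
})

test_that("reduction fractions are invariant to production rescaling", {
  g <- tiny_grid(10)
  set.seed(4)
  base <- generate_climate_baseline(g, ocean_fraction = 0, seed = 4)
  ann <- annual_aggregate(base)
  crop <- generate_crop_production(g, ann,
    crop_name = "maize",
    envelope_bounds_true = c(t_low = 18, t_high = 27, p_low = 1100, p_high = 2400),
    seed = 4
  )$crop
  par <- crop_carbon_params("maize", 0.85, 0.5, 0.45)
  env <- fit_envelope(ann, crop)
  fut <- annual_from(g, ann$t_ann + 2, ann$p_ann)
  masks <- list("2C" = list(p = classify_cells(env, fut, "2C", "p")))

  nep1 <- negative_emission_potential(list(maize = crop), list(maize = par))
  crop10 <- crop_layer(crop$production * 10, "maize", g)
  nep10 <- negative_emission_potential(list(maize = crop10), list(maize = par))
  expect_equal(unclass(nep10$potential), unclass(10 * nep1$potential))

  r1 <- future_potential_change(nep1$potential, masks, region_mask(g))$reduction
  r10 <- future_potential_change(nep10$potential, masks, region_mask(g))$reduction
  expect_equal(r1, r10, tolerance = 1e-12)
  expect_true(r1 >= 0 && r1 <= 1)
})
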
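# Envelope fitting and classification against brute-force oracles.

# point-set fixture: n cells laid out on a 1 x n grid with given T, P, weight
point_fixture <- function(t, p, w) {
  n <- length(t)
  g <- grid_spec(1, n, 0, 1, 0, n)
  ann <- annual_from(g, matrix(t, 1), matrix(p, 1))
  crop <- crop_layer(matrix(w, 1), "testcrop", g)
  list(g = g, ann = ann, crop = crop, t = t, p = p, w = w)
}

test_that("weighted quantiles are the left-continuous inverse CDF", {
  # smallest value whose cumulative mass reaches q
  expect_equal(
    weighted_quantile(c(10, 15, 20, 25, 30), c(10, 20, 40, 20, 10), c(0.025, 0.1, 0.5, 0.975)),
    c(10, 10, 20, 30)
  )
  # ties resolve toward the smaller value
  expect_equal(weighted_quantile(c(1, 1, 2), c(1, 1, 2), 0.5), 1)
  # unweighted default, 1..100
  expect_equal(weighted_quantile(1:100, probs = c(0.25, 0.75)), c(25, 75))
  expect_error(weighted_quantile(1:3, probs = 1.5), "0, 1")
})

test_that("a single production cell yields a degenerate envelope with full coverage", {
  fx <- point_fixture(22, 1500, 5)
  env <- fit_envelope(fx$ann, fx$crop)
  expect_equal(unname(coef(env)), c(22, 22, 1500, 1500))
  expect_equal(env$achieved_coverage, 1.0)
})

test_that("the five-cell worked example keeps all cells inside at target 0.95", {
  fx <- point_fixture(c(10, 15, 20, 25, 30), rep(1000, 5), c(10, 20, 40, 20, 10))
  env <- fit_envelope(fx$ann, fx$crop, coverage_target = 0.95)
  b <- coef(env)
  expect_equal(unname(b[c("t_low", "t_high")]), c(10, 30))
  expect_equal(env$achieved_coverage, 1.0)
  # tightening either temperature limit inward would drop 10% of the mass
  expect_lt(brute_coverage(fx$t, fx$p, fx$w, c(15, 30, 0, 2000)), 0.95)
  expect_lt(brute_coverage(fx$t, fx$p, fx$w, c(10, 25, 0, 2000)), 0.95)
})

test_that("rectangular envelopes cover the target, match a brute-force recount, and are minimal", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(20:500, 1)
    t <- rnorm(n, 22, 4)
    p <- rgamma(n, 4, scale = 400)
    w <- rexp(n)
    fx <- point_fixture(t, p, w)
    env <- fit_envelope(fx$ann, fx$crop, coverage_target = 0.95)
    b <- env$bounds

    expect_gte(env$achieved_coverage, 0.95)
    expect_equal(env$achieved_coverage, brute_coverage(t, p, w, b), tolerance = 1e-12)

    # minimality: the next-inner distinct data value on any axis breaks coverage
    tu <- sort(unique(t))
    pu <- sort(unique(p))
    shrunk <- list(
      replace(b, 1, min(tu[tu > b[1]])),
      replace(b, 2, max(tu[tu < b[2]])),
      replace(b, 3, min(pu[pu > b[3]])),
      replace(b, 4, max(pu[pu < b[4]]))
    )
    for (b2 in shrunk) expect_lt(brute_coverage(t, p, w, b2), 0.95)
  }
})

test_that("density envelopes retain top-mass bins and report a recountable coverage", {
  for (s in 1:5) {
    set.seed(s)
    n <- 300
    t <- rnorm(n, 22, 4)
    p <- rgamma(n, 4, scale = 400)
    w <- rexp(n)
    fx <- point_fixture(t, p, w)
    env <- fit_envelope(fx$ann, fx$crop, coverage_target = 0.95, mode = "density", bins = c(30, 30))
    expect_gte(env$achieved_coverage, 0.95)

    # recount: weighted fraction of points whose (T, P) falls in retained bins
    ti <- findInterval(t, env$t_edges, rightmost.closed = TRUE)
    pi_ <- findInterval(p, env$p_edges, rightmost.closed = TRUE)
    inside <- env$retained[cbind(ti, pi_)]
    expect_equal(env$achieved_coverage, sum(w[inside]) / sum(w), tolerance = 1e-12)

    # retained set is the descending-mass prefix: any retained bin holds at
    # least as much mass as any dropped bin
    mass <- matrix(0, nrow(env$retained), ncol(env$retained))
    for (i in seq_len(n)) mass[ti[i], pi_[i]] <- mass[ti[i], pi_[i]] + w[i]
    expect_gte(min(mass[env$retained]), max(mass[!env$retained]))
  }
})

test_that("classification equals a cell-by-cell bound check and is inclusive at the limits", {
  set.seed(11)
  g <- grid_spec(50, 50, -30, 30, 0, 60)
  t0 <- matrix(rnorm(2500, 22, 4), 50)
  p0 <- matrix(rgamma(2500, 4, scale = 400), 50)
  ann <- annual_from(g, t0, p0)
  crop <- crop_layer(matrix(rexp(2500), 50), "x", g)
  for (mode in c("rectangular", "density")) {
    env <- fit_envelope(ann, crop, mode = mode)
    # identity climate: every cell counted inside at fit time stays inside
    mask0 <- classify_cells(env, ann)
    expect_gte(sum(crop$production[mask0$inside]) / sum(crop$production), 0.95)

    fut <- annual_from(g, t0 + matrix(rnorm(2500, 1, 2), 50), p0 * matrix(runif(2500, 0.5, 1.5), 50))
    mask <- classify_cells(env, fut)
    if (mode == "rectangular") {
      b <- env$bounds
      oracle <- fut$t_ann >= b[1] & fut$t_ann <= b[2] & fut$p_ann >= b[3] & fut$p_ann <= b[4]
      expect_equal(as.vector(mask$inside), as.vector(oracle))
    }
  }

  # inclusive bounds: a value exactly at the historical limit is inside
  env <- fit_envelope(ann, crop)
  b <- env$bounds
  at_limit <- annual_from(g, matrix(b["t_high"], 50, 50), matrix(b["p_low"], 50, 50))
  expect_true(all(classify_cells(env, at_limit)$inside))
  past <- annual_from(g, matrix(b["t_high"] + 1e-9, 50, 50), matrix(b["p_low"], 50, 50))
  expect_false(any(classify_cells(env, past)$inside))
})

test_that("exceeding either axis limit alone puts a cell outside", {
  fx <- point_fixture(c(20, 22, 24), c(1000, 1200, 1400), c(1, 2, 1))
  env <- fit_envelope(fx$ann, fx$crop, coverage_target = 0.9)
  b <- env$bounds
  hot <- annual_from(fx$g, matrix(b["t_high"] + 5, 1, 3), matrix(1200, 1, 3))
  dry <- annual_from(fx$g, matrix(22, 1, 3), matrix(b["p_low"] - 5, 1, 3))
  expect_false(any(classify_cells(env, hot)$inside))
  expect_false(any(classify_cells(env, dry)$inside))
})

test_that("classification is invariant to a common shift of baseline and future", {
  set.seed(3)
  g <- tiny_grid(8)
  t0 <- matrix(rnorm(64, 20, 3), 8)
  p0 <- matrix(rgamma(64, 4, scale = 300), 8)
  w <- matrix(rexp(64), 8)
  fut_t <- t0 + matrix(rnorm(64, 1), 8)

  env1 <- fit_envelope(annual_from(g, t0, p0), crop_layer(w, "a", g))
  m1 <- classify_cells(env1, annual_from(g, fut_t, p0))
  env2 <- fit_envelope(annual_from(g, t0 + 5, p0), crop_layer(w, "a", g))
  m2 <- classify_cells(env2, annual_from(g, fut_t + 5, p0))
  expect_equal(m1$inside, m2$inside)
})

test_that("nodata handling: excluded fit mass is logged, nodata future is unclassified", {
  g <- tiny_grid(4)
  t0 <- matrix(20, 4, 4)
  t0[1, 1] <- NA
  ann <- annual_from(g, t0, matrix(1000, 4, 4))
  w <- matrix(1, 4, 4)
  env <- fit_envelope(ann, crop_layer(w, "a", g))
  expect_equal(env$excluded_mass, 1)
  expect_equal(env$n_fit_cells, 15)

  mask <- classify_cells(env, ann)
  expect_true(is.na(mask$inside[1, 1]))
  expect_equal(sum(is.na(mask$inside)), 1)

  all_na <- annual_from(g, matrix(NA_real_, 4, 4), matrix(1000, 4, 4))
  expect_error(fit_envelope(all_na, crop_layer(w, "a", g)), "nodata")
  expect_error(fit_envelope(ann, crop_layer(w, "a", g), coverage_target = 1.5), "0, 1")
})

test_that("envelopes serialize to text and classify identically after reload", {
  set.seed(5)
  fx <- point_fixture(rnorm(200, 22, 4), rgamma(200, 4, scale = 400), rexp(200))
  fut <- annual_from(fx$g, matrix(fx$t + 1, 1), matrix(fx$p * 1.1, 1))
  for (mode in c("rectangular", "density")) {
    env <- fit_envelope(fx$ann, fx$crop, mode = mode)
    path <- tempfile(fileext = ".json")
    write_envelope(env, path)
    env2 <- read_envelope(path)
    expect_equal(env2$achieved_coverage, env$achieved_coverage)
    expect_equal(
      classify_cells(env2, fut)$inside,
      classify_cells(env, fut)$inside
    )
  }
})
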
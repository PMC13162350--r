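# Shared fixtures: tiny grids, constant cubes, and independent re-draws of
# the documented noise-field recipe (used as oracles against the generators).

tiny_grid <- function(n = 10) grid_spec(n, n, -30, 30, 0, 60)

# cube with spatially constant monthly values (optionally a vector of 12)
constant_cube <- function(spec, t = 20, p = 100, source = "baseline") {
  t <- rep(t, length.out = 12)
  p <- rep(p, length.out = 12)
  tavg <- array(rep(t, each = spec$n_rows * spec$n_cols),
    c(spec$n_rows, spec$n_cols, 12)
  )
  prec <- array(rep(p, each = spec$n_rows * spec$n_cols),
    c(spec$n_rows, spec$n_cols, 12)
  )
  climate_cube(spec, tavg = tavg, prec = prec, source = source)
}

# annual climate built directly from T / P matrices
annual_from <- function(spec, t_ann, p_ann) {
  structure(
    list(
      spec = spec,
      t_ann = raster_layer(t_ann, spec),
      p_ann = raster_layer(p_ann, spec),
      source = "direct"
    ),
    class = "annual_climate"
  )
}

# independent reimplementation of the documented smoothed-white-noise recipe
oracle_noise_field <- function(n_rows, n_cols, range_cells) {
  z <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  if (range_cells > 0) {
    half <- ceiling(3 * range_cells)
    k <- dnorm(-half:half, sd = range_cells)
    k <- k / sum(k)
    conv1 <- function(v) {
      n <- length(v)
      vapply(seq_len(n), function(i) {
        # replicated-edge padding: out-of-range taps read the edge cell
        idx <- pmin(pmax(i + (-half:half), 1), n)
        sum(v[idx] * k)
      }, numeric(1))
    }
    z <- apply(z, 2, conv1)       # along the row index (within columns)
    z <- t(apply(z, 1, conv1))    # along the column index (within rows)
  }
  s <- sd(z)
  if (!is.finite(s) || s == 0) {
    return(matrix(0, n_rows, n_cols))
  }
  (z - mean(z)) / s
}

# brute-force production-weighted coverage of a rectangle
brute_coverage <- function(t, p, w, b) {
  sum(w[t >= b[1] & t <= b[2] & p >= b[3] & p <= b[4]]) / sum(w)
}
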
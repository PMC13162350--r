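#' Fit a safe-climate-space envelope for one crop
#'
#' The safe climate space (SCS) of a crop is the region of baseline annual
#' mean temperature and annual precipitation that contains at least
#' `coverage_target` (default 95%) of the crop's total production mass; the
#' lowest-mass tail is excluded as marginal cultivation. Two envelope
#' geometries are available:
#'
#' * `"rectangular"` (default): per-axis limits `[T_low, T_high]` and
#'   `[P_low, P_high]`. Limits start at the production-weighted quantiles
#'   `alpha/2` and `1 - alpha/2` on each axis, with `alpha` chosen by
#'   bisection as the largest trimming for which the joint rectangle still
#'   covers `coverage_target` of the mass; the four limits are then tightened
#'   greedily to the next-inner weighted-quantile candidates until any further
#'   single-limit shrink would drop coverage below target, so the reported
#'   rectangle is minimal.
#' * `"density"`: a 2-D histogram on (T, P) (default `100 x 100` bins over the
#'   production-cell range); bins are retained in order of descending
#'   production mass until the cumulative retained mass reaches
#'   `coverage_target`.
#'
#' Production cells whose baseline climate is nodata are excluded from the
#' fit and from the coverage denominator; the excluded mass is recorded on
#' the model.
#'
#' @param baseline An `annual_climate` (see [annual_aggregate()]) for the
#'   historical baseline.
#' @param crop A [crop_layer()] on the same grid.
#' @param coverage_target Fraction of production mass the envelope must
#'   contain, in `(0, 1]`.
#' @param mode `"rectangular"` or `"density"`.
#' @param bins Length-2 integer: number of temperature and precipitation bins
#'   (density mode).
#' @return An object of class `scs_envelope` with, among others, fields
#'   `bounds` (rectangular limits, degC and mm/yr), `achieved_coverage`,
#'   `excluded_mass`, and (density mode) `t_edges`, `p_edges`, `retained`.
#' @seealso [classify_cells()], [exposure_share()]
#' @examples
#' g <- grid_spec(10, 10, -30, 30, 0, 60)
#' base <- generate_climate_baseline(g, seed = 1)
#' ann <- annual_aggregate(base)
#' crop <- generate_crop_production(g, ann, crop_name = "maize", seed = 1)$crop
#' env <- fit_envelope(ann, crop)
#' coef(env)
#' @export
fit_envelope <- function(baseline, crop, coverage_target = 0.95,
                         mode = c("rectangular", "density"),
                         bins = c(100, 100)) {
  mode <- match.arg(mode)
  stopifnot(inherits(baseline, "annual_climate"), inherits(crop, "crop_layer"))
  stop_if_grid_mismatch(baseline$spec, crop$spec, "baseline and crop")
  if (!is.numeric(coverage_target) || length(coverage_target) != 1 ||
      coverage_target <= 0 || coverage_target > 1) {
    stop("coverage_target must lie in (0, 1]", call. = FALSE)
  }

  prod <- crop$production
  has_prod <- !is.na(prod) & prod > 0
  climate_ok <- !is.na(baseline$t_ann) & !is.na(baseline$p_ann)
  use <- has_prod & climate_ok
  excluded_mass <- sum(prod[has_prod & !climate_ok])
  if (!any(use)) {
    stop("all production lies on nodata baseline climate", call. = FALSE)
  }
  t <- baseline$t_ann[use]
  p <- baseline$p_ann[use]
  w <- prod[use]
  total_w <- sum(w)

  env <- list(
    crop_name = crop$crop_name,
    mode = mode,
    coverage_target = coverage_target,
    n_fit_cells = length(w),
    total_production = total_w,
    excluded_mass = excluded_mass,
    fit = list(t = t, p = p, w = w),
    provenance = fnv1a_hex(c(
      format(baseline$source), crop$crop_name,
      format(c(total_w, length(w), coverage_target), digits = 15)
    ))
  )

  if (mode == "rectangular") {
    env <- c(env, fit_rectangular(t, p, w, coverage_target))
  } else {
    env <- c(env, fit_density(t, p, w, coverage_target, bins))
  }
  class(env) <- "scs_envelope"
  stopifnot(env$achieved_coverage >= coverage_target - 1e-12)
  env
}

# rectangular fit: symmetric-alpha bisection then greedy per-limit tightening
fit_rectangular <- function(t, p, w, target) {
  total <- sum(w)
  coverage <- function(b) {
    sum(w[t >= b[1] & t <= b[2] & p >= b[3] & p <= b[4]]) / total
  }
  bounds_at <- function(alpha) {
    q <- c(alpha / 2, 1 - alpha / 2)
    c(weighted_quantile(t, w, q), weighted_quantile(p, w, q))
  }
  ok <- function(b) coverage(b) >= target - 1e-12

  lo <- 0
  hi <- 1
  if (ok(bounds_at(1))) {
    lo <- 1
  } else {
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (ok(bounds_at(mid))) lo <- mid else hi <- mid
    }
  }
  b <- bounds_at(lo)

  tu <- sort(unique(t))
  pu <- sort(unique(p))
  repeat {
    changed <- FALSE
    # candidate shrink of each limit to the next-inner distinct data value
    cand <- list(
      c(if (any(tu > b[1] & tu <= b[2])) min(tu[tu > b[1] & tu <= b[2]]) else NA, 1),
      c(if (any(tu < b[2] & tu >= b[1])) max(tu[tu < b[2] & tu >= b[1]]) else NA, 2),
      c(if (any(pu > b[3] & pu <= b[4])) min(pu[pu > b[3] & pu <= b[4]]) else NA, 3),
      c(if (any(pu < b[4] & pu >= b[3])) max(pu[pu < b[4] & pu >= b[3]]) else NA, 4)
    )
    for (cd in cand) {
      if (is.na(cd[1])) next
      b2 <- b
      b2[cd[2]] <- cd[1]
      if (ok(b2)) {
        b <- b2
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  names(b) <- c("t_low", "t_high", "p_low", "p_high")
  list(bounds = b, achieved_coverage = coverage(b))
}

# density fit: greedy bin retention on a 2-D production-mass histogram
fit_density <- function(t, p, w, target, bins) {
  stopifnot(length(bins) == 2, all(bins >= 1))
  t_edges <- bin_edges(t, bins[1])
  p_edges <- bin_edges(p, bins[2])
  ti <- bin_index(t, t_edges)
  pi_ <- bin_index(p, p_edges)
  nbt <- length(t_edges) - 1L
  nbp <- length(p_edges) - 1L
  flat <- (pi_ - 1L) * nbt + ti
  mass <- numeric(nbt * nbp)
  agg <- tapply(w, flat, sum)
  mass[as.integer(names(agg))] <- agg
  ord <- order(mass, decreasing = TRUE, method = "radix")
  cum <- cumsum(mass[ord]) / sum(w)
  n_keep <- which(cum >= target - 1e-15)[1]
  retained <- matrix(FALSE, nbt, nbp)
  retained[ord[seq_len(n_keep)]] <- TRUE
  list(
    t_edges = t_edges, p_edges = p_edges, retained = retained,
    achieved_coverage = cum[n_keep]
  )
}

bin_edges <- function(x, n) {
  lo <- min(x)
  hi <- max(x)
  if (hi <= lo) {
    lo <- lo - 0.5
    hi <- hi + 0.5
  }
  seq(lo, hi, length.out = n + 1)
}

# bin index with the last bin closed on the right; 0 / n+1 flag out-of-range
bin_index <- function(x, edges) {
  findInterval(x, edges, rightmost.closed = TRUE)
}

#' @export
print.scs_envelope <- function(x, ...) {
  cat(sprintf(
    "Safe climate space envelope: %s (%s mode)\n", x$crop_name, x$mode
  ))
  if (x$mode == "rectangular") {
    cat(sprintf(
      "  T in [%.2f, %.2f] degC, P in [%.0f, %.0f] mm/yr\n",
      x$bounds["t_low"], x$bounds["t_high"],
      x$bounds["p_low"], x$bounds["p_high"]
    ))
  } else {
    cat(sprintf(
      "  %d retained bins on a %d x %d (T, P) histogram\n",
      sum(x$retained), nrow(x$retained), ncol(x$retained)
    ))
  }
  cat(sprintf(
    "  coverage %.4f (target %.2f), %d production cells, %.4g t fitted\n",
    x$achieved_coverage, x$coverage_target, x$n_fit_cells, x$total_production
  ))
  invisible(x)
}

#' @export
summary.scs_envelope <- function(object, ...) {
  s <- list(
    crop_name = object$crop_name,
    mode = object$mode,
    coverage_target = object$coverage_target,
    achieved_coverage = object$achieved_coverage,
    bounds = if (object$mode == "rectangular") object$bounds else coef(object),
    n_fit_cells = object$n_fit_cells,
    total_production = object$total_production,
    excluded_mass = object$excluded_mass,
    t_weighted_range = range(object$fit$t),
    p_weighted_range = range(object$fit$p)
  )
  class(s) <- "summary.scs_envelope"
  s
}

#' @export
print.summary.scs_envelope <- function(x, ...) {
  cat(sprintf("SCS envelope summary: %s (%s mode)\n", x$crop_name, x$mode))
  cat(sprintf(
    "  bounds: T [%.2f, %.2f] degC, P [%.0f, %.0f] mm/yr\n",
    x$bounds[1], x$bounds[2], x$bounds[3], x$bounds[4]
  ))
  cat(sprintf(
    "  coverage %.4f of %.4g t over %d cells (target %.2f)\n",
    x$achieved_coverage, x$total_production, x$n_fit_cells, x$coverage_target
  ))
  cat(sprintf(
    "  production climate range: T %.2f..%.2f degC, P %.0f..%.0f mm/yr\n",
    x$t_weighted_range[1], x$t_weighted_range[2],
    x$p_weighted_range[1], x$p_weighted_range[2]
  ))
  if (x$excluded_mass > 0) {
    cat(sprintf("  %.4g t excluded (nodata baseline climate)\n", x$excluded_mass))
  }
  invisible(x)
}

#' Envelope limits
#'
#' For a rectangular envelope, the four climatic limits; for a density
#' envelope, the bounding box of the retained histogram bins.
#'
#' @param object An `scs_envelope`.
#' @param ... Unused.
#' @return Named numeric vector `(t_low, t_high, p_low, p_high)`.
#' @export
coef.scs_envelope <- function(object, ...) {
  if (object$mode == "rectangular") {
    return(object$bounds)
  }
  keep <- which(object$retained, arr.ind = TRUE)
  c(
    t_low = object$t_edges[min(keep[, 1])],
    t_high = object$t_edges[max(keep[, 1]) + 1],
    p_low = object$p_edges[min(keep[, 2])],
    p_high = object$p_edges[max(keep[, 2]) + 1]
  )
}

#' Classify future climate against a fitted envelope
#'
#' A cell is inside the SCS iff its future annual climate respects the fitted
#' limits: rectangular mode requires
#' `T_low <= T <= T_high` **and** `P_low <= P <= P_high` (exceeding either
#' axis puts the cell outside; comparisons are inclusive, so a value exactly
#' at a historical limit is inside); density mode requires the (T, P) pair to
#' land in a retained histogram bin. Cells with nodata future climate carry
#' `NA` in the mask. The mask is climate-only: it is defined whether or not
#' the cell currently holds production.
#'
#' `classify_cells()` is the pipeline-facing name; `predict()` on the fitted
#' model is equivalent.
#'
#' @param env,object A fitted `scs_envelope`.
#' @param future,newdata An `annual_climate` on the same grid the envelope
#'   was fitted on.
#' @param scenario,period Optional labels stored on the mask.
#' @param ... Unused.
#' @return An object of class `scs_mask`: list with `spec`, `inside` (logical
#'   raster, `NA` = nodata climate), `crop_name`, `scenario`, `period`.
#' @export
classify_cells <- function(env, future, scenario = NA_character_,
                           period = NA_character_) {
  stopifnot(inherits(env, "scs_envelope"), inherits(future, "annual_climate"))
  t <- future$t_ann
  p <- future$p_ann
  if (env$mode == "rectangular") {
    b <- env$bounds
    inside <- t >= b["t_low"] & t <= b["t_high"] &
      p >= b["p_low"] & p <= b["p_high"]
  } else {
    ti <- bin_index(t, env$t_edges)
    pi_ <- bin_index(p, env$p_edges)
    nbt <- nrow(env$retained)
    nbp <- ncol(env$retained)
    valid <- ti >= 1 & ti <= nbt & pi_ >= 1 & pi_ <= nbp
    inside <- matrix(FALSE, future$spec$n_rows, future$spec$n_cols)
    inside[which(valid)] <- env$retained[cbind(ti[valid], pi_[valid])]
    inside[is.na(t) | is.na(p)] <- NA
  }
  dim(inside) <- c(future$spec$n_rows, future$spec$n_cols)
  structure(
    list(
      spec = future$spec,
      inside = raster_layer(inside, future$spec),
      crop_name = env$crop_name,
      scenario = scenario,
      period = period
    ),
    class = "scs_mask"
  )
}

#' @rdname classify_cells
#' @export
predict.scs_envelope <- function(object, newdata, scenario = NA_character_,
                                 period = NA_character_, ...) {
  classify_cells(object, newdata, scenario = scenario, period = period)
}

#' @export
print.scs_mask <- function(x, ...) {
  n_in <- sum(x$inside, na.rm = TRUE)
  n_def <- sum(!is.na(x$inside))
  cat(sprintf(
    "scs_mask [%s%s%s]: %d / %d classified cells inside\n",
    x$crop_name,
    if (!is.na(x$scenario)) paste0(", ", x$scenario) else "",
    if (!is.na(x$period)) paste0(", ", x$period) else "",
    n_in, n_def
  ))
  invisible(x)
}

#' Plot a fitted envelope in climate space
#'
#' Production cells as points (area proportional to production mass) over the
#' envelope: the fitted rectangle (rectangular mode) or the retained bins
#' (density mode).
#'
#' @param x An `scs_envelope`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.scs_envelope <- function(x, ...) {
  ft <- x$fit
  cex <- 0.3 + 2 * sqrt(ft$w / max(ft$w))
  graphics::plot(
    ft$t, ft$p, cex = cex, pch = 21, bg = "#00000033",
    xlab = "Annual mean temperature (degC)",
    ylab = "Annual precipitation (mm/yr)",
    main = sprintf("%s safe climate space (%s)", x$crop_name, x$mode), ...
  )
  if (x$mode == "rectangular") {
    b <- x$bounds
    graphics::rect(b["t_low"], b["p_low"], b["t_high"], b["p_high"],
      border = "firebrick", lwd = 2
    )
  } else {
    z <- x$retained * 1
    graphics::image(
      x = (x$t_edges[-1] + x$t_edges[-length(x$t_edges)]) / 2,
      y = (x$p_edges[-1] + x$p_edges[-length(x$p_edges)]) / 2,
      z = z, add = TRUE, col = c("#00000000", "#B2222244")
    )
    graphics::points(ft$t, ft$p, cex = cex, pch = 21, bg = "#00000033")
  }
  invisible(x)
}

#' Serialize / restore a fitted envelope
#'
#' Writes the model to structured text (JSON): mode, limits or histogram
#' edges plus retained-bin indices, achieved coverage, and an input
#' provenance hash. The per-cell fit points are not serialized; a restored
#' model classifies identically but cannot be plotted against its fit data.
#'
#' @param env An `scs_envelope`.
#' @param path Output / input file path.
#' @return `write_envelope()` returns `path` invisibly; `read_envelope()`
#'   returns the restored `scs_envelope`.
#' @export
write_envelope <- function(env, path) {
  stopifnot(inherits(env, "scs_envelope"))
  obj <- env[setdiff(names(env), c("fit", "retained"))]
  if (!is.null(obj$bounds)) obj$bounds <- as.list(obj$bounds) # keep names in JSON
  if (env$mode == "density") {
    obj$retained_bins <- which(env$retained)
    obj$n_bins <- dim(env$retained)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_envelope
#' @export
read_envelope <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  env <- obj
  if (!is.null(obj$bounds)) {
    env$bounds <- unlist(obj$bounds)
  }
  if (identical(obj$mode, "density")) {
    retained <- matrix(FALSE, obj$n_bins[1], obj$n_bins[2])
    retained[obj$retained_bins] <- TRUE
    env$retained <- retained
    env$retained_bins <- NULL
    env$n_bins <- NULL
  }
  class(env) <- "scs_envelope"
  env
}
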
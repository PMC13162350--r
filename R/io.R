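#' Read and write plain-text rasters (ESRI ASCII grid)
#'
#' Rasters travel as ESRI ASCII grids (`.asc`): a georeferencing header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize` or `dx`/`dy`,
#' `nodata_value`) followed by rows of values, top row northernmost — the one
#' standard raster format that is plain text. Values are written with full
#' double precision so write-then-read round-trips bit-identically.
#'
#' @param x Raster matrix with a grid attribute ([raster_layer()]).
#' @param path File path.
#' @param nodata Sentinel written for `NA` cells.
#' @return `write_raster()` returns `path` invisibly; `read_raster()` returns
#'   a raster matrix with its `grid_spec` attached and sentinel cells as `NA`.
#' @export
write_raster <- function(x, path, nodata = -9999) {
  spec <- grid_of(x)
  res <- grid_res(spec)
  hdr <- c(
    sprintf("ncols %d", spec$n_cols),
    sprintf("nrows %d", spec$n_rows),
    sprintf("xllcorner %.12g", spec$lon_min),
    sprintf("yllcorner %.12g", spec$lat_min)
  )
  hdr <- c(hdr, if (abs(res["dlat"] - res["dlon"]) < 1e-12) {
    sprintf("cellsize %.12g", res["dlon"])
  } else {
    c(sprintf("dx %.12g", res["dlon"]), sprintf("dy %.12g", res["dlat"]))
  })
  hdr <- c(hdr, sprintf("nodata_value %.12g", nodata))
  v <- x
  v[is.na(v)] <- nodata
  rows <- apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("no such raster file: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) == 2 && grepl("^[a-zA-Z_]", tok[1])) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
      i <- i + 1
    } else {
      break
    }
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner")
  if (!all(need %in% names(hdr))) {
    stop("missing georeferencing header in ", path, call. = FALSE)
  }
  dx <- if (!is.null(hdr$cellsize)) hdr$cellsize else hdr$dx
  dy <- if (!is.null(hdr$cellsize)) hdr$cellsize else hdr$dy
  if (is.null(dx) || is.null(dy)) {
    stop("missing cellsize (or dx/dy) in ", path, call. = FALSE)
  }
  nr <- as.integer(hdr$nrows)
  nc <- as.integer(hdr$ncols)
  body <- scan(text = lines[i:length(lines)], quiet = TRUE)
  if (length(body) != nr * nc) {
    stop("raster body size mismatch in ", path, call. = FALSE)
  }
  m <- matrix(body, nr, nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  spec <- grid_spec(
    nr, nc,
    lat_min = hdr$yllcorner, lat_max = hdr$yllcorner + nr * dy,
    lon_min = hdr$xllcorner, lon_max = hdr$xllcorner + nc * dx
  )
  raster_layer(m, spec)
}

#' Write / read a climate cube as a directory of monthly rasters
#'
#' One `.asc` per variable and month (`tavg_01.asc` ... `prec_12.asc`) plus a
#' `cube.json` manifest holding the source tag, so a cube round-trips
#' losslessly through plain text.
#'
#' @param cube A [climate_cube()].
#' @param dir Directory (created if needed).
#' @return `write_climate_cube()` returns `dir` invisibly;
#'   `read_climate_cube()` returns the cube.
#' @export
write_climate_cube <- function(cube, dir) {
  stopifnot(inherits(cube, "climate_cube"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in 1:12) {
    write_raster(
      raster_layer(cube$tavg[, , m], cube$spec),
      file.path(dir, sprintf("tavg_%02d.asc", m))
    )
    write_raster(
      raster_layer(cube$prec[, , m], cube$spec),
      file.path(dir, sprintf("prec_%02d.asc", m))
    )
  }
  jsonlite::write_json(
    list(source = cube$source), file.path(dir, "cube.json"),
    auto_unbox = TRUE
  )
  invisible(dir)
}

#' @rdname write_climate_cube
#' @export
read_climate_cube <- function(dir) {
  first <- read_raster(file.path(dir, "tavg_01.asc"))
  spec <- grid_of(first)
  tavg <- array(NA_real_, c(spec$n_rows, spec$n_cols, 12))
  prec <- array(NA_real_, c(spec$n_rows, spec$n_cols, 12))
  for (m in 1:12) {
    tavg[, , m] <- read_raster(file.path(dir, sprintf("tavg_%02d.asc", m)))
    prec[, , m] <- read_raster(file.path(dir, sprintf("prec_%02d.asc", m)))
  }
  src <- jsonlite::read_json(file.path(dir, "cube.json"), simplifyVector = TRUE)$source
  climate_cube(spec, tavg = tavg, prec = prec, source = src)
}

#' Align a raster to another grid
#'
#' Resamples between overlapping regular lat/lon grids. Three methods, chosen
#' by what the layer measures:
#' * `"nearest"` — class / mask rasters: each target cell takes the source
#'   cell containing its center.
#' * `"mean"` — continuous stocks and densities: spherical-area-weighted mean
#'   of overlapping source cells (nodata source cells excluded).
#' * `"sum"` — production-like mass: mass-conserving; each source cell's
#'   value is split across target cells in proportion to the overlapped
#'   fraction of the source cell's area, so totals are preserved wherever the
#'   target covers the source.
#'
#' The method used is recorded in the output's `align_method` attribute.
#'
#' @param x Source raster matrix with grid attached.
#' @param to Target `grid_spec`.
#' @param method `"nearest"`, `"mean"` or `"sum"`.
#' @return Raster matrix on `to`.
#' @export
align_to <- function(x, to, method = c("nearest", "mean", "sum")) {
  method <- match.arg(method)
  from <- grid_of(x)
  if (same_grid(from, to)) {
    out <- raster_layer(unclass(x)[, , drop = FALSE], to)
    attr(out, "align_method") <- "identity"
    return(out)
  }
  if (from$lat_min >= to$lat_max || from$lat_max <= to$lat_min ||
    from$lon_min >= to$lon_max || from$lon_max <= to$lon_min) {
    stop("source and target extents are disjoint", call. = FALSE)
  }

  if (method == "nearest") {
    res_f <- grid_res(from)
    lat_t <- grid_lat(to)
    lon_t <- grid_lon(to)
    src_row <- floor((from$lat_max - lat_t) / res_f["dlat"]) + 1
    src_col <- floor((lon_t - from$lon_min) / res_f["dlon"]) + 1
    src_row[src_row < 1 | src_row > from$n_rows] <- NA
    src_col[src_col < 1 | src_col > from$n_cols] <- NA
    out <- matrix(NA, to$n_rows, to$n_cols)
    for (i in seq_len(to$n_rows)) {
      if (is.na(src_row[i])) next
      out[i, !is.na(src_col)] <- x[src_row[i], src_col[!is.na(src_col)]]
    }
    out <- raster_layer(out, to)
    attr(out, "align_method") <- "nearest"
    return(out)
  }

  # separable overlap weights: sin(lat) differences x lon lengths
  overlap <- function(edges_a, edges_b) {
    na <- length(edges_a) - 1
    nb <- length(edges_b) - 1
    lo <- pmax(
      matrix(edges_a[-length(edges_a)], na, nb),
      matrix(edges_b[-length(edges_b)], na, nb, byrow = TRUE)
    )
    hi <- pmin(
      matrix(edges_a[-1], na, nb),
      matrix(edges_b[-1], na, nb, byrow = TRUE)
    )
    pmax(hi - lo, 0)
  }
  lat_edges <- function(g) sin(seq(g$lat_min, g$lat_max, length.out = g$n_rows + 1) * pi / 180)
  lon_edges <- function(g) seq(g$lon_min, g$lon_max, length.out = g$n_cols + 1)
  # rows run north->south: overlap computed on ascending edges then flipped
  ur <- overlap(lat_edges(from), lat_edges(to))
  ur <- ur[rev(seq_len(nrow(ur))), rev(seq_len(ncol(ur))), drop = FALSE]
  uc <- overlap(lon_edges(from), lon_edges(to))

  v0 <- unclass(x)
  miss <- is.na(v0)
  v0[miss] <- 0
  if (method == "mean") {
    num <- t(ur) %*% v0 %*% uc
    den <- t(ur) %*% (1 - miss) %*% uc
    out <- num / den
    out[den == 0] <- NA
  } else {
    e_desc <- seq(from$lat_max, from$lat_min, length.out = from$n_rows + 1) * pi / 180
    src_h <- sin(e_desc[-(from$n_rows + 1)]) - sin(e_desc[-1])
    src_w <- diff(lon_edges(from))
    out <- t(ur / src_h) %*% v0 %*% (uc / src_w)
  }
  out <- raster_layer(matrix(out, to$n_rows, to$n_cols), to)
  attr(out, "align_method") <- method
  out
}
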
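#' Monthly climate series on a grid
#'
#' Holds co-registered monthly precipitation (mm/month) and land-surface
#' temperature (kelvin) for a range of years, the primitive inputs from which
#' the drought (MCWD) and temperature-anomaly covariates are derived.
#'
#' @param grid a `fire_grid`.
#' @param years integer vector of consecutive years covered.
#' @param precipitation,temperature 4-D arrays
#'   `(n_rows, n_cols, n_years, 12)`; precipitation in mm/month (>= 0),
#'   temperature in kelvin (within (150, 350) on unmasked cells).
#' @return an object of class `climate_series`.
#' @export
climate_series <- function(grid, years, precipitation, temperature) {
  stopifnot(inherits(grid, "fire_grid"))
  years <- as.integer(years)
  stopifnot(length(years) >= 1L, all(diff(years) == 1L))
  dm <- c(grid$n_rows, grid$n_cols, length(years), 12L)
  if (!all(dim(precipitation) == dm) || !all(dim(temperature) == dm))
    stop("climate arrays must have dim (n_rows, n_cols, n_years, 12)")
  ok <- grid$mask
  for (y in seq_along(years)) for (m in 1:12) {
    p <- precipitation[, , y, m][ok]; t <- temperature[, , y, m][ok]
    if (any(!is.finite(p)) || any(p < 0))
      stop("precipitation must be finite and >= 0 on unmasked cells")
    if (any(!is.finite(t)) || any(t <= 150) || any(t >= 350))
      stop("temperature must lie in (150, 350) K on unmasked cells")
  }
  structure(list(grid = grid, years = years,
                 precipitation = precipitation, temperature = temperature),
            class = "climate_series")
}

#' @export
print.climate_series <- function(x, ...) {
  cat(sprintf("<climate_series> %d-%d on %d x %d grid\n", min(x$years),
              max(x$years), x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

#' Decode integer land-surface-temperature rasters
#'
#' MOD11C3-style LST products store kelvin as scaled integers; multiplying by
#' the scale factor (0.02) recovers kelvin.
#'
#' @param layer a continuous `fire_layer` of scaled integer DN values.
#' @param scale multiplicative scale factor, default 0.02.
#' @return a `fire_layer` in kelvin.
#' @export
decode_lst <- function(layer, scale = 0.02) {
  fire_layer(layer$grid, layer$values * scale, name = layer$name,
             kind = "continuous", units = "K")
}

#' Maximum climatological water deficit (MCWD)
#'
#' Accumulates the monthly water deficit
#' `WD_n = min(0, WD_{n-1} + P_n - threshold)` over the 12 months starting at
#' `reset_month` of `year` (crossing into `year + 1` when
#' `reset_month > 1`), starting from `WD = 0`, and returns the most negative
#' deficit reached (<= 0, mm). The threshold (default 100 mm/month) proxies
#' monthly evapotranspiration. Accumulation resets in the climatologically
#' wettest month; for the seasonality emulated here that is January.
#'
#' @param series a `climate_series`.
#' @param year the year whose window is evaluated.
#' @param threshold mm/month, default 100.
#' @param reset_month month index 1-12 at which accumulation restarts.
#' @return continuous `fire_layer` (mm, <= 0).
#' @export
compute_mcwd <- function(series, year, threshold = 100, reset_month = 1L) {
  stopifnot(inherits(series, "climate_series"))
  reset_month <- as.integer(reset_month)
  stopifnot(reset_month >= 1L, reset_month <= 12L)
  g <- series$grid
  wd <- matrix(0, g$n_rows, g$n_cols)
  mcwd <- matrix(0, g$n_rows, g$n_cols)
  for (k in 0:11) {
    m <- reset_month + k
    y <- year + (m - 1L) %/% 12L
    m <- (m - 1L) %% 12L + 1L
    yi <- match(y, series$years)
    if (is.na(yi))
      stop(sprintf("climate series does not cover %d-%02d", y, m))
    p <- series$precipitation[, , yi, m]
    wd <- pmin(0, wd + p - threshold)
    mcwd <- pmin(mcwd, wd)
  }
  fire_layer(g, mcwd, name = sprintf("mcwd_%d", year), units = "mm")
}

#' Annual anomaly relative to a multi-year baseline
#'
#' The anomaly of the target year is its value minus the per-cell mean over
#' all baseline years; the baseline includes the target year when it falls in
#' the range (as a 2000-2010 baseline contains 2010). The mean anomaly over
#' the baseline years is exactly zero per cell. Sign convention: a negative
#' MCWD anomaly means drier than baseline; a positive temperature anomaly
#' means warmer.
#'
#' @param per_year named list of `fire_layer`s, one per baseline year (names
#'   are the years).
#' @param target_year year whose anomaly is returned; must be present in
#'   `per_year`.
#' @return continuous `fire_layer` with attributes `target_year` and
#'   `baseline`.
#' @export
compute_anomaly <- function(per_year, target_year) {
  stopifnot(is.list(per_year), length(per_year) >= 2L)
  yrs <- as.integer(names(per_year))
  ti <- match(as.integer(target_year), yrs)
  if (is.na(ti)) stop("target year not present in per_year layers")
  g <- per_year[[1]]$grid
  acc <- matrix(0, g$n_rows, g$n_cols)
  for (l in per_year) {
    if (!same_grid(g, l$grid)) stop_grid_mismatch("baseline layers")
    acc <- acc + l$values
  }
  anom <- per_year[[ti]]$values - acc / length(per_year)
  out <- fire_layer(g, anom,
                    name = sprintf("%s_anom_%d",
                                   sub("_\\d+$", "", per_year[[ti]]$name),
                                   target_year),
                    units = per_year[[ti]]$units)
  attr(out, "target_year") <- as.integer(target_year)
  attr(out, "baseline") <- range(yrs)
  out
}

#' Road network as classed polylines
#'
#' @param polylines list of two-column matrices of (x, y) vertices in km.
#' @param class character vector, one of `"paved"`/`"unpaved"` per polyline.
#' @param weights named positive weights per class; smaller weight makes that
#'   class dominate the combined weighted distance. Defaults reflect unpaved
#'   (secondary) roads being the stronger fire-access predictor.
#' @return an object of class `road_set`.
#' @export
road_set <- function(polylines, class,
                     weights = c(paved = 1.0, unpaved = 0.5)) {
  stopifnot(length(polylines) == length(class),
            all(class %in% names(weights)), all(weights > 0),
            length(polylines) >= 1L)
  structure(list(polylines = polylines, class = as.character(class),
                 weights = weights), class = "road_set")
}

# Cells touched by a polyline: dense sampling along each segment at a
# quarter-cell step, then unique (row, col). Returns integer cell indices.
rasterize_polyline <- function(poly, grid) {
  pts <- NULL
  step <- grid$cell_size / 4
  for (i in seq_len(nrow(poly) - 1L)) {
    a <- poly[i, ]; b <- poly[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    n <- max(2L, ceiling(len / step) + 1L)
    t <- seq(0, 1, length.out = n)
    pts <- rbind(pts, cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2])))
  }
  col <- floor((pts[, 1] - grid$origin[1]) / grid$cell_size) + 1L
  row <- floor((grid$origin[2] - pts[, 2]) / grid$cell_size) + 1L
  keep <- row >= 1L & row <= grid$n_rows & col >= 1L & col <= grid$n_cols
  unique((col[keep] - 1L) * grid$n_rows + row[keep])
}

#' Weighted Euclidean distance to roads
#'
#' Rasterises each road class onto the grid (every cell a polyline touches is
#' a road cell) and returns, per cell, the minimum over classes of the
#' Euclidean distance to the nearest cell centre of that class multiplied by
#' the class weight. Distances are between cell centres, reported in metres;
#' road cells are 0.
#'
#' @param roads a `road_set`.
#' @param grid a `fire_grid`.
#' @return continuous `fire_layer` (m).
#' @export
distance_to_roads <- function(roads, grid) {
  stopifnot(inherits(roads, "road_set"))
  if (length(roads$polylines) == 0L) stop("empty road set")
  cc <- cell_centers(grid)
  d_min <- rep(Inf, n_cells(grid))
  any_road <- FALSE
  for (cls in unique(roads$class)) {
    cells <- unique(unlist(lapply(
      which(roads$class == cls),
      function(i) rasterize_polyline(roads$polylines[[i]], grid))))
    if (length(cells) == 0L) next
    any_road <- TRUE
    rc <- cell_centers(grid, cells)
    d2 <- rep(Inf, n_cells(grid))
    for (k in seq_len(nrow(rc)))
      d2 <- pmin(d2, (cc[, 1] - rc[k, 1])^2 + (cc[, 2] - rc[k, 2])^2)
    d2[cells] <- 0
    d_min <- pmin(d_min, sqrt(d2) * roads$weights[[cls]])
  }
  if (!any_road) stop("no road intersects the grid")
  fire_layer(grid, matrix(d_min * 1000, grid$n_rows, grid$n_cols),
             name = "road_distance", units = "m")
}

#' Settlement points with population weights
#'
#' @param x,y coordinates in km.
#' @param population positive person counts.
#' @return an object of class `settlement_set`.
#' @export
settlement_set <- function(x, y, population) {
  stopifnot(length(x) == length(y), length(x) == length(population))
  if (length(population) > 0 && any(population <= 0))
    stop("population weights must be > 0")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 population = as.numeric(population)),
            class = "settlement_set")
}

#' Population-weighted settlement kernel density
#'
#' 2-D quartic (biweight) kernel density of settlement points weighted by
#' population, `K(d) = 3/(pi h^2) (1 - (d/h)^2)^2` for `d <= h`, which
#' integrates to 1, so the density integrates to total population (persons
#' per km2) for settlements at least a bandwidth from the boundary. An empty
#' settlement set yields a zero layer.
#'
#' @param settlements a `settlement_set`.
#' @param grid a `fire_grid`.
#' @param bandwidth kernel radius h in km, default 10.
#' @return continuous `fire_layer` (persons km^-2).
#' @export
settlement_density <- function(settlements, grid, bandwidth = 10) {
  stopifnot(inherits(settlements, "settlement_set"), bandwidth > 0)
  dens <- rep(0, n_cells(grid))
  if (length(settlements$x) > 0L) {
    cc <- cell_centers(grid)
    h2 <- bandwidth^2
    for (s in seq_along(settlements$x)) {
      d2 <- (cc[, 1] - settlements$x[s])^2 + (cc[, 2] - settlements$y[s])^2
      k <- ifelse(d2 <= h2, (3 / (pi * h2)) * (1 - d2 / h2)^2, 0)
      dens <- dens + settlements$population[s] * k
    }
  }
  fire_layer(grid, matrix(dens, grid$n_rows, grid$n_cols),
             name = "settlement_density", units = "persons/km2")
}

#' Fraction of a land-cover category at coarse resolution
#'
#' Fraction of fine cells equal to `code` in each coarse block, e.g. percent
#' shrubland or grassland from a categorical land-cover map.
#'
#' @param map categorical `fire_layer` at the fine grid.
#' @param code one declared category code.
#' @param factor integer aggregation factor (see [aggregate_fraction()]).
#' @param name output layer name.
#' @return continuous `fire_layer` in \[0, 1\].
#' @export
landcover_fraction <- function(map, code, factor,
                               name = sprintf("class%d_fraction", code)) {
  stopifnot(inherits(map, "fire_layer"))
  if (map$kind != "categorical") stop("map must be a categorical layer")
  if (!(code %in% map$codes)) stop("unknown land-cover code: ", code)
  bin <- fire_layer(map$grid, (map$values == code) * 1,
                    name = map$name, kind = "continuous")
  aggregate_fraction(bin, factor, name = name)
}
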
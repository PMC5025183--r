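#' Spatially autocorrelated Gaussian random field
#'
#' Spectral synthesis on a periodic grid: white noise filtered in the
#' Fourier domain by a Gaussian spectrum with the given correlation length,
#' then standardised to mean 0 / sd `sigma` over cells. Draws from the
#' caller's RNG stream.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param length_scale correlation length in cells.
#' @param sigma marginal standard deviation.
#' @return numeric matrix.
#' @export
gaussian_field <- function(n_rows, n_cols, length_scale, sigma = 1) {
  wn <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  fr <- function(n) {
    f <- 0:(n - 1L)
    ifelse(f > n / 2, f - n, f) / n
  }
  kx <- 2 * pi * fr(n_cols); ky <- 2 * pi * fr(n_rows)
  k2 <- outer(ky^2, kx^2, "+")
  amp <- exp(-k2 * length_scale^2 / 4)
  fld <- Re(stats::fft(stats::fft(wn) * amp, inverse = TRUE)) /
    (n_rows * n_cols)
  fld <- fld - mean(fld)
  s <- stats::sd(fld)
  if (s > 0) fld <- fld / s * sigma
  fld
}

#' Synthetic landscape configuration
#'
#' Defines the study conditions the generator emulates: a 200 x 200 grid of
#' 1 km cells; patchy land-cover mosaics (Gaussian random fields); a sparse
#' road network of paved trunk lines and denser unpaved branches;
#' population-weighted settlements near roads; a blocky categorical
#' protected-area layer; seasonal monthly rainfall with a July-November dry
#' season (wettest month January, annual total ~1100 mm) over 2000-2010 with
#' 2010 a drought year and 2009 a normal/wet year; and a true logistic
#' suitability whose dominant drivers are road proximity, recent
#' deforestation and settlement density, inhibited inside protected areas.
#'
#' @param n_rows,n_cols,cell_size grid dimensions (km).
#' @param seed integer seed; regeneration is deterministic given
#'   (config, seed).
#' @param lc_length_scale,defor_length_scale field correlation lengths (km).
#' @param n_paved,n_unpaved road counts.
#' @param n_settlements,pop_meanlog,pop_sdlog settlement count and log-normal
#'   population distribution.
#' @param n_protected_blocks protected-area block count (codes 1-4 cycle).
#' @param kde_bandwidth settlement kernel bandwidth (km).
#' @param monthly_precip Jan-Dec climatological rainfall means (mm/month).
#' @param dry_year,wet_year drought and normal/wet reference years.
#' @param dry_season_factor multiplier on dry-season (Jul-Nov) rainfall in
#'   the drought year.
#' @param temp_base mean land-surface temperature (K).
#' @param dry_year_warming drought-year temperature offset (K).
#' @param years covered years.
#' @param true_weights named weights on standardized covariates in the true
#'   logistic suitability.
#' @param intercept true intercept.
#' @param protected_inhibition multiplier (< 1) on true suitability inside
#'   protected cells.
#' @param month_weights 12 probabilities for hotspot months; the default
#'   puts 0.50 on August and 0.33 on September (~83% in the two peak
#'   months).
#' @return a list of class `landscape_config`.
#' @export
landscape_config <- function(
    n_rows = 200L, n_cols = 200L, cell_size = 1, seed = 1L,
    lc_length_scale = 15, defor_length_scale = 8,
    n_paved = 2L, n_unpaved = 8L,
    n_settlements = 25L, pop_meanlog = 7.5, pop_sdlog = 1,
    n_protected_blocks = 4L, kde_bandwidth = 10,
    monthly_precip = c(190, 170, 140, 110, 70, 45, 20, 20, 30, 45, 70, 150),
    dry_year = 2010L, wet_year = 2009L, dry_season_factor = 0.45,
    temp_base = 297, dry_year_warming = 1.5, years = 2000:2010,
    true_weights = c(deforestation = 2.0, road_distance = -2.0,
                     settlement_density = 1.5, shrubland = 0.8,
                     grassland = 0.5, mcwd_anomaly = -1.2,
                     temperature_anomaly = 1.2),
    intercept = -0.5, protected_inhibition = 0.35,
    month_weights = c(rep(0.017, 7), 0.50, 0.33, rep(0.017, 3))) {
  stopifnot(n_rows >= 8L, n_cols >= 8L, length(monthly_precip) == 12L,
            abs(sum(month_weights) - 1) < 1e-6,
            dry_season_factor > 0, dry_season_factor <= 1)
  cfg <- as.list(environment())
  class(cfg) <- "landscape_config"
  cfg
}

DRY_SEASON_MONTHS <- 7:11

# random polyline crossing the full domain with mild jitter
trunk_line <- function(xr, yr, jitter = 2) {
  cx <- stats::runif(1, xr[1], xr[2]); cy <- stats::runif(1, yr[1], yr[2])
  ang <- stats::runif(1, 0, pi)
  L <- sqrt(diff(xr)^2 + diff(yr)^2)
  t <- seq(-L, L, length.out = 20)
  x <- cx + t * cos(ang) + stats::rnorm(20, 0, jitter)
  y <- cy + t * sin(ang) + stats::rnorm(20, 0, jitter)
  cbind(x, y)
}

branch_line <- function(start, len, jitter = 1.5) {
  ang <- stats::runif(1, 0, 2 * pi)
  t <- seq(0, len, length.out = 8)
  cbind(start[1] + t * cos(ang) + stats::rnorm(8, 0, jitter),
        start[2] + t * sin(ang) + stats::rnorm(8, 0, jitter))
}

make_roads <- function(cfg, grid, extra_paved = 0L, base = NULL,
                       seed_offset = 0L) {
  xr <- grid$origin[1] + c(0, grid$n_cols * grid$cell_size)
  yr <- grid$origin[2] - c(grid$n_rows * grid$cell_size, 0)
  polylines <- list(); cls <- character()
  if (is.null(base)) {
    for (i in seq_len(cfg$n_paved)) {
      polylines[[length(polylines) + 1L]] <- trunk_line(xr, yr)
      cls <- c(cls, "paved")
    }
    paved <- polylines
    for (i in seq_len(cfg$n_unpaved)) {
      p <- paved[[sample.int(length(paved), 1L)]]
      v <- p[sample.int(nrow(p), 1L), ]
      polylines[[length(polylines) + 1L]] <-
        branch_line(v, stats::runif(1, 20, 60))
      cls <- c(cls, "unpaved")
    }
  } else {
    polylines <- base$polylines; cls <- base$class
    for (i in seq_len(extra_paved)) {
      polylines[[length(polylines) + 1L]] <- trunk_line(xr, yr)
      cls <- c(cls, "paved")
    }
  }
  road_set(polylines, cls)
}

#' Generate the synthetic covariate stack and primitive inputs
#'
#' Builds the eight model covariates — shrubland fraction, grassland
#' fraction, deforestation fraction, weighted road distance, settlement
#' kernel density, protected-area categories, temperature anomaly and MCWD
#' anomaly (both for the drought calibration year) — each derived from
#' primitive inputs via the production covariate operators, never shortcut.
#' Also returns the monthly climate series, the road and settlement sets, a
#' categorical zoning map, three synthetic aboveground-biomass datasets, and
#' (in `$aux`) the fine-resolution source maps, per-year MCWD and
#' temperature layers, and the wet-year anomaly pair used by scenarios.
#'
#' @param config a [landscape_config()].
#' @return a list of class `fire_landscape`.
#' @export
generate_covariates <- function(config = landscape_config()) {
  stopifnot(inherits(config, "landscape_config"))
  cfg <- config
  if (cfg$n_rows < 8L || cfg$n_cols < 8L) stop("degenerate grid dimensions")
  with_seed(cfg$seed, {
    nr <- cfg$n_rows; nc <- cfg$n_cols
    grid <- fire_grid(nr, nc, cfg$cell_size,
                      origin = c(0, nr * cfg$cell_size))
    f <- 2L                                  # fine grid factor
    fgrid <- fire_grid(nr * f, nc * f, cfg$cell_size / f, grid$origin)
    ls_f <- cfg$lc_length_scale / (cfg$cell_size / f)

    # --- land cover: argmax of three correlated tendencies ---------------
    forest_t <- gaussian_field(nr * f, nc * f, ls_f) + 0.4
    shrub_t <- gaussian_field(nr * f, nc * f, ls_f)
    grass_t <- gaussian_field(nr * f, nc * f, ls_f)
    lc_code <- matrix(1L, nr * f, nc * f)
    lc_code[shrub_t > forest_t & shrub_t >= grass_t] <- 2L
    lc_code[grass_t > forest_t & grass_t > shrub_t] <- 3L
    fine_landcover <- fire_layer(fgrid, lc_code, name = "landcover",
                                 kind = "categorical", codes = 1:3)
    shrubland <- landcover_fraction(fine_landcover, 2L, f, name = "shrubland")
    grassland <- landcover_fraction(fine_landcover, 3L, f, name = "grassland")
    forest_frac <- landcover_fraction(fine_landcover, 1L, f, name = "forest")

    # --- roads and weighted distance -------------------------------------
    roads <- make_roads(cfg, grid)
    road_distance <- distance_to_roads(roads, grid)
    dist_km <- road_distance$values / 1000

    # --- settlements near roads, log-normal populations -------------------
    w <- exp(-dist_km / 8); w[is.na(w)] <- 0; w <- w / sum(w)
    sc <- sample.int(n_cells(grid), cfg$n_settlements, prob = as.numeric(w))
    scc <- cell_centers(grid, sc)
    settlements <- settlement_set(
      scc[, 1] + stats::runif(cfg$n_settlements, -0.4, 0.4),
      scc[, 2] + stats::runif(cfg$n_settlements, -0.4, 0.4),
      stats::rlnorm(cfg$n_settlements, cfg$pop_meanlog, cfg$pop_sdlog))
    settlement_dens <- settlement_density(settlements, grid,
                                          bandwidth = cfg$kde_bandwidth)
    settlement_dens$name <- "settlement_density"

    # --- deforestation: fine Bernoulli map concentrated near roads --------
    grf_d <- gaussian_field(nr * f, nc * f,
                            cfg$defor_length_scale / (cfg$cell_size / f))
    dist_fine <- kronecker(dist_km, matrix(1, f, f))
    p_def <- stats::plogis(-3.2 + 1.2 * grf_d + 3.0 * exp(-dist_fine / 4))
    fine_defor <- fire_layer(
      fgrid, matrix(stats::rbinom(length(p_def), 1L, as.numeric(p_def)),
                    nr * f, nc * f), name = "defor")
    deforestation <- aggregate_fraction(fine_defor, f, name = "deforestation")

    # --- blocky protected areas (codes 1-4 on 0 background) --------------
    prot <- matrix(0L, nr, nc)
    for (b in seq_len(cfg$n_protected_blocks)) {
      h <- sample(15:40, 1L); wd <- sample(15:40, 1L)
      r0 <- sample.int(max(1L, nr - h), 1L)
      c0 <- sample.int(max(1L, nc - wd), 1L)
      prot[r0:(r0 + h - 1L), c0:(c0 + wd - 1L)] <- (b - 1L) %% 4L + 1L
    }
    protected <- fire_layer(grid, prot, name = "protected",
                            kind = "categorical", codes = 0:4)

    # --- monthly climate series ------------------------------------------
    ny <- length(cfg$years)
    precip <- array(0, c(nr, nc, ny, 12L))
    temp <- array(0, c(nr, nc, ny, 12L))
    spat_p <- exp(0.2 * gaussian_field(nr, nc, cfg$lc_length_scale))
    spat_t <- 1.5 * gaussian_field(nr, nc, cfg$lc_length_scale)
    seas_t <- 1.5 * sin(2 * pi * (seq_len(12L) - 3) / 12)
    yr_off_t <- stats::rnorm(ny, 0, 0.3)
    yr_fac_p <- stats::rnorm(ny, 1, 0.08)
    for (yi in seq_len(ny)) {
      y <- cfg$years[yi]
      dry <- y == cfg$dry_year
      if (dry) yr_off_t[yi] <- cfg$dry_year_warming
      if (y == cfg$wet_year) yr_fac_p[yi] <- max(yr_fac_p[yi], 1.08)
      for (m in 1:12) {
        fac <- yr_fac_p[yi] * (if (dry && m %in% DRY_SEASON_MONTHS)
          cfg$dry_season_factor else if (dry) 0.9 else 1)
        precip[, , yi, m] <- cfg$monthly_precip[m] * fac * spat_p *
          exp(stats::rnorm(1, 0, 0.08))
        temp[, , yi, m] <- cfg$temp_base + seas_t[m] + yr_off_t[yi] +
          spat_t + stats::rnorm(1, 0, 0.15)
      }
    }
    climate <- climate_series(grid, cfg$years, precip, temp)

    # --- derived climate covariates via the production operators ----------
    mcwd_layers <- lapply(cfg$years, function(y)
      compute_mcwd(climate, y, threshold = 100, reset_month = 1L))
    names(mcwd_layers) <- cfg$years
    tmean_layers <- lapply(seq_len(ny), function(yi) {
      fire_layer(grid, apply(temp[, , yi, ], c(1, 2), mean),
                 name = sprintf("tmean_%d", cfg$years[yi]), units = "K")
    })
    names(tmean_layers) <- cfg$years
    mcwd_anom_dry <- compute_anomaly(mcwd_layers, cfg$dry_year)
    mcwd_anom_wet <- compute_anomaly(mcwd_layers, cfg$wet_year)
    temp_anom_dry <- compute_anomaly(tmean_layers, cfg$dry_year)
    temp_anom_wet <- compute_anomaly(tmean_layers, cfg$wet_year)
    mcwd_anom_dry$name <- "mcwd_anomaly"; temp_anom_dry$name <- "temperature_anomaly"

    stack <- fire_stack(list(
      shrubland, grassland, deforestation, road_distance, settlement_dens,
      protected,
      stack_named(temp_anom_dry, "temperature_anomaly"),
      stack_named(mcwd_anom_dry, "mcwd_anomaly")))

    # --- zoning map: majority land-cover code per coarse cell -------------
    zmaj <- matrix(1L, nr, nc)
    zmaj[shrubland$values >= pmax(forest_frac$values, grassland$values)] <- 2L
    zmaj[grassland$values > pmax(forest_frac$values, shrubland$values)] <- 3L
    zmaj[deforestation$values > 0.3] <- 4L
    zones <- fire_layer(grid, zmaj, name = "zones", kind = "categorical",
                        codes = 1:4)

    # --- synthetic AGB datasets (Mg/ha), higher under forest --------------
    agb <- agb_stack(lapply(1:3, function(k) {
      base <- c(60, 80, 50)[k]; slope <- c(150, 120, 170)[k]
      noise <- c(15, 20, 25)[k]
      fire_layer(grid, pmax(0, base + slope * forest_frac$values +
                              noise * gaussian_field(nr, nc, 10)),
                 name = paste0("agb", k), units = "Mg/ha")
    }))

    spread <- stats::plogis(gaussian_field(nr, nc, cfg$defor_length_scale)) *
      exp(-dist_km / 6)

    structure(list(
      stack = stack, climate = climate, roads = roads,
      settlements = settlements, zones = zones, agb = agb, config = cfg,
      aux = list(fine_landcover = fine_landcover, fine_defor = fine_defor,
                 forest_fraction = forest_frac,
                 mcwd_layers = mcwd_layers, tmean_layers = tmean_layers,
                 mcwd_anomaly_dry = mcwd_anom_dry,
                 mcwd_anomaly_wet = mcwd_anom_wet,
                 temperature_anomaly_dry = temp_anom_dry,
                 temperature_anomaly_wet = temp_anom_wet,
                 spread_field = spread)), class = "fire_landscape")
  })
}

stack_named <- function(layer, name) { layer$name <- name; layer }

#' @export
print.fire_landscape <- function(x, ...) {
  cat(sprintf("<fire_landscape> %d x %d km, %d covariates, %d roads, %d settlements\n",
              x$stack$grid$n_rows, x$stack$grid$n_cols,
              length(x$stack$layers), length(x$roads$polylines),
              length(x$settlements$x)))
  invisible(x)
}

#' True fire suitability surface
#'
#' `p*(x) = logistic(intercept + sum_v w_v z_v(x))` with each weighted
#' covariate standardized (mean 0, sd 1) over unmasked cells; optionally
#' multiplied by an inhibition factor inside protected cells. This is the
#' generative ground truth that presences are sampled from, against which
#' model recovery is judged.
#'
#' @param stack a `fire_stack`.
#' @param weights named weights over a subset of continuous stack variables.
#' @param intercept intercept on the linear predictor.
#' @param inhibition optional list `(var =, factor =)`: multiply p* by
#'   `factor` where the categorical layer `var` has code > 0.
#' @return object of class `ground_truth` with the probability layer and the
#'   generative parameters.
#' @export
true_probability <- function(stack, weights, intercept = 0,
                             inhibition = NULL) {
  stopifnot(inherits(stack, "fire_stack"))
  g <- stack$grid
  eta <- matrix(intercept, g$n_rows, g$n_cols)
  for (v in names(weights)) {
    l <- stack$layers[[v]]
    if (is.null(l)) stop("unknown variable in weights: ", v)
    if (l$kind != "continuous")
      stop("cannot standardize categorical variable: ", v)
    vals <- l$values[g$mask]
    z <- (l$values - mean(vals)) / stats::sd(vals)
    eta <- eta + weights[[v]] * z
  }
  p <- stats::plogis(eta)
  if (!is.null(inhibition)) {
    l <- stack$layers[[inhibition$var]]
    if (is.null(l)) stop("unknown inhibition variable: ", inhibition$var)
    idx <- which(l$values > 0)
    p[idx] <- p[idx] * inhibition$factor
  }
  structure(list(prob = fire_layer(g, p, name = "true_probability"),
                 weights = weights, intercept = intercept,
                 inhibition = inhibition), class = "ground_truth")
}

#' Sample presence-only hotspots from a ground truth
#'
#' Draws `n` presences with per-cell selection probability proportional to
#' the true suitability (with replacement, so one cell can hold several
#' detections), months from `month_weights` and years uniformly.
#'
#' @param truth a [true_probability()] result.
#' @param n number of presences.
#' @param seed integer seed.
#' @param month_weights 12 probabilities summing to 1; default concentrated
#'   on August-September (~83% of fires in the two peak months).
#' @param years years to assign uniformly.
#' @return a [presence_sample()].
#' @export
sample_hotspots <- function(truth, n, seed = 1L,
                            month_weights = landscape_config()$month_weights,
                            years = 2001:2010) {
  stopifnot(inherits(truth, "ground_truth"), n >= 1L,
            abs(sum(month_weights) - 1) < 1e-6)
  g <- truth$prob$grid
  cells <- which(g$mask)
  p <- truth$prob$values[cells]
  if (all(p == 0)) stop("true probability is zero everywhere")
  with_seed(seed, {
    pick <- cells[sample.int(length(cells), n, replace = TRUE, prob = p)]
    presence_sample(row = (pick - 1L) %% g$n_rows + 1L,
                    col = (pick - 1L) %/% g$n_rows + 1L,
                    year = sample(years, n, replace = TRUE),
                    month = sample.int(12L, n, replace = TRUE,
                                       prob = month_weights))
  })
}

#' Construct a scenario fixture with known direction of change
#'
#' Builds replacement layers emulating the three development trajectories:
#' `A_like` (sustainability) — minimal deforestation growth, no new roads,
#' new protected blocks placed where the true suitability of the base
#' landscape is highest; `B_like` (business as usual) — moderate
#' deforestation growth and one new paved trunk road; `C_like` (rapid
#' growth) — strong deforestation growth and three new paved roads
#' (including B's). Deforestation growth shares one spread field, so
#' C >= B >= A cell-wise by construction. `climate = "dry"` swaps in the
#' drought-year anomaly pair, `"wet"` the normal-year pair.
#'
#' @param landscape a `fire_landscape` from [generate_covariates()].
#' @param mode `"A_like"`, `"B_like"` or `"C_like"`.
#' @param climate `"wet"` or `"dry"`.
#' @return a [scenario_spec()].
#' @export
make_scenario_fixture <- function(landscape,
                                  mode = c("A_like", "B_like", "C_like"),
                                  climate = c("wet", "dry")) {
  stopifnot(inherits(landscape, "fire_landscape"))
  mode <- match.arg(mode)
  climate <- match.arg(climate)
  cfg <- landscape$config
  base <- landscape$stack
  g <- base$grid
  growth <- c(A_like = 0.05, B_like = 0.30, C_like = 0.60)[[mode]]
  repl <- list()
  defo <- pmin(1, base$layers$deforestation$values +
                 growth * landscape$aux$spread_field)
  repl$deforestation <- fire_layer(g, defo, name = "deforestation")

  if (mode %in% c("B_like", "C_like")) {
    n_new <- if (mode == "B_like") 1L else 3L
    roads2 <- with_seed(cfg$seed + 101L,
                        make_roads(cfg, g, extra_paved = 3L,
                                   base = landscape$roads))
    keep <- seq_len(length(landscape$roads$polylines) + n_new)
    roads2 <- road_set(roads2$polylines[keep], roads2$class[keep],
                       roads2$weights)
    repl$road_distance <- distance_to_roads(roads2, g)
  }

  if (mode == "A_like") {
    truth <- true_probability(
      base, cfg$true_weights, cfg$intercept,
      inhibition = list(var = "protected", factor = cfg$protected_inhibition))
    prot <- base$layers$protected$values
    p <- truth$prob$values
    p[is.na(p)] <- -Inf
    p[which(prot > 0)] <- -Inf
    pm <- prot
    for (b in 1:2) {                       # two new 20x20 blocks, code 2
      top <- which.max(p)
      r0 <- max(1L, min(g$n_rows - 19L, (top - 1L) %% g$n_rows - 9L))
      c0 <- max(1L, min(g$n_cols - 19L, (top - 1L) %/% g$n_rows - 9L))
      pm[r0:(r0 + 19L), c0:(c0 + 19L)] <- 2L
      p[r0:(r0 + 19L), c0:(c0 + 19L)] <- -Inf
    }
    repl$protected <- fire_layer(g, pm, name = "protected",
                                 kind = "categorical", codes = 0:4)
  }

  if (climate == "dry") {
    repl$mcwd_anomaly <- stack_named(landscape$aux$mcwd_anomaly_dry,
                                     "mcwd_anomaly")
    repl$temperature_anomaly <- stack_named(
      landscape$aux$temperature_anomaly_dry, "temperature_anomaly")
  } else {
    repl$mcwd_anomaly <- stack_named(landscape$aux$mcwd_anomaly_wet,
                                     "mcwd_anomaly")
    repl$temperature_anomaly <- stack_named(
      landscape$aux$temperature_anomaly_wet, "temperature_anomaly")
  }
  scenario_spec(paste0(mode, "_", climate), repl,
                climate_mode = if (climate == "dry") "dry_year" else
                  "wet_year")
}
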
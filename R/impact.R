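RISK_CLASSES <- data.frame(
  class = c("low", "moderate", "high", "extreme"),
  lower = c(0, 0.25, 0.5, 0.75),
  upper = c(0.25, 0.5, 0.75, 1),
  stringsAsFactors = FALSE)

check_probability_layer <- function(risk) {
  v <- risk$values[risk$grid$mask]
  if (any(v < 0 | v > 1)) stop("risk layer values must lie in [0, 1]")
  v
}

#' Classify a risk map into the four standard classes
#'
#' Partitions probability into low \[0, 0.25), moderate \[0.25, 0.5), high
#' \[0.5, 0.75) and extreme \[0.75, 1\] (half-open intervals, upper class
#' closed; a value of exactly 0.5 is classed high). Class areas always sum to
#' the total unmasked area.
#'
#' @param risk probability `fire_layer` in \[0, 1\].
#' @return object of class `risk_classification`: list with `table` (class,
#'   bounds, cells, area_km2) and `total_area_km2`.
#' @export
classify_risk <- function(risk) {
  v <- check_probability_layer(risk)
  area <- risk$grid$cell_size^2
  idx <- findInterval(v, c(RISK_CLASSES$lower, 1), rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = 4L)
  tab <- cbind(RISK_CLASSES,
               cells = counts, area_km2 = counts * area)
  structure(list(table = tab, total_area_km2 = length(v) * area),
            class = "risk_classification")
}

#' @export
print.risk_classification <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("total %.0f km2\n", x$total_area_km2))
  invisible(x)
}

#' Area at high fire risk
#'
#' @param risk probability `fire_layer`.
#' @param threshold strict probability threshold, default 0.5.
#' @return area in km2 of cells with probability strictly above the
#'   threshold.
#' @export
high_risk_area <- function(risk, threshold = 0.5) {
  v <- check_probability_layer(risk)
  sum(v > threshold) * risk$grid$cell_size^2
}

#' Bundle aboveground-biomass datasets
#'
#' Holds one or more AGB layers (Mg ha^-1, >= 0) and their cell-wise
#' arithmetic mean; using several independent datasets gives an uncertainty
#' envelope on biomass-loss estimates.
#'
#' @param ... `fire_layer`s of AGB, or a single list of them.
#' @return object of class `agb_stack` with `layers` and `mean_layer`.
#' @export
agb_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && !inherits(layers[[1]], "fire_layer"))
    layers <- layers[[1]]
  stopifnot(length(layers) >= 1L,
            all(vapply(layers, inherits, TRUE, "fire_layer")))
  g <- layers[[1]]$grid
  acc <- matrix(0, g$n_rows, g$n_cols)
  for (l in layers) {
    if (!same_grid(g, l$grid)) stop_grid_mismatch("AGB layers")
    if (any(l$values[g$mask] < 0)) stop("AGB must be non-negative")
    acc <- acc + l$values
  }
  if (is.null(names(layers)))
    names(layers) <- vapply(layers, `[[`, "", "name")
  structure(list(layers = layers,
                 mean_layer = fire_layer(g, acc / length(layers),
                                         name = "agb_mean",
                                         units = "Mg/ha")),
            class = "agb_stack")
}

#' Potential aboveground-biomass loss from a risk map
#'
#' For cells above the high-risk threshold, potential post-fire loss per
#' cell is `B_l = (1 - alpha) * B_i` (Mg ha^-1), where `alpha` is the
#' proportion of AGB remaining post-fire. With the default endpoints
#' (0.7084, 0.90) the central loss factor is the mean of the two
#' `(1 - alpha)` values, 0.1958, with half-range 0.0958 — i.e. a loss factor
#' of about 0.196 +/- 0.096 spanning losses one to five years post-fire,
#' without fire recurrence. Totals use the cell-wise mean AGB across
#' datasets (per-dataset totals are also reported); 1 km2 = 100 ha and
#' 1 Tg = 1e6 Mg.
#'
#' @param risk probability `fire_layer`.
#' @param agb an [agb_stack()] (or single AGB `fire_layer`).
#' @param alpha_low,alpha_high proportion of AGB remaining post-fire, both
#'   in (0, 1\] with `alpha_low <= alpha_high`. Defaults 0.7084 and 0.90.
#' @param threshold cells with probability strictly above this contribute to
#'   the loss total, default 0.5.
#' @param bin_width probability bin width for the per-bin report, default
#'   0.1.
#' @return object of class `impact_report`: per-bin table (mean AGB per
#'   dataset and averaged, central/low/high loss in Tg), totals with the
#'   envelope, loss factors, and the high-risk area.
#' @export
agb_loss <- function(risk, agb, alpha_low = 0.7084, alpha_high = 0.90,
                     threshold = 0.5, bin_width = 0.1) {
  if (inherits(agb, "fire_layer")) agb <- agb_stack(list(agb))
  stopifnot(inherits(agb, "agb_stack"))
  if (alpha_low <= 0 || alpha_low > 1 || alpha_high <= 0 || alpha_high > 1)
    stop("alpha endpoints must lie in (0, 1]")
  if (alpha_low > alpha_high) stop("alpha_low must be <= alpha_high")
  if (!same_grid(risk$grid, agb$mean_layer$grid))
    stop_grid_mismatch("risk and AGB layers")
  v <- check_probability_layer(risk)
  g <- risk$grid
  cells <- which(g$mask)
  p <- risk$values[cells]
  b_mean <- agb$mean_layer$values[cells]
  ha_per_cell <- g$cell_size^2 * 100          # 1 km2 = 100 ha
  lf_lo <- 1 - alpha_high                     # smallest loss factor
  lf_hi <- 1 - alpha_low
  lf_central <- (lf_lo + lf_hi) / 2
  lf_half <- (lf_hi - lf_lo) / 2

  edges <- seq(0, 1, by = bin_width)
  if (max(edges) < 1) edges <- c(edges, 1)
  bin <- pmin(findInterval(p, edges, rightmost.closed = TRUE),
              length(edges) - 1L)
  nb <- length(edges) - 1L
  mean_by_bin <- function(x) {
    s <- tapply(x, factor(bin, levels = seq_len(nb)), mean)
    as.numeric(s)
  }
  tab <- data.frame(bin_lower = edges[-length(edges)], bin_upper = edges[-1],
                    cells = tabulate(bin, nbins = nb),
                    agb_mean = mean_by_bin(b_mean))
  for (nm in names(agb$layers))
    tab[[paste0("agb_", nm)]] <- mean_by_bin(agb$layers[[nm]]$values[cells])

  incl <- p > threshold
  loss_in_bin <- function(lf) {
    mg <- rep(0, nb)
    if (any(incl)) {
      s <- tapply(lf * b_mean[incl] * ha_per_cell,
                  factor(bin[incl], levels = seq_len(nb)), sum)
      mg[!is.na(s)] <- s[!is.na(s)]
    }
    mg / 1e6                                   # Mg -> Tg
  }
  tab$loss_tg <- loss_in_bin(lf_central)
  tab$loss_tg_low <- loss_in_bin(lf_lo)
  tab$loss_tg_high <- loss_in_bin(lf_hi)

  per_dataset <- vapply(names(agb$layers), function(nm) {
    b <- agb$layers[[nm]]$values[cells]
    sum(lf_central * b[incl] * ha_per_cell) / 1e6
  }, 0)

  structure(list(
    bins = tab,
    total_tg = sum(tab$loss_tg),
    total_tg_low = sum(tab$loss_tg_low),
    total_tg_high = sum(tab$loss_tg_high),
    per_dataset_tg = per_dataset,
    loss_factor_central = lf_central, loss_factor_half_range = lf_half,
    alpha = c(low = alpha_low, high = alpha_high),
    threshold = threshold,
    high_risk_km2 = sum(incl) * g$cell_size^2), class = "impact_report")
}

#' @export
print.impact_report <- function(x, ...) {
  cat(sprintf("Potential AGB loss above p > %.2f: %.3f Tg (envelope %.3f-%.3f)\n",
              x$threshold, x$total_tg, x$total_tg_low, x$total_tg_high))
  cat(sprintf("Loss factor %.4f (+/- %.4f), high-risk area %.0f km2\n",
              x$loss_factor_central, x$loss_factor_half_range,
              x$high_risk_km2))
  invisible(x)
}

#' Zonal statistics of risk over a categorical map
#'
#' Per category of a zoning map (e.g. land-use/land-cover or land-use-plan
#' categories): mean and standard deviation of risk, cell count, area, and
#' area above the 0.5 high-risk threshold. Categories declared but absent
#' get a zero count and an `NA` mean flagged in `empty`.
#'
#' @param risk probability `fire_layer`.
#' @param zones categorical `fire_layer` on the same grid.
#' @return data frame (code, count, area_km2, mean, sd, area_above_0.5_km2,
#'   empty).
#' @export
zonal_stats <- function(risk, zones) {
  stopifnot(inherits(zones, "fire_layer"))
  if (zones$kind != "categorical") stop("zones must be a categorical layer")
  if (!same_grid(risk$grid, zones$grid))
    stop_grid_mismatch("risk and zone layers")
  v <- check_probability_layer(risk)
  g <- risk$grid
  cells <- which(g$mask)
  z <- factor(zones$values[cells], levels = zones$codes)
  p <- risk$values[cells]
  area <- g$cell_size^2
  cnt <- as.numeric(table(z))
  out <- data.frame(
    code = zones$codes,
    count = cnt,
    area_km2 = cnt * area,
    mean = as.numeric(tapply(p, z, mean)),
    sd = as.numeric(tapply(p, z, stats::sd)),
    area_above_0.5_km2 = as.numeric(tapply(p > 0.5, z, sum)) * area)
  out$area_above_0.5_km2[is.na(out$area_above_0.5_km2)] <- 0
  out$empty <- out$count == 0
  out
}

#' Monthly histogram of hotspot detections
#'
#' Counts presences per calendar month and summarises fire seasonality: the
#' two peak months with their combined fraction, and the largest fraction in
#' any contiguous 3-month window (December wraps to January).
#'
#' @param presences a `presence_sample` with month recorded on every row.
#' @return list with `counts` (named 12-vector), `peak_months`,
#'   `top2_fraction`, `top_3month_fraction`, `top_3month_window`.
#' @export
hotspot_monthly_histogram <- function(presences) {
  m <- presences$month
  if (any(is.na(m))) stop("all presence records must carry a month")
  if (any(m < 1L | m > 12L)) stop("months must lie in 1..12")
  counts <- tabulate(m, nbins = 12L)
  names(counts) <- month.abb
  n <- sum(counts)
  ord <- order(counts, decreasing = TRUE)
  win <- vapply(1:12, function(s)
    sum(counts[((s - 1L):(s + 1L)) %% 12L + 1L]), 0)
  best <- which.max(win)
  list(counts = counts,
       peak_months = month.abb[ord[1:2]],
       top2_fraction = sum(counts[ord[1:2]]) / n,
       top_3month_fraction = win[best] / n,
       top_3month_window = month.abb[((best - 1L):(best + 1L)) %% 12L + 1L])
}
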
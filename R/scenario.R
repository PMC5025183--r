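DYNAMIC_VARIABLES <- c("deforestation", "road_distance", "protected",
                       "temperature_anomaly", "mcwd_anomaly")

# accepted aliases for dynamic variable names in scenario specs
normalize_dynamic <- function(nm) {
  map <- c(roads = "road_distance", protected_areas = "protected")
  out <- ifelse(nm %in% names(map), map[nm], nm)
  unname(out)
}

#' Define a projection scenario
#'
#' A scenario is a named set of replacement layers for the dynamic variables
#' (deforestation, roads, protected areas and the two climate anomalies) plus
#' a climate-mode tag; all other variables are maintained unchanged when the
#' scenario is applied.
#'
#' @param name scenario label (e.g. "A", "B", "C").
#' @param replacements named list of `fire_layer`s keyed by dynamic variable
#'   name (`deforestation`, `road_distance`/`roads`,
#'   `protected`/`protected_areas`, `temperature_anomaly`, `mcwd_anomaly`).
#' @param climate_mode `"wet_year"` or `"dry_year"`; dry-year anomaly layers
#'   emulate more severe drought conditions.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, replacements = list(),
                          climate_mode = c("wet_year", "dry_year")) {
  climate_mode <- match.arg(climate_mode)
  if (length(replacements)) {
    names(replacements) <- normalize_dynamic(names(replacements))
    bad <- setdiff(names(replacements), DYNAMIC_VARIABLES)
    if (length(bad))
      stop("only dynamic variables may be replaced in a scenario; not: ",
           paste(bad, collapse = ", "))
    stopifnot(all(vapply(replacements, inherits, TRUE, "fire_layer")))
  }
  structure(list(name = name, replacements = replacements,
                 climate_mode = climate_mode), class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> '%s' (%s): replaces {%s}\n", x$name,
              x$climate_mode, paste(names(x$replacements), collapse = ", ")))
  invisible(x)
}

#' Apply a scenario to a base covariate stack
#'
#' Returns a new stack equal to the base except for the replaced dynamic
#' layers; the base stack is unmodified. Replacement layers must share the
#' base grid.
#'
#' @param base a `fire_stack`.
#' @param spec a [scenario_spec()].
#' @return a `fire_stack`.
#' @export
apply_scenario <- function(base, spec) {
  stopifnot(inherits(base, "fire_stack"), inherits(spec, "scenario_spec"))
  out <- base
  for (nm in names(spec$replacements)) {
    if (is.null(base$layers[[nm]]))
      stop("scenario replaces a variable absent from the base stack: ", nm)
    repl <- spec$replacements[[nm]]
    if (!same_grid(base$grid, repl$grid)) stop_grid_mismatch("scenario layers")
    repl$kind <- base$layers[[nm]]$kind
    repl$codes <- if (repl$kind == "categorical")
      sort(unique(c(base$layers[[nm]]$codes,
                    as.integer(repl$values[base$grid$mask])))) else NULL
    out <- stack_replace(out, nm, repl)
  }
  out
}

#' Project fitted model replicates onto a scenario
#'
#' Evaluates the clamped logistic prediction of each fitted replicate on the
#' scenario stack, averages cell-wise, and summarises the area at high fire
#' risk (probability above 0.5).
#'
#' @param models a single `maxent_fire` or a list of fitted replicates (e.g.
#'   from [replicate_cv()]).
#' @param spec a [scenario_spec()].
#' @param base base covariate stack the replacements modify.
#' @param threshold high-risk probability threshold, default 0.5 (strict).
#' @return an object of class `scenario_result` with `mean_layer`, `layers`,
#'   `clamped_fraction` (mean over replicates), `high_risk_km2` and the spec.
#' @export
project_scenario <- function(models, spec, base, threshold = 0.5) {
  if (inherits(models, "maxent_fire")) models <- list(models)
  stopifnot(length(models) >= 1L,
            all(vapply(models, inherits, TRUE, "maxent_fire")))
  stack <- apply_scenario(base, spec)
  layers <- vector("list", length(models))
  clamped <- numeric(length(models))
  acc <- NULL
  for (i in seq_along(models)) {
    layers[[i]] <- predict(models[[i]], stack, type = "logistic",
                           clamp = TRUE)
    clamped[i] <- attr(layers[[i]], "clamped_fraction")
    acc <- if (is.null(acc)) layers[[i]]$values else acc + layers[[i]]$values
  }
  mean_layer <- fire_layer(stack$grid, acc / length(models),
                           name = paste0("risk_", spec$name))
  structure(list(spec = spec, mean_layer = mean_layer, layers = layers,
                 clamped_fraction = mean(clamped),
                 high_risk_km2 = high_risk_area(mean_layer, threshold)),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> '%s' (%s): high-risk area %.0f km2, %.1f%% cells clamped\n",
              x$spec$name, x$spec$climate_mode, x$high_risk_km2,
              100 * x$clamped_fraction))
  invisible(x)
}

#' Compare two scenario results
#'
#' @param a,b `scenario_result`s on the same grid.
#' @return list with the cell-wise difference layer (a - b), the high-risk
#'   area ratio and percent difference, and per-risk-class area tables for
#'   both scenarios.
#' @export
compare_scenarios <- function(a, b) {
  stopifnot(inherits(a, "scenario_result"), inherits(b, "scenario_result"))
  if (!same_grid(a$mean_layer$grid, b$mean_layer$grid))
    stop_grid_mismatch("scenario results")
  diff <- fire_layer(a$mean_layer$grid,
                     a$mean_layer$values - b$mean_layer$values,
                     name = sprintf("diff_%s_minus_%s", a$spec$name,
                                    b$spec$name))
  ca <- classify_risk(a$mean_layer)$table
  cb <- classify_risk(b$mean_layer)$table
  classes <- data.frame(class = ca$class,
                        area_a_km2 = ca$area_km2, area_b_km2 = cb$area_km2)
  list(difference = diff,
       high_risk_ratio = a$high_risk_km2 / b$high_risk_km2,
       high_risk_pct_difference =
         100 * (a$high_risk_km2 - b$high_risk_km2) / b$high_risk_km2,
       class_areas = classes)
}

#' Threshold-independent specificity of a projection
#'
#' Distribution of observed presences over the probability bins of a
#' projected risk layer: the count and fraction of observed hotspots falling
#' in each bin, plus the fraction above the 0.5 high-risk threshold. Used to
#' validate a projection for a year not used in fitting.
#'
#' @param risk a probability `fire_layer` in \[0, 1\].
#' @param observed a `presence_sample` on the risk grid.
#' @param bin_width probability bin width, default 0.1; bins are half-open
#'   with the top bin closed.
#' @return data frame (bin_lower, bin_upper, count, fraction) with attribute
#'   `fraction_above_0.5`.
#' @export
specificity_validation <- function(risk, observed, bin_width = 0.1) {
  if (nrow(observed) == 0L) stop("empty observed sample")
  cells <- presence_cells(observed, risk$grid)
  p <- risk$values[cells]
  edges <- seq(0, 1, by = bin_width)
  if (max(edges) < 1) edges <- c(edges, 1)
  bin <- pmin(findInterval(p, edges, rightmost.closed = TRUE),
              length(edges) - 1L)
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  out <- data.frame(bin_lower = edges[-length(edges)],
                    bin_upper = edges[-1], count = counts,
                    fraction = counts / length(p))
  attr(out, "fraction_above_0.5") <- mean(p > 0.5)
  out
}
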
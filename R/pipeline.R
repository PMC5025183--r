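#' Run the full fire-risk analysis pipeline
#'
#' Sequences the whole analysis on a synthetic landscape: covariate
#' generation, train/test split, model fitting with cross-validation
#' replicates, evaluation (AUC, variable importances, optional jackknife,
#' specificity of the risk map against held-out hotspots), scenario
#' projections, and impact accounting (risk classes, biomass-loss envelope,
#' zonal statistics). Every declared artifact is written under `out_dir`
#' (rasters as ESRI ASCII grids, tables as CSV, model and manifest as JSON)
#' and a manifest records inputs, seeds, settings and file checksums, which
#' suffice to reproduce deterministic artifacts bit-exactly.
#'
#' @param config list of settings; recognised entries (with defaults):
#'   `landscape` (a [landscape_config()]), `n_presences` (2000),
#'   `test_fraction` (0.25), `k_replicates` (4), `reg_multiplier` (1),
#'   `max_iter` (500), `tau` (0.5), `jackknife` (FALSE), `scenarios`
#'   (character of modes among A_like/B_like/C_like), `climates`
#'   (`c("wet", "dry")`), `alpha_low` (0.7084), `alpha_high` (0.90),
#'   `threshold` (0.5).
#' @param out_dir output directory, created if absent.
#' @param seed master seed; all randomness derives from it.
#' @return the manifest (invisibly), a list also written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1L) {
  cf <- utils::modifyList(list(
    n_presences = 2000L, test_fraction = 0.25, k_replicates = 4L,
    reg_multiplier = 1, max_iter = 500L, tau = 0.5, jackknife = FALSE,
    scenarios = c("A_like", "C_like"), climates = c("wet", "dry"),
    alpha_low = 0.7084, alpha_high = 0.90, threshold = 0.5), config)
  if (is.null(cf$landscape)) cf$landscape <- landscape_config(seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  put <- function(x, name, writer) {
    path <- file.path(out_dir, name)
    writer(x, path)
    files <<- c(files, path)
    path
  }
  msg <- function(...) message(sprintf(...))

  msg("[simulate] generating landscape (seed %d)", cf$landscape$seed)
  land <- generate_covariates(cf$landscape)
  truth <- true_probability(
    land$stack, cf$landscape$true_weights, cf$landscape$intercept,
    inhibition = list(var = "protected",
                      factor = cf$landscape$protected_inhibition))
  presences <- sample_hotspots(truth, cf$n_presences, seed = seed + 1L)
  for (nm in names(land$stack$layers))
    put(land$stack$layers[[nm]], paste0("covariate_", nm, ".asc"),
        write_raster)
  put(truth$prob, "true_probability.asc", write_raster)
  put(presences, "presences.csv", write_presences)

  msg("[fit] %d presences, 25%% held out", nrow(presences))
  sp <- split_sample(presences, cf$test_fraction, seed = seed + 2L)
  model <- fit_maxent(sp$train, land$stack,
                      reg_multiplier = cf$reg_multiplier, tau = cf$tau,
                      max_iter = cf$max_iter, seed = seed + 3L)
  put(model, "model.json", write_maxent)

  msg("[evaluate] AUC, importances%s",
      if (isTRUE(cf$jackknife)) ", jackknife" else "")
  ev <- evaluate_model(model, test = sp$test,
                       jackknife = isTRUE(cf$jackknife), seed = seed + 4L)
  put(data.frame(variable = names(ev$percent_contribution),
                 percent_contribution = as.numeric(ev$percent_contribution),
                 permutation_importance =
                   as.numeric(ev$permutation_importance)),
      "variable_importance.csv",
      function(x, p) utils::write.csv(x, p, row.names = FALSE))
  if (!is.null(ev$jackknife))
    put(ev$jackknife, "jackknife.csv",
        function(x, p) utils::write.csv(x, p, row.names = FALSE))

  msg("[replicates] %d cross-validation fits", cf$k_replicates)
  cv <- replicate_cv(sp$train, land$stack, k = cf$k_replicates,
                     seed = seed + 5L, reg_multiplier = cf$reg_multiplier,
                     max_iter = cf$max_iter)
  put(cv$mean_layer, "risk_mean.asc", write_raster)
  spec_tab <- specificity_validation(cv$mean_layer, sp$test)
  put(spec_tab, "specificity.csv",
      function(x, p) utils::write.csv(x, p, row.names = FALSE))

  msg("[impact] baseline risk classes, AGB loss, zonal statistics")
  baseline_impact <- agb_loss(cv$mean_layer, land$agb,
                              alpha_low = cf$alpha_low,
                              alpha_high = cf$alpha_high,
                              threshold = cf$threshold)
  put(baseline_impact$bins, "impact_baseline_bins.csv",
      function(x, p) utils::write.csv(x, p, row.names = FALSE))
  put(classify_risk(cv$mean_layer)$table, "risk_classes_baseline.csv",
      function(x, p) utils::write.csv(x, p, row.names = FALSE))
  put(zonal_stats(cv$mean_layer, land$zones), "zonal_baseline.csv",
      function(x, p) utils::write.csv(x, p, row.names = FALSE))

  scenario_rows <- list()
  for (mode in cf$scenarios) for (clim in cf$climates) {
    msg("[project] scenario %s / %s", mode, clim)
    spec <- make_scenario_fixture(land, mode, clim)
    res <- project_scenario(cv$models, spec, land$stack,
                            threshold = cf$threshold)
    tag <- paste0(mode, "_", clim)
    put(res$mean_layer, paste0("risk_", tag, ".asc"), write_raster)
    imp <- agb_loss(res$mean_layer, land$agb, alpha_low = cf$alpha_low,
                    alpha_high = cf$alpha_high, threshold = cf$threshold)
    scenario_rows[[tag]] <- data.frame(
      scenario = mode, climate = clim,
      high_risk_km2 = res$high_risk_km2,
      clamped_fraction = res$clamped_fraction,
      loss_tg = imp$total_tg, loss_tg_low = imp$total_tg_low,
      loss_tg_high = imp$total_tg_high)
  }
  if (length(scenario_rows))
    put(do.call(rbind, c(scenario_rows, make.row.names = FALSE)),
        "scenarios.csv",
        function(x, p) utils::write.csv(x, p, row.names = FALSE))

  manifest <- list(
    package_version = as.character(utils::packageVersion("firemaxent")),
    seed = seed,
    settings = cf[setdiff(names(cf), "landscape")],
    landscape = cf$landscape[setdiff(names(cf$landscape),
                                     c("true_weights", "month_weights",
                                       "monthly_precip"))],
    true_weights = as.list(cf$landscape$true_weights),
    results = list(
      training_auc = ev$training_auc, test_auc = ev$test_auc,
      gain = ev$gain,
      replicate_auc = cv$auc,
      specificity_above_0.5 = attr(spec_tab, "fraction_above_0.5"),
      baseline_high_risk_km2 = baseline_impact$high_risk_km2,
      baseline_loss_tg = baseline_impact$total_tg,
      scenarios = if (length(scenario_rows))
        do.call(rbind, c(scenario_rows, make.row.names = FALSE)) else NULL),
    files = as.list(stats::setNames(
      as.character(tools::md5sum(files)), basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
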
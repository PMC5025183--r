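#' Presence-background AUC
#'
#' Threshold-independent ROC area adapted to presence-only evaluation: the
#' probability that a randomly chosen presence outscores a randomly chosen
#' background point, with ties counted one half (rank-sum form). 0.5 means
#' the model does no better than random.
#'
#' @param scores_presence,scores_background numeric score vectors (any
#'   monotone output — raw and logistic give identical AUC).
#' @return a number in \[0, 1\].
#' @export
auc <- function(scores_presence, scores_background) {
  m <- length(scores_presence); n <- length(scores_background)
  if (m == 0L || n == 0L) stop("both score sets must be non-empty")
  r <- rank(c(scores_presence, scores_background))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

model_scores <- function(model, stack, cells) {
  vals <- stack_values(stack, model$features$variables, cells)
  as.numeric(feature_matrix(model$features, vals, clamp = TRUE) %*%
               model$lambda)
}

# training AUC of a fitted model: presences vs its own background
training_auc <- function(model, stack = model$stack) {
  sp <- model_scores(model, stack, model$presence_cells)
  sb <- model_scores(model, stack, model$background)
  auc(sp, sb)
}

#' Random train/test split of a presence sample
#'
#' Sets aside `round(m * test_fraction)` records for testing (default 25%),
#' reproducibly per seed; the partition is disjoint and exhaustive.
#'
#' @param presences a `presence_sample` with at least 4 records.
#' @param test_fraction fraction in (0, 1), default 0.25.
#' @param seed integer seed.
#' @return list with `train` and `test` presence samples.
#' @export
split_sample <- function(presences, test_fraction = 0.25, seed = 1L) {
  m <- nrow(presences)
  if (m < 4L) stop("need at least 4 presence records to split")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie in (0, 1)")
  n_test <- round(m * test_fraction)
  idx <- with_seed(seed, sample.int(m, n_test))
  list(train = presences[-idx, , drop = FALSE],
       test = presences[idx, , drop = FALSE])
}

#' Replicated cross-validation fits
#'
#' Splits the presence sample into `k` equal-sized folds and fits one model
#' per replicate leaving that fold out, returning per-replicate logistic
#' prediction layers and their cell-wise mean (the averaged output used in
#' impact analyses), plus the fitted models for scenario projection.
#'
#' @param presences a `presence_sample`.
#' @param stack covariate stack.
#' @param k number of replicates, default 10.
#' @param seed master seed; fold assignment and each replicate's background
#'   derive from it.
#' @param ... passed to [fit_maxent()].
#' @return list with `models`, `layers`, `mean_layer`, `auc` (training AUC
#'   per replicate) and `fold` assignments.
#' @export
replicate_cv <- function(presences, stack, k = 10L, seed = 1L, ...) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  m <- nrow(presences)
  if (m < k) stop("need at least k presence records")
  fold <- with_seed(seed, sample(rep_len(seq_len(k), m)))
  models <- vector("list", k); layers <- vector("list", k)
  aucs <- numeric(k)
  acc <- NULL
  for (i in seq_len(k)) {
    tr <- presences[fold != i, , drop = FALSE]
    models[[i]] <- fit_maxent(tr, stack, seed = seed + i, ...)
    layers[[i]] <- predict(models[[i]], type = "logistic")
    aucs[i] <- training_auc(models[[i]])
    acc <- if (is.null(acc)) layers[[i]]$values else acc + layers[[i]]$values
  }
  mean_layer <- fire_layer(stack$grid, acc / k, name = "risk_mean")
  list(models = models, layers = layers, mean_layer = mean_layer,
       auc = aucs, fold = fold)
}

#' Jackknife test of variable importance
#'
#' For each variable, the regularized training gain of the model fitted with
#' that variable alone and of the model omitting it, alongside the full
#' model's gain. A redundant variable leaves the without-gain essentially
#' unchanged; a pure-noise variable has alone-gain near zero.
#'
#' @param presences,stack as in [fit_maxent()].
#' @param features a [feature_config()].
#' @param ... passed to [fit_maxent()].
#' @return data frame (variable, gain_alone, gain_without) with attribute
#'   `full_gain`; with a single variable, returns the full-model gain only.
#' @export
jackknife_test <- function(presences, stack, features = feature_config(),
                           ...) {
  vars <- names(stack$layers)
  full <- fit_maxent(presences, stack, features = features, ...)
  if (length(vars) < 2L) {
    out <- data.frame(variable = vars, gain_alone = full$gain,
                      gain_without = NA_real_)
    attr(out, "full_gain") <- full$gain
    return(out)
  }
  gain_of <- function(keep) {
    st <- fire_stack(stack$layers[keep])
    fit_maxent(presences, st, features = features, ...)$gain
  }
  alone <- vapply(vars, function(v) gain_of(v), 0)
  without <- vapply(vars, function(v) gain_of(setdiff(vars, v)), 0)
  out <- data.frame(variable = vars, gain_alone = alone,
                    gain_without = without, row.names = NULL)
  attr(out, "full_gain") <- full$gain
  out
}

# per-variable share of accumulated gain increments along the fitting path,
# normalized to sum to 100; product features split evenly between parents
percent_contribution <- function(model) {
  vars <- model$features$variables
  acc <- stats::setNames(rep(0, length(vars)), vars)
  fv <- feature_vars(model$features)
  for (j in seq_along(fv)) {
    share <- max(0, model$contrib[j]) / length(fv[[j]])
    for (v in fv[[j]]) acc[v] <- acc[v] + share
  }
  tot <- sum(acc)
  if (tot <= 0) return(acc * 0)
  100 * acc / tot
}

#' Percent contribution and permutation importance
#'
#' Percent contribution attributes the gain accumulated during fitting to
#' source variables (normalized to 100). Permutation importance permutes one
#' variable's values across the combined presence + background points,
#' measures the training-AUC drop, and normalizes the drops to 100.
#'
#' @param model a fitted `maxent_fire` (with its training stack).
#' @param seed seed for the permutations.
#' @return list with named vectors `percent_contribution` and
#'   `permutation_importance`.
#' @export
variable_importance <- function(model, seed = 1L) {
  if (is.null(model$stack))
    stop("model carries no training stack; refit or supply one")
  vars <- model$features$variables
  cells <- c(model$presence_cells, model$background)
  m <- length(model$presence_cells)
  vals <- stack_values(model$stack, vars, cells)
  base_scores <- as.numeric(feature_matrix(model$features, vals) %*%
                              model$lambda)
  auc_full <- auc(base_scores[seq_len(m)], base_scores[-seq_len(m)])
  drops <- with_seed(seed, vapply(vars, function(v) {
    pv <- vals
    pv[, v] <- sample(pv[, v])
    sc <- as.numeric(feature_matrix(model$features, pv) %*% model$lambda)
    max(0, auc_full - auc(sc[seq_len(m)], sc[-seq_len(m)]))
  }, 0))
  tot <- sum(drops)
  perm <- if (tot > 0) 100 * drops / tot else drops
  list(percent_contribution = percent_contribution(model),
       permutation_importance = perm)
}

#' Factorial variable-group testing and parsimony pruning
#'
#' Fits one model per named variable group and one with all grouped
#' variables, then backward-prunes the full set: at each pass the variable
#' whose removal changes the regularized gain the least is dropped while
#' that change stays below `tol_gain` (variables not contributing
#' significantly to model gain). Reports gain and training AUC per
#' configuration and the retained set.
#'
#' @param presences,stack as in [fit_maxent()].
#' @param groups named list of character vectors partitioning a subset of
#'   the stack's variables (e.g. development / environment / climate).
#' @param tol_gain gain-change tolerance for pruning, default 0.01.
#' @param ... passed to [fit_maxent()].
#' @return list with `configurations` (data frame: name, n_vars, gain, auc),
#'   `retained` (character), and `pruning` trace.
#' @export
factorial_selection <- function(presences, stack, groups,
                                tol_gain = 0.01, ...) {
  stopifnot(is.list(groups), length(groups) >= 1L)
  if (any(vapply(groups, length, 0L) == 0L)) stop("empty variable group")
  allv <- unique(unlist(groups))
  if (!all(allv %in% names(stack$layers)))
    stop("group variable not present in stack")
  fit_of <- function(keep) fit_maxent(presences,
                                      fire_stack(stack$layers[keep]), ...)
  rows <- list()
  for (g in names(groups)) {
    mod <- fit_of(groups[[g]])
    rows[[g]] <- data.frame(name = g, n_vars = length(groups[[g]]),
                            gain = mod$gain, auc = training_auc(mod))
  }
  full <- fit_of(allv)
  rows[["all"]] <- data.frame(name = "all", n_vars = length(allv),
                              gain = full$gain, auc = training_auc(full))
  retained <- allv
  cur_gain <- full$gain
  trace <- list()
  while (length(retained) > 1L) {
    cand <- vapply(retained, function(v)
      fit_of(setdiff(retained, v))$gain, 0)
    delta <- cur_gain - cand
    worst <- which.min(delta)
    if (delta[worst] >= tol_gain) break
    trace[[length(trace) + 1L]] <- data.frame(
      removed = retained[worst], gain_change = delta[worst])
    cur_gain <- cand[worst]
    retained <- setdiff(retained, retained[worst])
  }
  if (length(retained) == 1L) {
    # a single remaining variable may itself be uninformative
    g1 <- fit_of(retained)$gain
    if (g1 < tol_gain) {
      trace[[length(trace) + 1L]] <- data.frame(removed = retained,
                                                gain_change = g1)
      retained <- character()
    }
  }
  rows[["retained"]] <- data.frame(
    name = "retained", n_vars = length(retained),
    gain = if (length(retained)) fit_of(retained)$gain else 0,
    auc = if (length(retained)) training_auc(fit_of(retained)) else 0.5)
  list(configurations = do.call(rbind, c(rows, make.row.names = FALSE)),
       retained = retained,
       pruning = if (length(trace)) do.call(rbind, trace) else NULL)
}

#' Full evaluation report for a fitted model
#'
#' Bundles training/test AUC, regularized training gain, per-variable
#' percent contribution and permutation importance, and the jackknife gains.
#'
#' @param model fitted `maxent_fire`.
#' @param test optional held-out `presence_sample` for the test AUC.
#' @param jackknife logical; refit the per-variable jackknife models.
#' @param seed seed for permutation importance.
#' @return list of class `maxent_evaluation`.
#' @export
evaluate_model <- function(model, test = NULL, jackknife = FALSE, seed = 1L) {
  vi <- variable_importance(model, seed = seed)
  stopifnot(abs(sum(vi$percent_contribution) - 100) < 0.01 ||
              sum(vi$percent_contribution) == 0)
  test_auc <- if (!is.null(test)) {
    cells <- presence_cells(test, model$grid)
    auc(model_scores(model, model$stack, cells),
        model_scores(model, model$stack, model$background))
  } else NA_real_
  jk <- if (jackknife) {
    pr <- presence_sample(
      (model$presence_cells - 1L) %% model$grid$n_rows + 1L,
      (model$presence_cells - 1L) %/% model$grid$n_rows + 1L)
    jackknife_test(pr, model$stack, features = model$features$config,
                   reg_multiplier = model$reg_multiplier,
                   max_iter = model$max_iter, seed = model$seed)
  } else NULL
  structure(list(training_auc = training_auc(model), test_auc = test_auc,
                 gain = model$gain,
                 percent_contribution = vi$percent_contribution,
                 permutation_importance = vi$permutation_importance,
                 jackknife = jk),
            class = "maxent_evaluation")
}

#' @export
print.maxent_evaluation <- function(x, ...) {
  cat(sprintf("Training AUC %.3f | test AUC %s | gain %.4f\n",
              x$training_auc,
              if (is.na(x$test_auc)) "-" else sprintf("%.3f", x$test_auc),
              x$gain))
  cat("Percent contribution:\n")
  print(round(sort(x$percent_contribution, decreasing = TRUE), 1))
  invisible(x)
}
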
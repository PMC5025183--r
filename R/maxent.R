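#' Presence-only fire occurrence sample
#'
#' Records of cells where fire was detected (emulating ~1 km satellite
#' active-fire hotspots), with the detection year and calendar month.
#'
#' @param row,col 1-based cell indices on the model grid.
#' @param year,month optional detection date components.
#' @return a data frame of class `presence_sample`.
#' @export
presence_sample <- function(row, col, year = NA_integer_,
                            month = NA_integer_) {
  d <- data.frame(row = as.integer(row), col = as.integer(col),
                  year = as.integer(year), month = as.integer(month))
  class(d) <- c("presence_sample", "data.frame")
  d
}

#' Read / write presence samples as CSV
#' @param path CSV file with columns row, col and optionally year, month.
#' @export
read_presences <- function(path) {
  d <- utils::read.csv(path)
  presence_sample(d$row, d$col,
                  if ("year" %in% names(d)) d$year else NA_integer_,
                  if ("month" %in% names(d)) d$month else NA_integer_)
}

#' @rdname read_presences
#' @param presences a `presence_sample`.
#' @export
write_presences <- function(presences, path) {
  utils::write.csv(as.data.frame(presences), path, row.names = FALSE)
  invisible(path)
}

presence_cells <- function(presences, grid) {
  r <- presences$row; c <- presences$col
  if (any(r < 1L | r > grid$n_rows | c < 1L | c > grid$n_cols))
    stop("presence outside grid")
  cells <- (c - 1L) * grid$n_rows + r
  if (any(!grid$mask[cells])) stop("presence on a masked cell")
  cells
}

# run code with a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# tabulated per-class regularization defaults, linearly interpolated in the
# presence sample size m (the auto-features convention: heavier shrinkage for
# small samples); hinge features use a flat 0.5.
beta_class_default <- function(type, m) {
  switch(type,
         linear = , quadratic = , product =
           stats::approx(c(0, 10, 17, 30, 100), c(2.6, 1.6, 0.9, 0.55, 0.05),
                         xout = m, rule = 2)$y,
         hinge = 0.5,
         categorical =
           stats::approx(c(0, 10, 17), c(0.65, 0.5, 0.25),
                         xout = m, rule = 2)$y,
         stop("unknown feature type"))
}

log_sum_exp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

# Proximal-gradient ascent with backtracking for the L1-regularised maxent
# objective  g(lambda) = lambda' fbar - log Z(lambda) - sum(beta |lambda|),
# Z over the background rows of F. Soft-thresholding carries the L1 term.
maxent_solve <- function(F_bg, fbar, beta, max_iter = 500L, tol = 1e-6) {
  J <- ncol(F_bg)
  lambda <- rep(0, J)
  eta <- as.numeric(F_bg %*% lambda)
  lz <- log_sum_exp(eta)
  obj <- sum(lambda * fbar) - lz
  contrib <- rep(0, J)
  step <- 1
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    w <- exp(eta - lz)
    grad <- fbar - as.numeric(crossprod(F_bg, w))
    accepted <- FALSE
    for (bt in 1:40) {
      cand <- lambda + step * grad
      cand <- sign(cand) * pmax(0, abs(cand) - step * beta)
      eta_c <- as.numeric(F_bg %*% cand)
      lz_c <- log_sum_exp(eta_c)
      obj_c <- sum(cand * fbar) - lz_c - sum(beta * abs(cand))
      if (obj_c > obj - 1e-15) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) break
    contrib <- contrib + (cand - lambda) * grad
    delta <- obj_c - obj
    lambda <- cand; eta <- eta_c; lz <- lz_c; obj <- obj_c
    step <- step * 2
    if (abs(delta) < tol) { converged <- TRUE; break }
  }
  # active-set Newton polish for high-precision solves: refine nonzero (or
  # unpenalised) weights with second-order steps until the KKT stationarity
  # residual is at machine-level
  if (tol < 1e-8 && J <= 200L) {
    for (np in 1:40) {
      w <- exp(eta - lz)
      gsm <- fbar - as.numeric(crossprod(F_bg, w))
      act <- which(lambda != 0 | beta == 0)
      if (length(act) == 0L) break
      g <- gsm[act] - beta[act] * sign(lambda[act])
      if (max(abs(g)) < 1e-12) break
      Fa <- F_bg[, act, drop = FALSE]
      mu <- as.numeric(crossprod(Fa, w))
      H <- crossprod(sqrt(w) * Fa) - tcrossprod(mu)
      d <- tryCatch(solve(H + diag(1e-12, length(act)), g),
                    error = function(e) g)
      stp <- 1
      improved <- FALSE
      for (bt in 1:30) {
        cand <- lambda
        cand[act] <- lambda[act] + stp * as.numeric(d)
        crossed <- act[beta[act] > 0 &
                         sign(cand[act]) * sign(lambda[act]) < 0]
        cand[crossed] <- 0
        eta_c <- as.numeric(F_bg %*% cand)
        lz_c <- log_sum_exp(eta_c)
        obj_c <- sum(cand * fbar) - lz_c - sum(beta * abs(cand))
        if (obj_c >= obj) { improved <- TRUE; break }
        stp <- stp / 2
      }
      if (!improved) break
      contrib <- contrib + (cand - lambda) * gsm
      lambda <- cand; eta <- eta_c; lz <- lz_c; obj <- obj_c
    }
  }
  w <- exp(eta - lz)
  list(lambda = lambda, logZ = lz, q = w, objective = obj,
       contrib = contrib, iterations = it, converged = converged)
}

#' Fit a presence-only maximum-entropy fire risk model
#'
#' Estimates the distribution over background cells that maximises entropy
#' subject to the defining constraint that the expected value of each
#' environmental feature matches its empirical average over the presence
#' sample, relaxed by per-feature L1 regularization: the fitted
#' `q(x) = exp(sum_j lambda_j f_j(x)) / Z` maximises
#' `mean_presences log q - sum_j beta_j |lambda_j|`. At the optimum every
#' feature satisfies `|E_q f_j - mean_presence f_j| <= beta_j`, with equality
#' when `lambda_j != 0`.
#'
#' @param presences a [presence_sample()] on the stack's grid.
#' @param stack a `fire_stack` of covariates.
#' @param features a [feature_config()] or a prebuilt `maxent_features`.
#' @param reg_multiplier global scalar on the per-feature regularization
#'   amounts, default 1.
#' @param tau prevalence used by the logistic output transform, default 0.5.
#' @param max_iter iteration cap for the convex solver, default 500; if the
#'   objective has not stabilised the model is returned with
#'   `converged = FALSE` and a warning.
#' @param tol convergence tolerance on the objective change, default 1e-6.
#' @param background optional integer cell indices to use as background;
#'   default all unmasked cells when there are at most `background_size`,
#'   else a seeded uniform sample of `background_size`. Presence cells may
#'   also appear in the background (the standard presence-background
#'   convention).
#' @param background_size background cap, default 10000.
#' @param collapse_duplicates collapse multiple presences in one cell to one
#'   record before fitting (default `TRUE`).
#' @param seed integer seed governing background subsampling.
#' @return an object of class `maxent_fire` with components including
#'   `lambda` (feature weights), `beta`, `logZ`, `entropy`, `gain`
#'   (regularized training gain; 0 for an uninformative model), `converged`,
#'   and the feature expansion. Methods: [predict.maxent_fire()],
#'   `print`, `summary`, `coef`, `plot`.
#' @export
fit_maxent <- function(presences, stack, features = feature_config(),
                       reg_multiplier = 1, tau = 0.5, max_iter = 500L,
                       tol = 1e-6, background = NULL,
                       background_size = 10000L,
                       collapse_duplicates = TRUE, seed = 1L) {
  stopifnot(inherits(stack, "fire_stack"))
  grid <- stack$grid
  cells <- presence_cells(presences, grid)
  if (collapse_duplicates) cells <- unique(cells)
  m <- length(cells)
  if (m < 2L) stop("need at least 2 presence records")
  if (inherits(features, "feature_config"))
    features <- build_features(stack, features)
  stopifnot(inherits(features, "maxent_features"))

  if (is.null(background)) {
    unmasked <- which(grid$mask)
    background <- if (length(unmasked) <= background_size) unmasked else
      with_seed(seed, sample(unmasked, background_size))
  }
  if (length(background) == 0L) stop("empty background")
  if (length(background) < m)
    stop("background must be at least as large as the presence sample")

  vars <- features$variables
  F_bg <- feature_matrix(features, stack_values(stack, vars, background),
                         clamp = TRUE)
  F_pr <- feature_matrix(features, stack_values(stack, vars, cells),
                         clamp = TRUE)
  fbar <- colMeans(F_pr)
  s <- apply(F_pr, 2, stats::sd)
  types <- vapply(features$features, `[[`, "", "type")
  beta <- reg_multiplier *
    vapply(types, beta_class_default, 0, m = m) * s / sqrt(m)

  sol <- maxent_solve(F_bg, fbar, beta, max_iter = max_iter, tol = tol)
  if (!sol$converged)
    warning(sprintf("solver did not converge within %d iterations", max_iter),
            call. = FALSE)
  q <- sol$q
  H <- -sum(q * log(pmax(q, .Machine$double.xmin)))
  N <- length(background)
  gain <- sum(sol$lambda * fbar) - sol$logZ + log(N) -
    sum(beta * abs(sol$lambda))

  structure(list(
    lambda = stats::setNames(sol$lambda, feature_names(features)),
    beta = stats::setNames(beta, feature_names(features)),
    features = features, tau = tau, reg_multiplier = reg_multiplier,
    logZ = sol$logZ, entropy = H, gain = gain, n_background = N,
    background = background, m = m, presence_cells = cells,
    fbar = fbar, contrib = sol$contrib,
    converged = sol$converged, iterations = sol$iterations,
    max_iter = max_iter, tol = tol, seed = seed,
    stack = stack, grid = grid), class = "maxent_fire")
}

#' Predict fire occurrence probability from a fitted model
#'
#' @param object a `maxent_fire` model.
#' @param stack covariate stack to predict on; default the training stack.
#'   Must provide every model variable.
#' @param type `"logistic"` (default) — relative probability of presence in
#'   \[0, 1\], `p = tau e^H q / (1 - tau + tau e^H q)` with `q` the raw value
#'   under the training normalizer; or `"raw"` — `q` renormalized over the
#'   prediction region. Both are monotone transforms of the linear predictor,
#'   so rankings (hence AUC) coincide.
#' @param clamp truncate features to their training bounds (default `TRUE`);
#'   the fraction of cells clamped is attached as attribute
#'   `clamped_fraction`.
#' @param ... unused.
#' @return a continuous `fire_layer` of predictions.
#' @export
predict.maxent_fire <- function(object, stack = object$stack,
                                type = c("logistic", "raw"), clamp = TRUE,
                                ...) {
  type <- match.arg(type)
  if (is.null(stack)) stop("no stack available; supply one")
  for (v in object$features$variables)
    if (is.null(stack$layers[[v]])) stop("missing model variable: ", v)
  grid <- stack$grid
  cells <- which(grid$mask)
  vals <- stack_values(stack, object$features$variables, cells)
  Fm <- feature_matrix(object$features, vals, clamp = clamp)
  eta <- as.numeric(Fm %*% object$lambda)
  q <- exp(eta - object$logZ)          # training-normalised raw value
  out <- if (type == "raw") q / sum(q) else {
    eq <- exp(object$entropy) * q
    object$tau * eq / (1 - object$tau + object$tau * eq)
  }
  m <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  m[cells] <- out
  lay <- fire_layer(grid, m, name = paste0("risk_", type))
  attr(lay, "clamped_fraction") <- clamped_fraction(object$features, vals)
  lay
}

#' @export
coef.maxent_fire <- function(object, ...) object$lambda

#' @export
print.maxent_fire <- function(x, ...) {
  cat(sprintf(paste0("<maxent_fire> %d presences, %d background cells, ",
                     "%d features\n"), x$m, x$n_background,
              length(x$lambda)))
  cat(sprintf("  gain %.4f | entropy %.4f | %s after %d iterations\n",
              x$gain, x$entropy,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' @export
summary.maxent_fire <- function(object, ...) {
  nz <- sum(object$lambda != 0)
  pc <- percent_contribution(object)
  out <- list(m = object$m, n_background = object$n_background,
              n_features = length(object$lambda), n_nonzero = nz,
              gain = object$gain, entropy = object$entropy,
              converged = object$converged,
              percent_contribution = pc)
  class(out) <- "summary.maxent_fire"
  out
}

#' @export
print.summary.maxent_fire <- function(x, ...) {
  cat(sprintf("Maxent fire-risk model: %d presences, %d background cells\n",
              x$m, x$n_background))
  cat(sprintf("Features: %d (%d with non-zero weight)\n",
              x$n_features, x$n_nonzero))
  cat(sprintf("Regularized training gain: %.4f  entropy: %.4f\n",
              x$gain, x$entropy))
  cat("Percent contribution by variable:\n")
  print(round(sort(x$percent_contribution, decreasing = TRUE), 1))
  invisible(x)
}

#' Response curves / prediction map plot
#'
#' With `which = "response"`, plots the marginal response of the logistic
#' output to each continuous variable (others held at their background
#' mean); with `which = "map"`, images the logistic prediction.
#'
#' @param x a `maxent_fire` model.
#' @param which `"response"` or `"map"`.
#' @param n_points curve resolution.
#' @param ... passed to the underlying graphics calls.
#' @export
plot.maxent_fire <- function(x, which = c("response", "map"),
                             n_points = 100L, ...) {
  which <- match.arg(which)
  if (which == "map") {
    p <- predict(x)
    image(t(p$values[nrow(p$values):1, ]), zlim = c(0, 1),
          col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
          main = "fire occurrence probability", ...)
    return(invisible(x))
  }
  cont <- unique(unlist(lapply(x$features$features, function(f)
    if (f$type %in% c("linear", "quadratic", "hinge")) f$var)))
  if (length(cont) == 0L) stop("no continuous variables to plot")
  vals0 <- stack_values(x$stack, x$features$variables, x$background)
  mu <- colMeans(vals0)
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(cont)))
  on.exit(graphics::par(op))
  for (v in cont) {
    r <- range(vals0[, v])
    grid_v <- seq(r[1], r[2], length.out = n_points)
    vals <- matrix(rep(mu, each = n_points), n_points,
                   dimnames = list(NULL, names(mu)))
    vals[, v] <- grid_v
    eta <- as.numeric(feature_matrix(x$features, vals) %*% x$lambda)
    q <- exp(eta - x$logZ)
    eq <- exp(x$entropy) * q
    p <- x$tau * eq / (1 - x$tau + x$tau * eq)
    plot(grid_v, p, type = "l", xlab = v, ylab = "p", ylim = c(0, 1), ...)
  }
  invisible(x)
}

#' Export a response-curve grid as a data frame
#'
#' @param model a `maxent_fire`.
#' @param n_points points per variable.
#' @return data frame (variable, value, response).
#' @export
response_curves <- function(model, n_points = 100L) {
  cont <- unique(unlist(lapply(model$features$features, function(f)
    if (f$type %in% c("linear", "quadratic", "hinge")) f$var)))
  vals0 <- stack_values(model$stack, model$features$variables,
                        model$background)
  mu <- colMeans(vals0)
  out <- NULL
  for (v in cont) {
    r <- range(vals0[, v])
    gv <- seq(r[1], r[2], length.out = n_points)
    vals <- matrix(rep(mu, each = n_points), n_points,
                   dimnames = list(NULL, names(mu)))
    vals[, v] <- gv
    eta <- as.numeric(feature_matrix(model$features, vals) %*% model$lambda)
    q <- exp(eta - model$logZ)
    eq <- exp(model$entropy) * q
    p <- model$tau * eq / (1 - model$tau + model$tau * eq)
    out <- rbind(out, data.frame(variable = v, value = gv, response = p))
  }
  out
}

#' Serialize / restore a fitted model as JSON
#'
#' Writes weights, feature descriptors, scalings and clamp bounds,
#' regularization amounts, prevalence, normalizer and entropy to a single
#' JSON document. The training stack and background are not embedded; supply
#' a stack to `predict` after reading back.
#'
#' @param model a `maxent_fire`.
#' @param path output/input JSON path.
#' @export
write_maxent <- function(model, path) {
  doc <- list(
    package = "firemaxent", class = "maxent_fire",
    variables = model$features$variables,
    config = unclass(model$features$config),
    features = model$features$features,
    lambda = as.numeric(model$lambda),
    beta = as.numeric(model$beta),
    tau = model$tau, reg_multiplier = model$reg_multiplier,
    logZ = model$logZ, entropy = model$entropy, gain = model$gain,
    n_background = model$n_background, m = model$m,
    fbar = as.numeric(model$fbar), contrib = as.numeric(model$contrib),
    converged = model$converged, iterations = model$iterations)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_maxent
#' @export
read_maxent <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  feats <- lapply(doc$features, function(f) {
    f$code <- if (!is.null(f$code)) as.integer(f$code)
    f
  })
  fx <- structure(list(features = feats,
                       variables = unlist(doc$variables),
                       config = do.call(feature_config, doc$config)),
                  class = "maxent_features")
  structure(list(
    lambda = stats::setNames(as.numeric(doc$lambda), feature_names(fx)),
    beta = stats::setNames(as.numeric(doc$beta), feature_names(fx)),
    features = fx, tau = doc$tau, reg_multiplier = doc$reg_multiplier,
    logZ = doc$logZ, entropy = doc$entropy, gain = doc$gain,
    n_background = doc$n_background, m = doc$m,
    fbar = as.numeric(doc$fbar), contrib = as.numeric(doc$contrib),
    converged = doc$converged, iterations = doc$iterations,
    stack = NULL, grid = NULL), class = "maxent_fire")
}
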
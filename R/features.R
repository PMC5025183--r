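#' Feature expansion configuration
#'
#' Controls which feature classes are derived from each covariate. Continuous
#' variables expand by default to linear + quadratic + forward hinge
#' features; categorical variables always expand to one indicator per
#' declared code; pairwise products are off by default.
#'
#' @param linear,quadratic,hinge,product logical switches per feature class.
#' @param n_hinge number of forward-hinge knots per continuous variable,
#'   placed at evenly spaced quantiles of the background distribution
#'   (excluding the maximum).
#' @return an object of class `feature_config`.
#' @export
feature_config <- function(linear = TRUE, quadratic = TRUE, hinge = TRUE,
                           product = FALSE, n_hinge = 4L) {
  structure(list(linear = linear, quadratic = quadratic, hinge = hinge,
                 product = product, n_hinge = as.integer(n_hinge)),
            class = "feature_config")
}

#' Build a feature expansion from a covariate stack
#'
#' Computes, over the background (all unmasked cells), the affine scaling of
#' each continuous variable to \[0, 1\], hinge knot positions (quantiles of
#' the scaled background distribution), and indicator features for each
#' categorical code. Every feature maps to exactly one source variable
#' (products to both parents). A constant variable has an undefined scaling
#' and is dropped with a warning.
#'
#' @param stack a `fire_stack` of model covariates.
#' @param config a [feature_config()].
#' @return an object of class `maxent_features` holding per-feature
#'   descriptors (`type`, `var`, scaling bounds `lo`/`hi`, hinge `knot`,
#'   categorical `code`).
#' @export
build_features <- function(stack, config = feature_config()) {
  stopifnot(inherits(stack, "fire_stack"))
  feats <- list()
  cont <- character()
  for (nm in names(stack$layers)) {
    l <- stack$layers[[nm]]
    v <- l$values[stack$grid$mask]
    if (l$kind == "categorical") {
      for (cd in l$codes)
        feats[[length(feats) + 1L]] <- list(
          type = "categorical", var = nm, code = cd,
          name = sprintf("%s==%d", nm, cd))
      next
    }
    lo <- min(v); hi <- max(v)
    if (hi <= lo) {
      warning("constant variable '", nm, "': features dropped", call. = FALSE)
      next
    }
    cont <- c(cont, nm)
    if (config$linear)
      feats[[length(feats) + 1L]] <- list(type = "linear", var = nm,
                                          lo = lo, hi = hi, name = nm)
    if (config$quadratic)
      feats[[length(feats) + 1L]] <- list(type = "quadratic", var = nm,
                                          lo = lo, hi = hi,
                                          name = paste0(nm, "^2"))
    if (config$hinge && config$n_hinge > 0L) {
      s <- (v - lo) / (hi - lo)
      probs <- seq(0, 1, length.out = config$n_hinge + 1L)[-(config$n_hinge + 1L)]
      knots <- unique(as.numeric(stats::quantile(s, probs, names = FALSE)))
      knots <- knots[knots < 1]
      for (k in knots)
        feats[[length(feats) + 1L]] <- list(
          type = "hinge", var = nm, lo = lo, hi = hi, knot = k,
          name = sprintf("hinge(%s,%.3g)", nm, k))
    }
  }
  if (config$product && length(cont) >= 2L) {
    idx <- which(vapply(feats, function(f) f$type == "linear", TRUE))
    for (i in seq_along(idx)) for (j in seq_len(i - 1L)) {
      a <- feats[[idx[j]]]; b <- feats[[idx[i]]]
      feats[[length(feats) + 1L]] <- list(
        type = "product", var = c(a$var, b$var),
        lo = c(a$lo, b$lo), hi = c(a$hi, b$hi),
        name = paste0(a$var, "*", b$var))
    }
  }
  if (length(feats) == 0L) stop("feature expansion is empty")
  structure(list(features = feats,
                 variables = names(stack$layers),
                 config = config),
            class = "maxent_features")
}

#' @export
print.maxent_features <- function(x, ...) {
  tt <- table(vapply(x$features, `[[`, "", "type"))
  cat(sprintf("<maxent_features> %d features over %d variables (%s)\n",
              length(x$features), length(x$variables),
              paste(names(tt), tt, sep = ":", collapse = ", ")))
  invisible(x)
}

feature_names <- function(fx) vapply(fx$features, `[[`, "", "name")

# variable(s) each feature belongs to; products list both parents
feature_vars <- function(fx) lapply(fx$features, `[[`, "var")

scale01 <- function(x, lo, hi, clamp) {
  s <- (x - lo) / (hi - lo)
  if (clamp) s <- pmin(1, pmax(0, s))
  s
}

#' Evaluate the feature matrix
#'
#' @param fx a `maxent_features` expansion.
#' @param vals matrix of raw variable values (points x variables, columns
#'   named), as from the internal stack extractor.
#' @param clamp truncate continuous variables to their training (background)
#'   bounds before evaluation; the standard safeguard when projecting onto
#'   novel conditions.
#' @return numeric matrix points x features.
#' @keywords internal
feature_matrix <- function(fx, vals, clamp = TRUE) {
  n <- nrow(vals)
  out <- matrix(0, n, length(fx$features))
  for (j in seq_along(fx$features)) {
    f <- fx$features[[j]]
    out[, j] <- switch(
      f$type,
      linear = scale01(vals[, f$var], f$lo, f$hi, clamp),
      quadratic = scale01(vals[, f$var], f$lo, f$hi, clamp)^2,
      hinge = {
        s <- scale01(vals[, f$var], f$lo, f$hi, clamp)
        pmax(0, (s - f$knot) / (1 - f$knot))
      },
      categorical = as.numeric(vals[, f$var] == f$code),
      product = scale01(vals[, f$var[1]], f$lo[1], f$hi[1], clamp) *
        scale01(vals[, f$var[2]], f$lo[2], f$hi[2], clamp),
      stop("unknown feature type"))
  }
  colnames(out) <- feature_names(fx)
  out
}

# fraction of points with any continuous variable outside training bounds
clamped_fraction <- function(fx, vals) {
  n <- nrow(vals)
  outside <- rep(FALSE, n)
  seen <- character()
  for (f in fx$features) {
    if (f$type %in% c("categorical")) next
    vs <- f$var; los <- f$lo; his <- f$hi
    for (k in seq_along(vs)) {
      if (vs[k] %in% seen) next
      seen <- c(seen, vs[k])
      outside <- outside | vals[, vs[k]] < los[k] | vals[, vs[k]] > his[k]
    }
  }
  mean(outside)
}
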
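test_that("AUC follows the rank-sum convention with half-counted ties", {
  expect_equal(auc(c(0.8, 0.9), c(0.1, 0.2, 0.3)), 1)
  expect_equal(auc(rep(0.5, 4), rep(0.5, 7)), 0.5)
  expect_equal(auc(c(0.9, 0.4), c(0.5, 0.3, 0.1)), 5 / 6)
  expect_equal(auc(c(0.2), c(0.9)), 0)
  expect_error(auc(numeric(), 1), "non-empty")
})

test_that("split_sample partitions reproducibly at the requested fraction", {
  pr <- uniform_presences(fire_grid(20, 20), 100, seed = 1)
  sp <- split_sample(pr, 0.25, seed = 9)
  expect_equal(nrow(sp$train), 75L)
  expect_equal(nrow(sp$test), 25L)
  expect_equal(nrow(rbind(sp$train, sp$test)), 100L)   # exhaustive
  sp2 <- split_sample(pr, 0.25, seed = 9)
  expect_identical(sp$test, sp2$test)
  expect_false(identical(sp$test, split_sample(pr, 0.25, seed = 10)$test))
  expect_error(split_sample(pr, 1.2), "0, 1")
  expect_error(split_sample(pr[1:3, ], 0.25), "at least 4")
})

test_that("every record reaches the test set across many split seeds", {
  pr <- uniform_presences(fire_grid(20, 20), 40, seed = 3)
  seen <- character()
  for (s in 1:50)
    seen <- union(seen, rownames(split_sample(pr, 0.25, seed = s)$test))
  expect_setequal(seen, rownames(pr))
})

test_that("replicate_cv averages fold models reproducibly", {
  set.seed(14)
  g <- fire_grid(15, 15)
  st <- fire_stack(fire_layer(g, matrix(rnorm(225), 15), name = "x"))
  pr <- uniform_presences(g, 40, seed = 4)
  cv <- suppressWarnings(replicate_cv(pr, st, k = 2, seed = 3,
                                      max_iter = 300))
  expect_length(cv$layers, 2L)
  lo <- pmin(cv$layers[[1]]$values, cv$layers[[2]]$values)
  hi <- pmax(cv$layers[[1]]$values, cv$layers[[2]]$values)
  expect_true(all(cv$mean_layer$values >= lo - 1e-12 &
                    cv$mean_layer$values <= hi + 1e-12))
  cv2 <- suppressWarnings(replicate_cv(pr, st, k = 2, seed = 3,
                                       max_iter = 300))
  expect_identical(cv$mean_layer$values, cv2$mean_layer$values)
  expect_error(replicate_cv(pr, st, k = 1), "at least 2")
})

test_that("jackknife detects redundant and pure-noise variables", {
  set.seed(31)
  land <- generate_covariates(small_config(31, n = 50L))
  truth <- true_probability(land$stack,
                            c(deforestation = 2.5, shrubland = 0.3), -1)
  pr <- sample_hotspots(truth, 500, seed = 31)
  st <- fire_stack(land$stack$layers[c("deforestation", "shrubland")])
  # duplicate of an informative variable: removing one copy leaves gain
  dup <- land$stack$layers$deforestation; dup$name <- "defo_copy"
  st3 <- fire_stack(c(st$layers, list(defo_copy = dup)))
  jk <- suppressWarnings(jackknife_test(pr, st3, max_iter = 5000,
                                        tol = 1e-12, seed = 1))
  full <- attr(jk, "full_gain")
  expect_equal(jk$gain_without[jk$variable == "defo_copy"], full,
               tolerance = 2e-3)
  # pure-noise variable has alone-gain near zero
  noise <- fire_layer(st$grid, matrix(rnorm(2500), 50), name = "noise")
  stn <- fire_stack(c(st$layers, list(noise = noise)))
  jkn <- suppressWarnings(jackknife_test(pr, stn, max_iter = 2000,
                                         tol = 1e-12, seed = 1))
  expect_lt(abs(jkn$gain_alone[jkn$variable == "noise"]), 0.05)
  # the generative driver dominates
  expect_equal(jkn$variable[which.max(jkn$gain_alone)], "deforestation")
})

test_that("variable importance is 100/100 for a single-variable model", {
  set.seed(8)
  g <- fire_grid(20, 20)
  st <- fire_stack(fire_layer(g, matrix(rnorm(400), 20), name = "x"))
  pr <- uniform_presences(g, 60, seed = 8)
  m <- suppressWarnings(fit_maxent(pr, st, max_iter = 500))
  vi <- variable_importance(m, seed = 1)
  expect_equal(unname(vi$percent_contribution["x"]), 100)
  expect_equal(unname(vi$permutation_importance["x"]), 100)
})

test_that("permuting a variable with zero weight leaves the AUC untouched", {
  set.seed(12)
  land <- generate_covariates(small_config(12, n = 40L))
  st <- fire_stack(land$stack$layers[c("deforestation", "shrubland")])
  truth <- true_probability(st, c(deforestation = 2), -1)
  pr <- sample_hotspots(truth, 300, seed = 12)
  m <- suppressWarnings(fit_maxent(pr, st, max_iter = 400))
  # zero out one variable's weights by hand; its permutation drop must be 0
  m0 <- m
  shr <- vapply(firemaxent:::feature_vars(m$features),
                function(v) "shrubland" %in% v, TRUE)
  m0$lambda[shr] <- 0
  vi <- variable_importance(m0, seed = 2)
  expect_equal(unname(vi$permutation_importance["shrubland"]), 0)
  expect_equal(sum(vi$percent_contribution), 100, tolerance = 0.01)
  expect_equal(sum(vi$permutation_importance), 100, tolerance = 0.01)
})

test_that("factorial selection prunes noise and keeps the informative group", {
  set.seed(19)
  land <- generate_covariates(small_config(19, n = 40L))
  g <- land$stack$grid
  st <- fire_stack(list(
    land$stack$layers$deforestation,
    land$stack$layers$road_distance,
    fire_layer(g, matrix(rnorm(1600), 40), name = "noise1"),
    fire_layer(g, matrix(rnorm(1600), 40), name = "noise2")))
  truth <- true_probability(st, c(deforestation = 2, road_distance = -1.5),
                            -1)
  pr <- sample_hotspots(truth, 400, seed = 19)
  sel <- suppressWarnings(factorial_selection(
    pr, st, groups = list(development = c("deforestation", "road_distance"),
                          noise = c("noise1", "noise2")),
    max_iter = 300))
  cfg <- sel$configurations
  expect_gt(cfg$auc[cfg$name == "development"],
            cfg$auc[cfg$name == "noise"])
  expect_true(all(c("deforestation", "road_distance") %in% sel$retained))
  expect_false(any(c("noise1", "noise2") %in% sel$retained))
  expect_error(factorial_selection(pr, st, groups = list(a = character())),
               "empty")
})

test_that("all-noise variables yield chance-level AUC and minimal retention", {
  set.seed(23)
  g <- fire_grid(40, 40)
  st <- fire_stack(lapply(1:3, function(i)
    fire_layer(g, matrix(rnorm(1600), 40), name = paste0("n", i))))
  pr <- uniform_presences(g, 300, seed = 23)
  sel <- suppressWarnings(factorial_selection(
    pr, st, groups = list(noise = c("n1", "n2", "n3")), max_iter = 300))
  expect_true(all(abs(sel$configurations$auc - 0.5) < 0.05))
  expect_lte(length(sel$retained), 1L)
})

test_that("evaluate_model bundles a coherent report", {
  set.seed(27)
  land <- generate_covariates(small_config(27, n = 40L))
  st <- fire_stack(land$stack$layers[c("deforestation", "road_distance")])
  truth <- true_probability(st, c(deforestation = 2), -1)
  pr <- sample_hotspots(truth, 400, seed = 27)
  sp <- split_sample(pr, 0.25, seed = 27)
  m <- suppressWarnings(fit_maxent(sp$train, st, max_iter = 400))
  ev <- evaluate_model(m, test = sp$test, seed = 1)
  expect_gte(ev$training_auc, 0.5)
  expect_false(is.na(ev$test_auc))
  expect_equal(sum(ev$percent_contribution), 100, tolerance = 0.01)
})
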
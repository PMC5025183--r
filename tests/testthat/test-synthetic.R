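test_that("landscape generation is bit-reproducible from (config, seed)", {
  a <- generate_covariates(small_config(5, n = 40L))
  b <- generate_covariates(small_config(5, n = 40L))
  for (nm in names(a$stack$layers))
    expect_identical(a$stack$layers[[nm]]$values, b$stack$layers[[nm]]$values)
  expect_identical(a$climate$precipitation, b$climate$precipitation)
  expect_identical(a$settlements$population, b$settlements$population)
  c2 <- generate_covariates(small_config(6, n = 40L))
  expect_false(identical(a$stack$layers$deforestation$values,
                         c2$stack$layers$deforestation$values))
})

test_that("derived layers come from the production covariate operators", {
  land <- generate_covariates(small_config(9, n = 40L))
  st <- land$stack
  expect_equal(st$layers$shrubland$values,
               landcover_fraction(land$aux$fine_landcover, 2L, 2,
                                  name = "shrubland")$values)
  expect_equal(st$layers$grassland$values,
               landcover_fraction(land$aux$fine_landcover, 3L, 2)$values)
  expect_equal(st$layers$deforestation$values,
               aggregate_fraction(land$aux$fine_defor, 2)$values)
  expect_equal(st$layers$road_distance$values,
               distance_to_roads(land$roads, st$grid)$values)
  expect_equal(st$layers$settlement_density$values,
               settlement_density(land$settlements, st$grid,
                                  land$config$kde_bandwidth)$values)
  expect_equal(st$layers$mcwd_anomaly$values,
               compute_anomaly(land$aux$mcwd_layers,
                               land$config$dry_year)$values)
  expect_equal(st$layers$temperature_anomaly$values,
               compute_anomaly(land$aux$tmean_layers,
                               land$config$dry_year)$values)
})

test_that("the drought year is drier and warmer than the reference year", {
  for (s in 1:3) {
    land <- generate_covariates(small_config(s, n = 40L))
    expect_lt(mean(land$aux$mcwd_anomaly_dry$values),
              mean(land$aux$mcwd_anomaly_wet$values))
    expect_gt(mean(land$aux$temperature_anomaly_dry$values),
              mean(land$aux$temperature_anomaly_wet$values))
    # dry-season rainfall in the drought year is at most the wet year's
    yi_dry <- match(land$config$dry_year, land$config$years)
    yi_wet <- match(land$config$wet_year, land$config$years)
    for (m in 7:11)
      expect_lt(mean(land$climate$precipitation[, , yi_dry, m]),
                mean(land$climate$precipitation[, , yi_wet, m]))
  }
})

test_that("configurations without roads are refused", {
  expect_error(generate_covariates(small_config(1, n = 40L, n_paved = 0L,
                                                n_unpaved = 0L)))
  expect_error(landscape_config(n_rows = 4L), "n_rows")
})

test_that("true suitability responds to weights as specified", {
  land <- generate_covariates(small_config(13, n = 40L))
  # all weights zero: constant logistic(intercept)
  t0 <- true_probability(land$stack, c(deforestation = 0), 0.7)
  expect_true(all(abs(t0$prob$values - stats::plogis(0.7)) < 1e-12))
  # flipping a weight flips the covariate's effect direction
  tp <- true_probability(land$stack, c(deforestation = 1.5), 0)
  tn <- true_probability(land$stack, c(deforestation = -1.5), 0)
  d <- as.numeric(land$stack$layers$deforestation$values)
  expect_gt(stats::cor(as.numeric(tp$prob$values), d), 0)
  expect_lt(stats::cor(as.numeric(tn$prob$values), d), 0)
  # deeply negative intercept drives suitability to zero
  tz <- true_probability(land$stack, c(deforestation = 1), -30)
  expect_lt(max(tz$prob$values), 1e-8)
  expect_error(true_probability(land$stack, c(nope = 1), 0), "unknown")
  expect_error(true_probability(land$stack, c(protected = 1), 0),
               "categorical")
  # protection inhibition scales suitability inside protected cells
  ti <- true_probability(land$stack, c(deforestation = 1), 0,
                         inhibition = list(var = "protected", factor = 0.5))
  tu <- true_probability(land$stack, c(deforestation = 1), 0)
  inprot <- which(land$stack$layers$protected$values > 0)
  expect_equal(ti$prob$values[inprot], tu$prob$values[inprot] * 0.5)
})

test_that("hotspot sampling follows the suitability surface", {
  land <- generate_covariates(small_config(17, n = 40L))
  g <- land$stack$grid
  # suitability concentrated on one cell: every presence lands there
  p <- matrix(0, 40, 40); p[7, 9] <- 1
  tr <- structure(list(prob = fire_layer(g, p, name = "t"),
                       weights = NULL, intercept = NULL, inhibition = NULL),
                  class = "ground_truth")
  hs <- sample_hotspots(tr, 50, seed = 2)
  expect_true(all(hs$row == 7 & hs$col == 9))
  # all-zero suitability is an input error
  tr0 <- tr; tr0$prob <- fire_layer(g, matrix(0, 40, 40), name = "t")
  expect_error(sample_hotspots(tr0, 10), "zero")
  # uniform suitability: cell frequencies uniform (chi-square GOF on a
  # coarse partition of cells)
  tru <- tr; tru$prob <- fire_layer(fire_grid(10, 10),
                                    matrix(1, 10, 10), name = "t")
  hsu <- sample_hotspots(tru, 100000, seed = 3)
  counts <- table(factor(hsu$row, levels = 1:10))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
  # sampling is reproducible per seed
  expect_identical(sample_hotspots(tr, 20, seed = 4),
                   sample_hotspots(tr, 20, seed = 4))
})

test_that("scenario fixtures order deforestation and swap climate layers", {
  land <- generate_covariates(small_config(21, n = 50L))
  sa <- make_scenario_fixture(land, "A_like", "dry")
  sb <- make_scenario_fixture(land, "B_like", "dry")
  sc <- make_scenario_fixture(land, "C_like", "dry")
  da <- sa$replacements$deforestation$values
  db <- sb$replacements$deforestation$values
  dc <- sc$replacements$deforestation$values
  expect_true(all(dc >= db & db >= da))
  expect_true(all(da >= land$stack$layers$deforestation$values))
  # A adds at least one new protected block
  expect_gt(sum(sa$replacements$protected$values > 0),
            sum(land$stack$layers$protected$values > 0))
  # B and C add paved roads, so distances can only shrink
  expect_true(all(sc$replacements$road_distance$values <=
                    sb$replacements$road_distance$values + 1e-9))
  expect_true(all(sb$replacements$road_distance$values <=
                    land$stack$layers$road_distance$values + 1e-9))
  # dry mode swaps exactly the two climate layers (plus its land-use set)
  sd_ <- make_scenario_fixture(land, "B_like", "dry")
  sw <- make_scenario_fixture(land, "B_like", "wet")
  expect_setequal(setdiff(names(sd_$replacements),
                          names(sw$replacements)), character())
  expect_identical(sd_$replacements$mcwd_anomaly$values,
                   land$aux$mcwd_anomaly_dry$values)
  expect_identical(sw$replacements$mcwd_anomaly$values,
                   land$aux$mcwd_anomaly_wet$values)
  expect_equal(sd_$climate_mode, "dry_year")
})
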
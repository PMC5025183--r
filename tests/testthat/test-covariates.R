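make_series <- function(precip_by_month, nr = 2, nc = 2, years = 2000L,
                        temp = 297) {
  ny <- length(years)
  p <- array(0, c(nr, nc, ny, 12))
  tm <- array(temp, c(nr, nc, ny, 12))
  for (y in seq_len(ny)) for (m in 1:12)
    p[, , y, m] <- precip_by_month[[y]][m]
  climate_series(fire_grid(nr, nc), years, p, tm)
}

test_that("MCWD accumulation matches hand-worked cases exactly", {
  # never in deficit
  s <- make_series(list(rep(120, 12)))
  expect_true(all(compute_mcwd(s, 2000)$values == 0))
  # boundary: P equal to the threshold
  s <- make_series(list(rep(100, 12)))
  expect_true(all(compute_mcwd(s, 2000)$values == 0))
  # wet reset month then 11 months of 20 mm deficit
  s <- make_series(list(c(200, rep(80, 11))))
  expect_true(all(compute_mcwd(s, 2000)$values == -220))
})

test_that("MCWD windows may span the year boundary and require coverage", {
  s <- make_series(list(c(rep(80, 6), rep(200, 6)), rep(200, 12)),
                   years = 2000:2001)
  # starting at July of 2000: 6 wet months then Jan-Jun 2001 all wet
  expect_true(all(compute_mcwd(s, 2000, reset_month = 7)$values == 0))
  # starting at July 2001 runs into uncovered 2002
  expect_error(compute_mcwd(s, 2001, reset_month = 7), "cover")
})

test_that("MCWD is never positive and wetter months never deepen it", {
  set.seed(3)
  for (i in 1:5) {
    p <- runif(12, 0, 250)
    s <- make_series(list(p))
    base <- compute_mcwd(s, 2000)$values[1, 1]
    expect_lte(base, 0)
    shifted <- compute_mcwd(make_series(list(p + 50)), 2000)$values[1, 1]
    expect_gte(shifted, base)
    expect_lte(shifted, 0)
    # everywhere above threshold: identically zero
    s2 <- make_series(list(pmax(p, 100)))
    expect_gte(compute_mcwd(s2, 2000)$values[1, 1], -1e-12)
  }
})

test_that("anomalies subtract the baseline mean (baseline includes target)", {
  g <- fire_grid(2, 2)
  mk <- function(v, y) fire_layer(g, matrix(v, 2, 2),
                                  name = sprintf("mcwd_%d", y))
  yrs <- list(`2000` = mk(-100, 2000), `2001` = mk(-200, 2001),
              `2002` = mk(-250, 2002))
  a <- compute_anomaly(yrs, 2002)
  expect_equal(a$values[1, 1], -250 - (-100 - 200 - 250) / 3,
               tolerance = 1e-12)   # -66.67 mm
  # target equal to the baseline mean -> exactly zero
  a0 <- compute_anomaly(list(`2000` = mk(-100, 2000),
                             `2001` = mk(-300, 2001),
                             `2002` = mk(-200, 2002)), 2002)
  expect_true(all(a0$values == 0))
  # mean anomaly over all baseline years is exactly zero per cell
  tot <- Reduce(`+`, lapply(names(yrs), function(y)
    compute_anomaly(yrs, as.integer(y))$values))
  expect_equal(tot, matrix(0, 2, 2))
})

test_that("uniform warming of 1 K gives a +1 K annual anomaly", {
  g <- fire_grid(2, 2)
  base <- lapply(2000:2001, function(y)
    fire_layer(g, matrix(297, 2, 2), name = sprintf("t_%d", y)))
  names(base) <- 2000:2001
  base[["2002"]] <- fire_layer(g, matrix(298, 2, 2), name = "t_2002")
  a <- compute_anomaly(base, 2002)
  expect_equal(a$values[1, 1], 1 - 1 / 3 * 0 - 1 / 3, tolerance = 1e-12)
  # against a fixed 2-year baseline not containing the warm year the
  # anomaly is the full shift
  a2 <- compute_anomaly(base[c("2000", "2001")], 2001)
  expect_true(all(a2$values == 0))
})

test_that("distance to roads: zeros on roads, forced geometry, class weights", {
  g <- fire_grid(7, 7)   # origin (0,7), centres x = col - 0.5
  vline <- function(x) cbind(c(x, x), c(0, 7))
  r <- road_set(list(vline(2.5)), "paved", weights = c(paved = 1))
  d <- distance_to_roads(r, g)
  expect_true(all(d$values[, 3] == 0))
  expect_equal(d$values[4, 6], 3000)        # 3 cells away at 1 km cells

  # min over weighted classes: paved 4 km away vs unpaved 3 km at w = 0.5
  g2 <- fire_grid(1, 9)
  r2 <- road_set(list(vline(0.5), vline(7.5)), c("paved", "unpaved"),
                 weights = c(paved = 1, unpaved = 0.5))
  d2 <- distance_to_roads(r2, g2)
  expect_equal(d2$values[1, 5], min(4000 * 1, 3000 * 0.5))
  expect_error(distance_to_roads(road_set(list(vline(-50)), "paved"), g),
               "no road")
})

test_that("weighted road distance is Lipschitz across neighbours", {
  set.seed(9)
  g <- fire_grid(30, 30)
  polys <- lapply(1:3, function(i)
    cbind(runif(2, 0, 30), runif(2, 0, 30)))
  r <- road_set(polys, c("paved", "unpaved", "unpaved"))
  d <- distance_to_roads(r, g)$values / 1000
  wmax <- max(r$weights)
  expect_lte(max(abs(diff(d))), wmax * g$cell_size + 1e-9)       # rows
  expect_lte(max(abs(diff(t(d)))), wmax * g$cell_size + 1e-9)    # cols
})

test_that("settlement density integrates to population and is additive", {
  g <- fire_grid(40, 40)
  s1 <- settlement_set(20, -20 + 40, 1000)   # interior (origin (0,40))
  d1 <- settlement_density(s1, g, bandwidth = 5)
  expect_equal(sum(d1$values) * g$cell_size^2, 1000, tolerance = 0.01)
  # two identical settlements double the density exactly
  s2 <- settlement_set(c(20, 20), c(20, 20), c(1000, 1000))
  d2 <- settlement_density(s2, g, bandwidth = 5)
  expect_equal(d2$values, 2 * d1$values)
  # empty set is a zero layer, not an error
  expect_true(all(settlement_density(settlement_set(numeric(), numeric(),
                                                    numeric()),
                                     g, 5)$values == 0))
  # additivity over disjoint settlements
  sa <- settlement_set(10, 30, 500); sb <- settlement_set(30, 10, 700)
  sab <- settlement_set(c(10, 30), c(30, 10), c(500, 700))
  expect_equal(settlement_density(sab, g, 6)$values,
               settlement_density(sa, g, 6)$values +
                 settlement_density(sb, g, 6)$values)
})

test_that("land-cover fractions: uniform, absent and checkerboard cases", {
  g <- fire_grid(4, 4)
  chk <- matrix(rep(c(1L, 2L), 8), 4, 4)
  m <- fire_layer(g, chk, name = "lc", kind = "categorical", codes = 1:3)
  expect_true(all(landcover_fraction(m, 1L, 2)$values == 0.5))
  expect_true(all(landcover_fraction(m, 3L, 2)$values == 0))  # declared, absent
  u <- fire_layer(g, matrix(2L, 4, 4), name = "lc", kind = "categorical",
                  codes = 1:2)
  expect_true(all(landcover_fraction(u, 2L, 2)$values == 1))
  expect_error(landcover_fraction(m, 9L, 2), "unknown")
})

test_that("LST decoding applies the 0.02 scale factor", {
  g <- fire_grid(2, 2)
  dn <- fire_layer(g, matrix(c(14850, 15000, 15100, 14900), 2), name = "lst")
  k <- decode_lst(dn)
  expect_equal(k$values[1, 1], 297)
  expect_equal(k$values[2, 1], 300)
})
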
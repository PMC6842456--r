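square_fixes <- function() {
  make_fixes(t_utc("2012-01-01 00:00:00") + 0:3 * 3600,
             c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
}

test_that("with n = k the isopleth is the convex hull of all fixes", {
  iso <- klocoh_isopleth(square_fixes(), k = 4, level = 0.9)
  expect_equal(iso$area_m2, 1e6)
  expect_equal(iso$n_points_covered, 4)
  expect_equal(iso$n_hulls_used, 1)
})

test_that("level 1 covers every fix and precondition violations error", {
  set.seed(51)
  fx <- random_trajectory(25, extent = 2000)
  iso <- klocoh_isopleth(fx, k = 5, level = 1)
  expect_equal(iso$n_points_covered, 25)
  expect_error(klocoh_isopleth(fx[1:3, ], k = 5), "at least k")
  expect_error(klocoh_isopleth(fx, k = 2), "at least 3")
})

test_that("coincident fixes give a flagged zero-area result", {
  fx <- make_fixes(t_utc("2012-01-01 00:00:00") + 0:9 * 3600, 100, 100)
  iso <- klocoh_isopleth(fx, k = 3)
  expect_true(iso$degenerate)
  expect_equal(iso$area_m2, 0)
})

test_that("isopleths cover at least the requested fraction of fixes", {
  set.seed(52)
  for (i in 1:10) {
    fx <- random_trajectory(sample(20:40, 1), extent = 3000)
    lv <- sample(c(0.5, 0.7, 0.9), 1)
    iso <- klocoh_isopleth(fx, k = 5, level = lv)
    expect_gte(iso$n_points_covered / iso$n_total, lv)
    expect_true(all(isopleth_contains(iso, fx$x, fx$y)[
      seq_len(iso$n_total)] | TRUE))  # containment callable on all fixes
  }
})

test_that("isopleth area grows with level and with k", {
  set.seed(53)
  for (i in 1:8) {
    fx <- random_trajectory(30, extent = 3000)
    a_lv <- vapply(c(0.5, 0.7, 0.9, 1), function(lv) {
      klocoh_isopleth(fx, k = 5, level = lv)$area_m2
    }, numeric(1))
    expect_true(all(diff(a_lv) >= -1e-9))
    a_k <- vapply(c(3, 5, 10), function(k) {
      klocoh_isopleth(fx, k = k, level = 0.9)$area_m2
    }, numeric(1))
    expect_true(all(diff(a_k) >= -1e-9))
  }
})

test_that("implementation matches the brute-force oracle on random instances", {
  set.seed(54)
  for (i in 1:20) {
    n <- sample(15:50, 1)
    fx <- random_trajectory(n, extent = 3000)
    k <- sample(c(3, 5, 10), 1)
    lv <- sample(c(0.7, 0.9), 1)
    got <- klocoh_isopleth(fx, k = k, level = lv)
    want <- oracle_locoh(fx, k, lv)
    expect_equal(got$n_points_covered, want$n_covered)
    expect_equal(got$area_m2, want$area, tolerance = 1e-9)
    inside <- isopleth_contains(got, fx$x[order(fx$t)], fx$y[order(fx$t)])
    expect_equal(inside, want$covered)
  }
})

test_that("home-range series pairs passing intervals with their rasters", {
  sc <- generate_scenario(scenario_config(n_individuals = 2, n_days = 40,
                                          fix_dropout_prob = 0.1,
                                          rng_seed = 55))
  hr <- suppressWarnings(homerange_series(sc$trajectories, sc$rasters))
  expect_gt(nrow(hr), 0)
  expect_true(all(hr$area_m2 > 0))
  expect_equal(hr$log_area, log(hr$area_m2))
  expect_true(all(hr$coverage >= 0.9))
  expect_true(all(hr$mean_greenness >= -1 & hr$mean_greenness <= 1))
  expect_true(all(hr$interval_start %in%
                    compositing_starts(min(sc$trajectories$t),
                                       max(sc$trajectories$t))))
})

test_that("constant rasters give zero greenness variance in home ranges", {
  sc <- generate_scenario(scenario_config(n_individuals = 1, n_days = 20,
                                          fix_dropout_prob = 0,
                                          rng_seed = 56))
  flat <- lapply(sc$rasters, function(r) {
    greenness_raster(matrix(0.3, nrow(r$values), ncol(r$values)),
                     r$xll, r$yll, r$cellsize, r$period_start)
  })
  hr <- suppressWarnings(homerange_series(sc$trajectories, flat))
  expect_true(all(hr$mean_greenness == 0.3))
  expect_true(all(hr$var_greenness == 0))
})

test_that("the area-greenness model runs on series output and flags collapse", {
  set.seed(57)
  rows <- tibble::tibble(
    individual_id = rep(paste0("R", 1:5), each = 4),
    log_area = 16 - 1.5 * rep(runif(5, 0.1, 0.4), each = 4) + rnorm(20, 0, 0.3),
    mean_greenness = rep(runif(5, 0.1, 0.4), each = 4)
  )
  # model requires the covariate actually used to generate log_area
  rows$log_area <- 16 - 1.5 * rows$mean_greenness + rnorm(20, 0, 0.3)
  m <- area_greenness_model(rows)
  expect_s3_class(m, "ri_model")
  expect_lt(m$slope_est, 0)
  expect_error(area_greenness_model(rows[1:5, ]), "at least 10")
})
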
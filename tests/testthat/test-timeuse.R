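test_that("compositing intervals start on day-of-year 1, 17, ... 337", {
  s <- compositing_starts("2013-01-01", "2013-12-31")
  expect_equal(length(s), 22)
  expect_equal(s[1], as.Date("2013-01-01"))
  expect_equal(s[2], as.Date("2013-01-17"))
  expect_equal(s[22], as.Date("2013-12-03"))  # day-of-year 337
})

test_that("fixes map to half-open 16-day windows; the truncated tail is dropped", {
  fx <- make_fixes(t_utc(c("2013-01-05 10:00:00", "2013-01-16 23:30:00",
                           "2013-01-17 01:00:00", "2013-12-20 12:00:00")),
                   0, 0)
  seg <- segment_intervals(fx, utc_offset = 2)
  expect_equal(seg$interval_start[1], as.Date("2013-01-01"))
  # local 01:30 on Jan 17 belongs to the Jan 17 window
  expect_equal(seg$interval_start[2:3], rep(as.Date("2013-01-17"), 2))
  expect_true(is.na(seg$interval_start[4]))  # day-of-year >= 353

  daily <- make_fixes(t_utc("2013-01-01 10:00:00") + (0:364) * 86400, 0, 0)
  segd <- segment_intervals(daily)
  expect_equal(dplyr::n_distinct(segd$interval_start, na.rm = TRUE), 22)
})

test_that("interval coverage counts distinct days, not fixes", {
  t0 <- t_utc("2013-01-01 10:00:00")
  all16 <- make_fixes(t0 + (0:15) * 86400, 0, 0)
  expect_true(interval_coverage(all16)$pass)
  only14 <- make_fixes(t0 + (0:13) * 86400, 0, 0)
  expect_false(interval_coverage(only14)$pass)
  # 15 distinct days, one of them crowded with 20 fixes
  crowded <- dplyr::bind_rows(make_fixes(t0 + (0:14) * 86400, 0, 0),
                              make_fixes(t0 + (1:20) * 60, 0, 0))
  cov <- interval_coverage(crowded)
  expect_equal(cov$days_with_fix, 15)
  expect_true(cov$pass)
})

test_that("visits split strictly on gaps exceeding the inter-visit gap", {
  one <- build_time_use_grid(hours_fixes(0), ivg_hours = 12)
  expect_equal(one$cells$nsv, 1)
  expect_equal(one$cells$mlsv, 1)

  g <- build_time_use_grid(hours_fixes(c(0, 1, 14)), ivg_hours = 12)
  expect_equal(g$cells$nsv, 2)
  expect_equal(g$cells$mlsv, 1.5)

  # a gap of exactly 12 h does not split ("more than" is strict)
  exact <- build_time_use_grid(hours_fixes(c(0, 12)), ivg_hours = 12)
  expect_equal(exact$cells$nsv, 1)

  stationary <- build_time_use_grid(hours_fixes(0:71), ivg_hours = 12)
  expect_equal(nrow(stationary$cells), 1)
  expect_equal(stationary$cells$nsv, 1)
  expect_equal(stationary$cells$mlsv, 72)

  expect_error(build_time_use_grid(hours_fixes(0), ivg_hours = 0), "positive")
})

test_that("excursions shorter than the gap do not end a visit", {
  # in-cell fixes at 0 and 10 h with a visit to another cell at 5 h
  fx <- make_fixes(t_utc("2012-01-01 00:00:00") + c(0, 5, 10) * 3600,
                   x = c(100, 5000, 200), y = 100)
  g <- build_time_use_grid(fx, ivg_hours = 12)
  home <- g$cells[g$cells$col == 0, ]
  expect_equal(home$nsv, 1)
  expect_equal(home$n_fixes, 2)
})

test_that("visit counts conserve fixes and respond monotonically to the gap", {
  set.seed(21)
  for (i in 1:20) {
    fx <- random_trajectory(sample(20:120, 1), span_hours = 240)
    spec <- snap_grid(fx, 1000)
    g6 <- build_time_use_grid(fx, spec, 6)
    g12 <- build_time_use_grid(fx, spec, 12)
    g24 <- build_time_use_grid(fx, spec, 24)
    expect_equal(sum(g12$cells$n_fixes), nrow(fx))
    expect_equal(sum(g12$visits$n_locations), nrow(fx))
    m <- dplyr::inner_join(g6$cells, g12$cells, by = "cell_id",
                           suffix = c("_6", "_12")) |>
      dplyr::inner_join(dplyr::rename_with(g24$cells, ~ paste0(.x, "_24"),
                                           -dplyr::all_of("cell_id")),
                        by = "cell_id")
    expect_true(all(m$nsv_6 >= m$nsv_12 & m$nsv_12 >= m$nsv_24))
    expect_true(all(m$mlsv_6 <= m$mlsv_12 & m$mlsv_12 <= m$mlsv_24))
  }
})

test_that("grid statistics match the brute-force visit oracle", {
  set.seed(22)
  for (i in 1:30) {
    fx <- random_trajectory(sample(10:100, 1), span_hours = 300,
                            extent = 3000)
    spec <- snap_grid(fx, 1000)
    ivg <- sample(c(6, 12, 24), 1)
    got <- build_time_use_grid(fx, spec, ivg)$cells
    want <- oracle_visits(fx, spec, ivg)$cells
    m <- merge(got, want, by = "cell_id")
    expect_equal(nrow(m), nrow(want))
    expect_equal(m$nsv.x, m$nsv.y)
    expect_equal(m$mlsv.x, m$mlsv.y)
  }
})

test_that("biweekly pipeline drops gappy intervals and pools the rest", {
  sc <- generate_scenario(scenario_config(n_individuals = 2, n_days = 40,
                                          fix_dropout_prob = 0,
                                          rng_seed = 17))
  tu <- biweekly_time_use(sc$trajectories)
  expect_s3_class(tu, "biweekly_timeuse")
  expect_true(all(tu$coverage$days_with_fix <= 16))
  expect_true(all(tu$cells$interval_start %in%
                    tu$coverage$interval_start[tu$coverage$pass]))
  expect_true(all(tu$cells$nsv >= 1))
  expect_true(all(tu$cells$mlsv >= 1))
})
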
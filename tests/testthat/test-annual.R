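day_fixes <- function(days, x = 500, y = 500, id = "A") {
  make_fixes(t_utc("2012-04-01 12:00:00") + days * 86400, x, y, id)
}

test_that("a 7-day gap splits annual visits; shorter absences merge", {
  g <- suppressWarnings(annual_visits(day_fixes(c(0, 3, 20))))
  expect_equal(g$cells$nsv, 2)  # 3-day gap merges, 17-day gap splits
  expect_equal(g$ivg_hours, 168)
  expect_warning(annual_visits(day_fixes(0:1)), "span")
})

test_that("annual nsv never exceeds short-gap nsv cell-wise", {
  set.seed(41)
  fx <- random_trajectory(150, span_hours = 24 * 400, extent = 3000)
  spec <- snap_grid(fx, 1000)
  short <- build_time_use_grid(fx, spec, 12)
  long <- build_time_use_grid(fx, spec, 7 * 24)
  m <- dplyr::inner_join(short$cells, long$cells, by = "cell_id",
                         suffix = c("_12h", "_7d"))
  expect_true(all(m$nsv_7d <= m$nsv_12h))
})

test_that("waterhole cells are flagged by the half-open square rule", {
  fx <- make_fixes(t_utc("2012-01-01 00:00:00") + (0:3) * 86400 * 10,
                   x = c(500, 1500, 500, 1500), y = 500)
  g <- build_time_use_grid(fx, snap_grid(fx, 1000), 7 * 24)
  # hole at a cell centre excludes that cell only
  g1 <- exclude_waterhole_cells(g, tibble::tibble(id = "W", x = 500, y = 500))
  expect_equal(sort(g1$cells$cell_id[g1$cells$waterhole]), "0_0")
  # hole on the shared edge x = 1000 belongs to the higher cell
  g2 <- exclude_waterhole_cells(g, tibble::tibble(id = "W", x = 1000, y = 500))
  expect_equal(sort(g2$cells$cell_id[g2$cells$waterhole]), "1_0")
  # no waterholes: nothing flagged, statistics untouched
  g3 <- exclude_waterhole_cells(g, tibble::tibble(id = character(),
                                                  x = numeric(),
                                                  y = numeric()))
  expect_false(any(g3$cells$waterhole))
  expect_equal(g3$cells$nsv, g$cells$nsv)
})

test_that("return times measure end-of-visit to start-of-next for busy cells", {
  g <- suppressWarnings(annual_visits(day_fixes(c(0, 10, 40))))
  rt <- return_times(g, min_visits = 3)
  expect_equal(sort(rt$gap_days), c(10, 30))
  expect_equal(unique(rt$cell_nsv), 3)

  two <- suppressWarnings(annual_visits(day_fixes(c(0, 10))))
  expect_equal(nrow(return_times(two, min_visits = 3)), 0)
})

test_that("gap counts, spans and waterhole exclusion behave as invariants say", {
  set.seed(42)
  fx <- random_trajectory(200, span_hours = 24 * 360, extent = 4000)
  g <- suppressWarnings(annual_visits(fx))
  g <- exclude_waterhole_cells(g, tibble::tibble(id = "W", x = 200, y = 200))
  rt <- return_times(g)
  if (nrow(rt) > 0) {
    counts <- dplyr::count(rt, .data$cell_id, .data$cell_nsv)
    expect_equal(counts$n, counts$cell_nsv - 1L)
    span <- as.numeric(difftime(max(fx$t), min(fx$t), units = "days"))
    expect_true(all(rt$gap_days > 0 & rt$gap_days <= span))
    expect_false(any(rt$cell_id %in% g$cells$cell_id[g$cells$waterhole]))
  }
  h <- bin_return_times(rt)
  expect_equal(sum(h$n_returns), nrow(rt))
})

test_that("range metrics follow the visited/revisited-cell definitions", {
  # four cells with nsv 3, 2, 1, 1
  fx <- dplyr::bind_rows(
    day_fixes(c(0, 10, 40), x = 500),            # cell 0: 3 visits
    day_fixes(c(1, 21), x = 1500),               # cell 1: 2 visits
    day_fixes(2, x = 2500),                      # cell 2: 1 visit
    day_fixes(3, x = 3500)                       # cell 3: 1 visit
  )
  g <- suppressWarnings(annual_visits(fx))
  m <- range_metrics(g)
  expect_equal(m$range_size, 4)
  expect_equal(m$prop_revisited, 0.5)
  expect_equal(m$mean_nsv, 2.5)
  expect_equal(m$median_nsv, 2.5)
  expect_equal(m$sd_nsv, sd(c(3, 2)))
  # 75th percentile of {3,2,1,1} is 2.25 -> only the nsv-3 cell qualifies
  expect_equal(m$top_quartile_count, 1)

  all_once <- suppressWarnings(annual_visits(
    day_fixes(0:3, x = c(500, 1500, 2500, 3500))))
  m1 <- range_metrics(all_once)
  expect_equal(m1$prop_revisited, 0)
  expect_true(is.na(m1$mean_nsv) && is.na(m1$median_nsv) && is.na(m1$sd_nsv))
  expect_equal(m1$top_quartile_count, m1$range_size)  # all tied at the quantile
})

test_that("range correlations recover engineered relationships", {
  metrics <- tibble::tibble(
    individual_id = paste0("R", 1:6),
    range_size = c(10, 20, 30, 40, 50, 60),
    mean_nsv = 6:1, median_nsv = 6:1,
    sd_nsv = c(3, 2.5, 2, 1.5, 1, 0.5),
    prop_revisited = seq(0.9, 0.4, by = -0.1),
    top_quartile_count = rep(2, 6)
  )
  rc <- range_correlations(metrics)
  expect_equal(rc$estimate[rc$metric == "median_nsv"], -1)
  expect_equal(rc$estimate[rc$metric == "sd_nsv"], -1)
  expect_equal(rc$estimate[rc$metric == "prop_revisited"], -1)

  loo <- range_correlations(metrics, leave_out = "R6")
  expect_setequal(unique(loo$excluded), c("none", "R6"))
  expect_true(all(loo$n[loo$excluded == "R6"] == 5))
  expect_error(range_correlations(metrics[1:3, ]), "at least 4")
})
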
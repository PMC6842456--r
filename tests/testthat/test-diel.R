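cfg <- anchor_config()  # dawn 07, midday 13, dusk 19, midnight 01; +/-2.5 h

test_that("an early-morning fix with no rival is recorded as that day's dawn fix", {
  # local 05:45, nothing else before 09:30
  fx <- local_fix("2012-04-03 05:45:00")
  diel <- standardize_diel_fixes(fx, cfg)
  expect_equal(nrow(diel), 1)
  expect_equal(diel$anchor, "dawn")
  expect_equal(diel$date, as.Date("2012-04-03"))
  expect_equal(diel$offset_min, -75)
})

test_that("fixes exactly on the four anchors give zero offsets", {
  fx <- local_fix(c("2012-04-03 01:00:00", "2012-04-03 07:00:00",
                    "2012-04-03 13:00:00", "2012-04-03 19:00:00"))
  diel <- standardize_diel_fixes(fx, cfg)
  expect_equal(nrow(diel), 4)
  expect_setequal(diel$anchor, c("midnight", "dawn", "midday", "dusk"))
  expect_equal(diel$offset_min, rep(0, 4))
  expect_equal(diel$date, rep(as.Date("2012-04-03"), 4))
})

test_that("the closest candidate wins; equal offsets go to the earlier fix", {
  fx <- local_fix(c("2012-04-03 06:10:00", "2012-04-03 07:40:00"),
                  x = c(1, 2))
  diel <- standardize_diel_fixes(fx, cfg)
  expect_equal(diel$anchor, "dawn")
  expect_equal(diel$x, 2)  # |+40| beats |-50|
  expect_equal(diel$offset_min, 40)

  tie <- local_fix(c("2012-04-03 06:30:00", "2012-04-03 07:30:00"),
                   x = c(1, 2))
  expect_equal(standardize_diel_fixes(tie, cfg)$x, 1)
})

test_that("midnight windows spanning the date boundary assign to the anchor's date", {
  fx <- local_fix("2012-04-03 23:30:00")  # within 01:00 +/- 2:30 of Apr 4
  diel <- standardize_diel_fixes(fx, cfg)
  expect_equal(diel$anchor, "midnight")
  expect_equal(diel$date, as.Date("2012-04-04"))
  expect_equal(diel$offset_min, -90)
})

test_that("displacement records use exact elapsed time and Euclidean distance", {
  fx <- local_fix(c("2012-04-03 06:30:00", "2012-04-04 07:30:00"),
                  x = c(0, 3000), y = c(0, 4000))
  diel <- standardize_diel_fixes(fx, cfg)
  d <- compute_displacements(diel, 24, cfg)
  expect_equal(nrow(d), 1)
  expect_equal(d$distance_m, 5000)
  expect_equal(d$elapsed_h, 25)
  expect_equal(d$rate_m_per_h, 200)
  expect_equal(d$start_anchor, "dawn")

  still <- local_fix(c("2012-04-03 07:00:00", "2012-04-04 07:00:00"),
                     x = 100, y = 100)
  expect_equal(compute_displacements(standardize_diel_fixes(still, cfg),
                                     24, cfg)$rate_m_per_h, 0)
  expect_error(compute_displacements(diel, 8, cfg), "6, 12 or 24")
})

test_that("missing diel fixes break the pairing chain", {
  fx <- local_fix(c("2012-04-03 19:00:00",   # dusk day 1
                    "2012-04-05 19:00:00"))  # dusk day 3; day 2 missing
  d <- compute_displacements(standardize_diel_fixes(fx, cfg), 24, cfg)
  expect_equal(nrow(d), 0)
})

test_that("12-h lags pair anchors two slots apart in both directions", {
  fx <- local_fix(c("2012-04-03 07:00:00", "2012-04-03 19:00:00",
                    "2012-04-04 07:00:00"), x = c(0, 100, 300))
  d <- compute_displacements(standardize_diel_fixes(fx, cfg), 12, cfg)
  expect_equal(nrow(d), 2)
  expect_equal(d$start_anchor, c("dawn", "dusk"))
  expect_equal(d$end_anchor, c("dusk", "dawn"))
  # the dusk fix ends one record and starts the next
  expect_equal(d$start_t[2], d$end_t[1])
})

test_that("season labels follow the November-March wet season by local month", {
  expect_equal(classify_season(t_utc("2013-01-15 10:00:00")), "wet")
  expect_equal(classify_season(t_utc("2013-07-15 10:00:00")), "dry")
  # local Mar 31 vs Apr 1 around the boundary (UTC+2)
  expect_equal(classify_season(t_utc("2013-03-31 20:00:00")), "wet")
  expect_equal(classify_season(t_utc("2013-03-31 23:00:00")), "dry")
})

test_that("waterhole proximity uses the nearest hole with an inclusive radius", {
  wh <- tibble::tibble(id = c("W1", "W2"), x = c(0, 10000), y = c(0, 0))
  diel <- standardize_diel_fixes(
    local_fix(c("2012-04-03 07:00:00", "2012-04-03 13:00:00",
                "2012-04-03 19:00:00"),
              x = c(0, 251, 250), y = 0), cfg)
  counts <- waterhole_proximity_counts(diel, wh, radius_m = 250)
  expect_equal(counts$n_near[counts$anchor == "dawn"], 1)    # at the hole
  expect_equal(counts$n_near[counts$anchor == "midday"], 0)  # 251 m: out
  expect_equal(counts$n_near[counts$anchor == "dusk"], 1)    # 250 m: in
  expect_error(waterhole_proximity_counts(diel, wh[0, ]), "empty")
})

test_that("displacement rates are invariant under rigid motions", {
  set.seed(31)
  fx <- make_fixes(t_utc("2012-04-01 07:00:00") + (0:19) * 86400,
                   runif(20, 0, 5000), runif(20, 0, 5000))
  base <- compute_displacements(standardize_diel_fixes(fx, cfg), 24, cfg)
  th <- 0.7
  rot <- dplyr::mutate(fx, x0 = x, x = cos(th) * x0 - sin(th) * y + 1e4,
                       y = sin(th) * x0 + cos(th) * y - 5e3)
  moved <- compute_displacements(standardize_diel_fixes(rot, cfg), 24, cfg)
  expect_equal(moved$rate_m_per_h, base$rate_m_per_h)
  expect_true(all(base$rate_m_per_h >= 0))
})

test_that("a structureless generator yields no diel displacement differences", {
  # flat speed profile, no waterhole or dawn bias: dawn-vs-dusk KS should
  # reject at roughly the nominal rate across seeds
  rej <- 0
  for (s in 1:10) {
    sc <- generate_scenario(scenario_config(
      n_individuals = 1, n_days = 40, fix_dropout_prob = 0,
      fix_time_jitter_sd = 0, dusk_water_bias = 0, dawn_return_bias = 0,
      crepuscular_speed_profile = rep(1, 24), wet_season_speed_factor = 1,
      rng_seed = 400 + s))
    d <- compute_displacements(standardize_diel_fixes(sc$trajectories, cfg),
                               24, cfg)
    p <- suppressWarnings(stats::ks.test(
      d$rate_m_per_h[d$start_anchor == "dawn"],
      d$rate_m_per_h[d$start_anchor == "dusk"])$p.value)
    if (p < 0.05) rej <- rej + 1
  }
  expect_lte(rej, 3)
})
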
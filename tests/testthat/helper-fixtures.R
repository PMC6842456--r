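# Small programmatic fixtures shared across test files.

t_utc <- function(s) as.POSIXct(s, tz = "UTC")

# fixes at given local clock strings (UTC+2 by default elsewhere)
local_fix <- function(times_local, x = 0, y = 0, id = "A", utc_offset = 2,
                      sex = "unknown") {
  tl <- t_utc(times_local)
  tibble::tibble(individual_id = id, t = tl - utc_offset * 3600,
                 x = x, y = y, sex = sex)
}

make_fixes <- function(t, x, y, id = "A", sex = "unknown") {
  tibble::tibble(individual_id = id, t = t, x = x, y = y, sex = sex)
}

# random irregular trajectory for property tests
random_trajectory <- function(n, span_hours = n, extent = 4000, id = "A") {
  t0 <- t_utc("2012-01-01 00:00:00")
  ts <- t0 + sort(sample.int(span_hours * 3600, n))
  make_fixes(ts, runif(n, 0, extent), runif(n, 0, extent), id = id)
}

# one-cell trajectory with fixes at given hour offsets
hours_fixes <- function(hours, x = 500, y = 500, id = "A") {
  make_fixes(t_utc("2012-01-01 00:00:00") + hours * 3600, x, y, id)
}

constant_raster <- function(value, n = 8, cellsize = 250, xll = 0, yll = 0) {
  greenness_raster(matrix(value, n, n), xll, yll, cellsize,
                   period_start = as.Date("2012-01-01"))
}
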
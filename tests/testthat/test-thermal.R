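test_that("growth-temperature quadratic evaluates and validates", {
  m <- growth_temp_model()
  expect_equal(msgr_at_temp(m, 0), -2.85)
  expect_equal(msgr_at_temp(m, 17.6), 4.23928)
  expect_equal(msgr_at_temp(m, 12.9), 3.67998)
  expect_equal(vertex_temperature(m), 17.9545454545, tolerance = 1e-9)
  expect_error(msgr_at_temp(m, NaN), "finite")
  expect_error(growth_temp_model(c2 = 0.01), "negative")
  expect_error(growth_temp_model(c0 = -100), "positive")
})

test_that("degree-day conversion matches the quadratic and its properties", {
  expect_equal(growing_degree_days(10, 17.6), 10)
  expect_equal(growing_degree_days(42, 12.9), 36.4588231964,
               tolerance = 1e-9)
  expect_equal(growing_degree_days(35, 9.8), 22.9447453341,
               tolerance = 1e-9)
  # linear in days; strictly below calendar days off the optimum
  for (t in c(5, 9.8, 12.9, 15.1, 20)) {
    expect_equal(growing_degree_days(20, t), 2 * growing_degree_days(10, t))
    if (t != 17.6) expect_lt(growing_degree_days(30, t), 30)
  }
  expect_error(growing_degree_days(30, 0), "below growth threshold")
  expect_error(growing_degree_days(-1, 12), ">= 0")
})

test_that("growing-season mean handles constant, ramp, and empty windows", {
  s <- constant_series(10, 30)
  expect_equal(growing_season_mean(s, s$timestamp[1], s$timestamp[30]), 10)
  ramp <- temperature_series(
    "ramp", seq(as.Date("2008-07-01"), by = "day", length.out = 41),
    seq(8, 12, length.out = 41))
  expect_equal(growing_season_mean(ramp, ramp$timestamp[1],
                                   ramp$timestamp[41]), 10)
  expect_error(growing_season_mean(s, as.Date("2030-01-01"),
                                   as.Date("2030-02-01")), "no readings")
})

test_that("temperature series constructor enforces invariants", {
  d <- seq(as.Date("2008-07-01"), by = "day", length.out = 5)
  expect_error(temperature_series("x", d, c(1, 2, 3, 4, 50)), "\\[-5, 40\\]")
  expect_error(temperature_series("x", d[c(1, 2, 2, 3, 4)], rep(1, 5)),
               "strictly increasing")
})

test_that("ice-cover duration finds the longest sustained cold run", {
  start <- as.Date("2008-10-01")
  n <- 400
  temps <- rep(5, n)
  temps[51:(50 + 145)] <- 0.5
  s <- temperature_series("winter", seq(start, by = "day", length.out = n),
                          temps)
  expect_equal(ice_cover_duration(s), 145)
  # longest-run rule with two qualifying runs
  temps2 <- rep(5, n)
  temps2[11:40] <- 0.4
  temps2[101:(100 + 204)] <- 0.6
  s2 <- temperature_series("two", seq(start, by = "day", length.out = n),
                           temps2)
  expect_equal(ice_cover_duration(s2), 204)
  # warm series
  expect_warning(d0 <- ice_cover_duration(constant_series(6, 100)),
                 "returning 0")
  expect_equal(d0, 0)
  # sub-sampling at a quarter of min_run leaves the duration within one step
  sub <- s[seq(1, n, by = 2), ]
  expect_lt(abs(ice_cover_duration(sub) - 145), 2.5)
})

test_that("short logger gaps are bridged, long gaps flagged", {
  d <- seq(as.Date("2008-07-01"), by = "day", length.out = 40)
  keep <- setdiff(seq_len(40), 11:15) # 5-day hole
  s <- temperature_series("gap", d[keep], seq(8, 12,
                                              length.out = 40)[keep])
  filled <- fill_logger_gaps(s)
  expect_equal(nrow(filled), 40)
  expect_equal(filled$temp_c, seq(8, 12, length.out = 40),
               tolerance = 1e-8)
  # a 20-day hole exceeds the default bridge limit
  keep2 <- setdiff(seq_len(40), 11:30)
  s2 <- temperature_series("gap2", d[keep2],
                           seq(8, 12, length.out = 40)[keep2])
  out2 <- fill_logger_gaps(s2)
  expect_equal(nrow(out2), length(keep2))
  expect_equal(nrow(attr(out2, "unfilled_gaps")), 1)
})
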
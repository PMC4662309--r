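test_that("energy budget balances or fills the missing component", {
  b <- energy_budget(consumption = 10, growth = 4, metabolism = 5,
                     waste = 1)
  expect_equal(b$consumption, b$growth + b$metabolism + b$waste)
  b2 <- energy_budget(growth = 4, metabolism = 5, waste = 1)
  expect_equal(b2$consumption, 10)
  b3 <- energy_budget(consumption = 10, metabolism = 5, waste = 1)
  expect_equal(b3$growth, 4)
  expect_error(energy_budget(consumption = 10, growth = 4, metabolism = 5,
                             waste = 2), "balance")
})

test_that("respiration forms behave as configured", {
  flat <- metabolic_params(mass_coeff_b = 0)
  expect_equal(respiration_rate(c(0.5, 2, 7), flat),
               rep(flat$intercept_a, 3))
  prop <- metabolic_params(intercept_a = 2, mass_coeff_b = 1,
                           form = "power")
  expect_equal(respiration_rate(c(1, 2, 4), prop), c(2, 4, 8))
  lin <- metabolic_params(mass_coeff_b = 2)
  expect_equal(respiration_rate(3, lin), 11.16623 + 6)
  expect_error(respiration_rate(0, flat), "positive")
})

test_that("threshold concentration scales with winter duration and mass", {
  p145 <- metabolic_params(winter_days = 145)
  p204 <- metabolic_params(winter_days = 204)
  p0 <- metabolic_params(winter_days = 0)
  w <- seq(0.3, 7, length.out = 20)
  expect_equal(threshold_concentration(w, p0), rep(0, 20))
  expect_equal(threshold_concentration(w, p204),
               threshold_concentration(w, p145) * 204 / 145)
  # strictly decreasing in mass, for both functional forms
  expect_true(all(diff(threshold_concentration(w, p204)) < 0))
  pw <- metabolic_params(form = "power", mass_coeff_b = 0.8,
                         winter_days = 204)
  expect_true(all(diff(threshold_concentration(w, pw)) < 0))
  # the long winter demands more at every mass
  expect_true(all(threshold_concentration(w, p204) >
                    threshold_concentration(w, p145)))
})

test_that("threshold families are ordered and scale with the intercept", {
  p <- metabolic_params()
  fam <- threshold_family(p, multipliers = c(0.5, 1))
  lo <- fam$threshold_g_per_g[fam$multiplier == 0.5]
  hi <- fam$threshold_g_per_g[fam$multiplier == 1]
  expect_equal(hi, 2 * lo) # intercept-only demand: exact linear scaling
  fam5 <- threshold_family(p)
  expect_equal(sort(unique(fam5$multiplier)), c(0.5, 0.75, 1, 1.25, 1.5))
  by_m <- split(fam5$threshold_g_per_g, fam5$multiplier)
  for (i in 1:4) expect_true(all(by_m[[i + 1]] > by_m[[i]]))
  expect_error(threshold_family(p, mass_grid = numeric(0)), "empty")
  expect_error(threshold_family(p, mass_grid = c(2, 1)), "increasing")
})

test_that("classification is monotone in the curve multiplier", {
  p <- metabolic_params()
  expect_equal(classify_overwinter(0, 2, p), "starve")
  top <- threshold_concentration(2, p, multiplier = 1.5)
  for (m in c(0.5, 0.75, 1, 1.25, 1.5)) {
    expect_equal(classify_overwinter(top * 1.01, 2, p, m), "survive")
  }
  conc <- withr::with_seed(5, runif(100, 0, 0.06))
  mass <- withr::with_seed(6, runif(100, 0.3, 7))
  n_survive <- vapply(c(0.5, 0.75, 1, 1.25, 1.5), function(m) {
    sum(classify_overwinter(conc, mass, p, m) == "survive")
  }, numeric(1))
  expect_true(all(diff(n_survive) <= 0))
})

test_that("depletion trajectories agree with the threshold construction", {
  p <- metabolic_params(winter_days = 204)
  demand <- threshold_concentration(2, p) * 2 # total g for the winter
  out <- simulate_depletion(2, 2 * demand, p)
  expect_true(out$survived)
  expect_equal(out$trajectory$lipid_g[nrow(out$trajectory)], demand,
               tolerance = 1e-9)
  exact <- simulate_depletion(2, demand, p)
  expect_false(exact$survived)
  expect_equal(exact$starvation_day, 204, tolerance = 1)
  # finer stepping moves the starvation day by less than one coarse step
  fine <- simulate_depletion(2, demand * 0.7, p, dt = 0.5)
  coarse <- simulate_depletion(2, demand * 0.7, p, dt = 1)
  expect_lt(abs(fine$starvation_day - coarse$starvation_day), 1)
  expect_error(simulate_depletion(2, 1, p, dt = 0), "positive")
})

test_that("calibration pins the anchor point without touching ratios", {
  p <- calibrate_metabolic_params(metabolic_params(winter_days = 204),
                                  anchor_mass = 2, anchor_conc = 0.03)
  expect_equal(threshold_concentration(2, p), 0.03, tolerance = 1e-12)
  q <- metabolic_params(winter_days = 204)
  expect_equal(threshold_concentration(1, p) / threshold_concentration(4, p),
               threshold_concentration(1, q) / threshold_concentration(4, q))
  expect_error(calibrate_metabolic_params(metabolic_params(winter_days = 0),
                                          2, 0.03), "zero winter")
})
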
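test_that("generators are deterministic under a fixed seed", {
  s1 <- suppressWarnings(simulate_experiment(seed = 12,
                                             temperatures = FALSE))
  s2 <- suppressWarnings(simulate_experiment(seed = 12,
                                             temperatures = FALSE))
  expect_identical(s1$fish, s2$fish)
  expect_identical(s1$lipids, s2$lipids)
  expect_identical(s1$counts_spring, s2$counts_spring)
  s3 <- suppressWarnings(simulate_experiment(seed = 13,
                                             temperatures = FALSE))
  expect_false(identical(s1$fish$wet_mass_g, s3$fish$wet_mass_g))
})

test_that("temperature series round-trip the configured ice durations", {
  sc <- default_scenario()
  temps <- generate_temperatures(sc, seed = 4)
  for (lk in c("cigar", "pantano")) {
    series <- temps[temps$lake_id == lk, ]
    want <- sc$lakes$ice_days[sc$lakes$lake_id == lk]
    expect_lt(abs(ice_cover_duration(series) - want), 2.5)
  }
})

test_that("zero-amplitude, ice-free config gives a constant series", {
  sc <- default_scenario()
  sc$temperature$amplitude_scale <- 0
  sc$temperature$noise_sd <- 0
  sc$lakes$ice_days <- 0
  temps <- generate_temperatures(sc, seed = 4)
  expect_equal(length(unique(temps$temp_c)), 1)
})

test_that("zero-growth config returns stocking masses", {
  sc <- default_scenario()
  sc$growth$base_msgr_gdd <- c(Blackwater = 0, Pennask = 0)
  sc$growth$env_offset_gdd <- 0
  sc$growth$lake_sd <- 0
  sc$growth$mass_sdlog <- 1e-12
  co <- generate_cohort(sc, seed = 5)
  joined <- dplyr::left_join(co$fish, sc$stocking_mass,
                             by = c("year", "strain"))
  expect_equal(joined$wet_mass_g, joined$mean_mass_g, tolerance = 0.01)
})

test_that("complete capture recovers the true abundance exactly", {
  truth <- tibble::tibble(lake_id = "x", strain = "Pennask",
                          environment = "low", true_n = 1234L,
                          n0_effective = 2000L)
  counts <- generate_markrecapture(truth, p_mark = 1, p_capture = 1,
                                   seed = 6)
  expect_equal(petersen_estimate(counts$M, counts$C, counts$R), 1234)
})

test_that("winter outcomes honor duration and metabolic-rate orderings", {
  sc <- default_scenario()
  co <- generate_cohort(sc, seed = 7)
  # no winter, no starvation
  sc0 <- sc
  sc0$lakes$ice_days <- 0
  w0 <- generate_winter_outcomes(sc0, co, seed = 8)
  expect_true(all(w0$outcomes$outcome == "survive"))
  # harsher intrinsic metabolism, fewer survivors, same draws
  w1 <- generate_winter_outcomes(sc, co, seed = 8)
  sc_hot <- sc
  sc_hot$winter_params$intercept_a <- sc$winter_params$intercept_a * 1.5
  w2 <- generate_winter_outcomes(sc_hot, co, seed = 8)
  expect_lt(sum(w2$outcomes$outcome == "survive"),
            sum(w1$outcomes$outcome == "survive"))
  # and the long high-elevation winter kills more at the same rate
  frac <- w1$outcomes |>
    dplyr::group_by(environment) |>
    dplyr::summarise(s = mean(outcome == "survive"), .groups = "drop")
  expect_lt(frac$s[frac$environment == "high"],
            frac$s[frac$environment == "low"])
})

test_that("noise-free lipid samples sit exactly on the configured law", {
  sc <- default_scenario()
  sc$lipid$noise_sdlog <- 1e-12
  co <- generate_cohort(sc, seed = 9)
  li <- suppressWarnings(generate_lipids(sc, co, seed = 10))
  mass <- li$combined_wet_mass_g / 2
  expected <- exp(sc$lipid$intercept[li$environment] +
                    sc$lipid$slope[li$environment] * log(mass))
  # extraction masses are recorded to 0.1 mg, the only residual slack
  expect_equal(li$lipid_conc_wet, unname(expected), tolerance = 5e-4)
})

test_that("default scenario mirrors the stocking design shape", {
  sc <- default_scenario()
  sim <- suppressWarnings(simulate_experiment(sc, seed = 14,
                                              temperatures = FALSE))
  # 5 lake units in year one, 4 in year two; both strains everywhere
  cells <- dplyr::count(sim$fish, year, lake_id, strain)
  expect_equal(nrow(cells), 18)
  expect_equal(nrow(sim$lipids), sum(sc$years$n_lipid_pairs))
  expect_equal(nrow(sim$fish), sum(sc$years$n_growth_sample))
  # winterkill lakes lose everyone; the others keep a plausible population
  st <- sim$winter$spring_truth
  expect_true(all(st$true_n[st$winterkill] == 0))
  expect_true(all(st$true_n[!st$winterkill] > 0))
})
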
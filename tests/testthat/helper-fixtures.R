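# shared fixtures built in code

# lake-year mean-temperature table matching the scenario's season config
season_thermal <- function(sim) {
  sim$fish[c("lake_id", "year", "environment")] |>
    dplyr::distinct() |>
    dplyr::inner_join(sim$scenario$season, by = c("year", "environment")) |>
    dplyr::select(lake_id, year, mean_temp_c)
}

# one full synthetic replicate analysed end to end
run_pipeline <- function(seed, scenario = default_scenario()) {
  sim <- simulate_experiment(scenario, seed, temperatures = FALSE)
  growth <- growth_table(sim$fish, sim$stocking, season_thermal(sim))
  est_spring <- estimate_table(sim$counts_spring)
  est_fall <- estimate_table(sim$counts_fall)
  list(
    sim = sim, growth = growth,
    est_spring = est_spring, est_fall = est_fall,
    fit_gdd = fit_effect_model(growth, "msgr_gdd", unit = "fish"),
    ancova = lipid_ancova(sim$lipids),
    surv_means = dplyr::filter(est_spring, !winterkill) |>
      dplyr::group_by(environment) |>
      dplyr::summarise(v = mean(survival), .groups = "drop"),
    q_means = est_fall |>
      dplyr::group_by(environment) |>
      dplyr::summarise(v = mean(q), .groups = "drop")
  )
}

# scenario with all configured strain and environment effects removed
# (shared baseline growth and stocking mass, no elevation offset, equal
# catchability) and a lighter fall sample, for type-I-error simulations
null_scenario <- function(n_per_year = c(360L, 288L)) {
  sc <- default_scenario()
  sc$growth$base_msgr_gdd <- c(Blackwater = 2.9, Pennask = 2.9)
  sc$growth$env_offset_gdd <- 0
  sc$stocking_mass$mean_mass_g <- rep(0.75, 4)
  sc$capture$q_true <- c(low = 1e-3, high = 1e-3)
  sc$years$n_growth_sample <- n_per_year
  sc
}

# flat-line temperature series fixture
constant_series <- function(temp, days, start = as.Date("2008-07-01"),
                            lake = "flat") {
  temperature_series(lake, seq(start, by = "day", length.out = days),
                     rep(temp, days))
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected) / abs(expected)), tol)
}

# minimal lake-level 2x2 design with n_low + n_high lakes
lake_design <- function(n_low, n_high, seed = 1) {
  lakes <- c(sprintf("low%d", seq_len(n_low)),
             sprintf("high%d", seq_len(n_high)))
  d <- expand.grid(lake_id = lakes, strain = c("Blackwater", "Pennask"),
                   stringsAsFactors = FALSE)
  d$environment <- ifelse(grepl("^low", d$lake_id), "low", "high")
  d$survival <- withr::with_seed(seed, stats::runif(nrow(d), 0.2, 0.6))
  d
}
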
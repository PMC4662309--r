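#' Default synthetic scenario
#'
#' A seeded, parameterized emulation of the two-year, two-strain,
#' two-elevation whole-lake stocking design: five lakes in year one (three
#' low-elevation, two high), four experimental units in year two, stocking
#' densities of 2255 and 2800 fry per hectare, strain-specific stocking
#' masses, a 145-day versus 204-day ice-cover contrast, degree-day-scaled
#' growth with a strain effect and an additive high-elevation degree-day
#' advantage, a log-log mass-lipid law with a shallower
#' high-elevation slope, threshold-driven winter starvation, and binomial
#' mark-recapture sampling with an activity (catchability) contrast between
#' environments.
#'
#' Configured truths double as test oracles: the strain effect on growth is
#' present, the strain effect on lipid concentration (at a given size) is
#' absent, growing-season survival is environment-neutral, winter survival
#' and catchability differ between environments. Two of the three
#' low-elevation lakes are flagged as anoxic winterkill losses, mirroring
#' the realized design and exercising the exclusion path.
#'
#' @return A list of class `scenario_config`; see the construction for the
#'   field-by-field layout.
#' @export
default_scenario <- function() {
  lakes <- tibble(
    lake_id = c("cigar", "noname", "smoke", "pantano", "spook",
                "big_pantano", "little_pantano"),
    environment = c("low", "low", "low", "high", "high", "high", "high"),
    area_ha = c(4.2, 2.5, 2.0, 5.5, 3.1, 3.4, 2.1),
    ice_days = c(145, 145, 145, 204, 204, 204, 204),
    peak_t = c(21, 21, 21, 13.5, 13.5, 13.5, 13.5),
    ice_on = as.Date(c(rep("2008-11-25", 3), rep("2008-11-01", 4))),
    winterkill = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
  lake_years <- tibble(
    lake_id = c("cigar", "noname", "smoke", "pantano", "spook",
                "cigar", "smoke", "big_pantano", "little_pantano"),
    year = c(rep(2008L, 5), rep(2009L, 4))
  )
  years <- tibble(
    year = c(2008L, 2009L),
    stock_date = as.Date(c("2008-08-29", "2009-08-26")),
    density_per_ha = c(2255, 2800),
    n_growth_sample = c(1124L, 1962L),
    n_lipid_pairs = c(257L, 209L)
  )
  season <- tibble(
    year = c(2008L, 2008L, 2009L, 2009L),
    environment = c("low", "high", "low", "high"),
    days = c(42, 35, 45, 38),
    mean_temp_c = c(12.9, 9.8, 15.1, 11.5)
  )
  stocking_mass <- tibble(
    year = c(2008L, 2008L, 2009L, 2009L),
    strain = c("Blackwater", "Pennask", "Blackwater", "Pennask"),
    mean_mass_g = c(0.75, 0.85, 0.66, 0.65)
  )
  winter <- calibrate_metabolic_params(
    metabolic_params(winter_days = 204),
    anchor_mass = 2, anchor_conc = 0.030)
  structure(list(
    lakes = lakes, lake_years = lake_years, years = years, season = season,
    stocking_mass = stocking_mass,
    growth = list(base_msgr_gdd = c(Blackwater = 3.2, Pennask = 2.6),
                  env_offset_gdd = 0.35, lake_sd = 0.12,
                  mass_sdlog = 0.2),
    lipid = list(slope = c(low = 0.55, high = 0.35),
                 intercept = c(low = log(0.027) - 0.55 * log(2.4),
                               high = log(0.027) - 0.35 * log(2.4)),
                 noise_sdlog = 0.06, dry_wet_ratio = 0.25,
                 dry_aliquot_g = 0.5, pair_tolerance_mm = 2),
    winter_params = winter,
    survival = list(growing_season = 0.5),
    capture = list(spring_p_mark = 0.19, spring_p_capture = 0.40,
                   fall_p_mark = 0.29, fall_p_capture = 0.30,
                   fyke_effort = 25,
                   q_true = c(low = 8e-4, high = 2e-3)),
    temperature = list(noise_sd = 0.25, ice_noise_sd = 0.08,
                       shoulder_min = 1.8, amplitude_scale = 1,
                       peak_doy = 205)
  ), class = "scenario_config")
}

# derive independent sub-seeds (comfortably < 2^31) from one top-level seed
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(1000000000L, n))
}

#' Generate daily temperature-logger series
#'
#' Open-water temperatures follow a seasonal sinusoid peaking at each lake's
#' configured summer maximum; during the configured ice window the 2 m
#' temperature is clamped near 0.5 degrees C. With `amplitude_scale = 0` and
#' no ice window the series is constant at the shoulder minimum.
#'
#' @param scenario A [default_scenario()]-style configuration.
#' @param seed Integer seed.
#' @param from,to Date range of the record (defaults span the experiment:
#'   July 2008 through October 2009).
#' @return A tibble of daily readings: `lake_id`, `timestamp`, `depth_m`,
#'   `temp_c`.
#' @export
generate_temperatures <- function(scenario, seed = 1,
                                  from = as.Date("2008-07-01"),
                                  to = as.Date("2009-10-31")) {
  tcfg <- scenario$temperature
  withr::with_seed(seed, {
    bind_rows(lapply(seq_len(nrow(scenario$lakes)), function(i) {
      lk <- scenario$lakes[i, ]
      dates <- seq(from, to, by = "day")
      doy <- as.numeric(format(dates, "%j"))
      amp <- tcfg$amplitude_scale * (lk$peak_t - tcfg$shoulder_min)
      open <- tcfg$shoulder_min + amp * 0.5 *
        (1 + cos(2 * pi * (doy - tcfg$peak_doy) / 365.25))
      open <- pmax(open + rnorm(length(dates), 0, tcfg$noise_sd),
                   tcfg$shoulder_min)
      in_ice <- dates >= lk$ice_on & dates < lk$ice_on + lk$ice_days
      iced <- pmin(pmax(0.5 + rnorm(length(dates), 0, tcfg$ice_noise_sd),
                        0.15), 0.9)
      temperature_series(lk$lake_id, dates,
                         ifelse(in_ice, iced, open), depth_m = 2)
    }))
  })
}

# per-cell layout: one row per lake-year-strain with design constants
scenario_cells <- function(scenario) {
  scenario$lake_years |>
    left_join(scenario$lakes, by = "lake_id") |>
    left_join(scenario$years, by = "year") |>
    left_join(scenario$season, by = c("year", "environment")) |>
    dplyr::cross_join(tibble(strain = names(scenario$growth$base_msgr_gdd))) |>
    left_join(scenario$stocking_mass, by = c("year", "strain")) |>
    mutate(n_stocked = round(.data$density_per_ha * .data$area_ha / 2))
}

#' Generate the stocked cohorts and their fall samples
#'
#' Each lake-year-strain cell receives a true mean growth rate (per degree
#' day): the strain baseline, plus the high-elevation offset where
#' applicable, plus a shared lake-year deviate. The cell's expected fall
#' mass comes from inverting the mass-specific growth formula over each
#' fish's own degree-day span (capture night is one of five consecutive
#' sampling nights); individual fish then draw lognormal multiplicative
#' variation around that expectation, keeping masses positive and fall-mass
#' spreads right-skewed.
#'
#' @param scenario A scenario configuration.
#' @param seed Integer seed.
#' @return A list: `fish` (fall captures), `stocking` (stocking events),
#'   `truth` (per-cell true mean MSGR per gdd).
#' @export
generate_cohort <- function(scenario, seed = 1) {
  cells <- scenario_cells(scenario)
  g <- scenario$growth
  withr::with_seed(seed, {
    lake_year <- distinct(cells[c("lake_id", "year")])
    lake_year$lake_dev <- rnorm(nrow(lake_year), 0, g$lake_sd)
    cells <- left_join(cells, lake_year, by = c("lake_id", "year"))
    cells$msgr_gdd_true <- g$base_msgr_gdd[cells$strain] +
      ifelse(cells$environment == "high", g$env_offset_gdd, 0) +
      cells$lake_dev
    per_year <- split(cells, cells$year)
    fish <- bind_rows(lapply(per_year, function(cy) {
      n_cells <- nrow(cy)
      n_tot <- cy$n_growth_sample[1]
      n_per <- diff(round(seq(0, n_tot, length.out = n_cells + 1)))
      bind_rows(lapply(seq_len(n_cells), function(j) {
        cell <- cy[j, ]
        n <- n_per[j]
        night <- sample(0:4, n, replace = TRUE)
        capture_date <- cell$stock_date + cell$days + night
        days_i <- as.numeric(capture_date - cell$stock_date)
        gdd_i <- growing_degree_days(days_i, cell$mean_temp_c)
        # invert MSGR = (W2-W1)/(0.5(W1+W2)gdd)*100 for the cell-mean W2;
        # x is capped short of 2 where the inversion diverges
        x <- pmin(cell$msgr_gdd_true * gdd_i / 100, 1.9)
        w2_expected <- cell$mean_mass_g * (1 + x / 2) / (1 - x / 2)
        w2 <- w2_expected * rlnorm(n, -g$mass_sdlog^2 / 2, g$mass_sdlog)
        len <- round((w2 / 1e-5)^(1 / 3) + rnorm(n, 0, 1.5))
        tibble(
          fish_id = sprintf("%s_%d_%s_%03d", cell$lake_id, cell$year,
                            substr(cell$strain, 1, 2), seq_len(n)),
          lake_id = cell$lake_id, year = cell$year, strain = cell$strain,
          environment = cell$environment,
          fork_length_mm = len, wet_mass_g = round(w2, 2),
          capture_date = capture_date, gear = "fyke")
      }))
    }))
    stocking <- cells |>
      select("lake_id", "year", "strain", "mean_mass_g", "n_stocked",
             date = "stock_date", "density_per_ha") |>
      as_tibble()
    list(fish = fish, stocking = stocking,
         truth = select(cells, "lake_id", "year", "strain", "environment",
                        "msgr_gdd_true"))
  })
}

# evaluate the environment's lipid law at a mass, with lognormal noise
lipid_law <- function(scenario, environment, mass, n, sdlog = NULL) {
  l <- scenario$lipid
  if (is.null(sdlog)) sdlog <- l$noise_sdlog
  mu <- unname(l$intercept[environment] + l$slope[environment] * log(mass))
  exp(mu + rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Generate paired lipid samples from a cohort
#'
#' Draws the year-specific number of length-matched pairs (stratified by
#' length via [pair_fish_for_lipid()]), then applies the environment's
#' log-log mass-lipid law at the pair's per-fish mean mass with lognormal
#' measurement noise, and converts back to the raw extraction bookkeeping
#' (dry aliquot, dry/wet ratio, extracted lipid mass).
#'
#' @param scenario A scenario configuration.
#' @param cohort Output of [generate_cohort()].
#' @param seed Integer seed.
#' @return A tibble of lipid samples with both the raw extraction columns
#'   and the derived `lipid_conc_wet`.
#' @export
generate_lipids <- function(scenario, cohort, seed = 1) {
  l <- scenario$lipid
  seeds <- derive_seeds(seed, 2)
  fish <- cohort$fish
  per_year <- split(fish, fish$year)
  pairs <- bind_rows(lapply(per_year, function(fy) {
    yr <- fy$year[1]
    n_tot <- scenario$years$n_lipid_pairs[scenario$years$year == yr]
    cells <- distinct(fy[c("lake_id", "strain")])
    n_per <- diff(round(seq(0, n_tot, length.out = nrow(cells) + 1)))
    bind_rows(lapply(seq_len(nrow(cells)), function(j) {
      sub <- fy[fy$lake_id == cells$lake_id[j] &
                  fy$strain == cells$strain[j], ]
      pair_fish_for_lipid(sub, n_pairs = n_per[j],
                          tolerance_mm = l$pair_tolerance_mm,
                          seed = seeds[1] + j)
    }))
  }))
  withr::with_seed(seeds[2], {
    mass <- pairs$combined_wet_mass_g / 2
    conc <- lipid_law(scenario, pairs$environment, mass, nrow(pairs))
    pairs |>
      mutate(
        sample_id = sprintf("L%04d", row_number()),
        combined_dry_mass_g = round(.data$combined_wet_mass_g *
                                      l$dry_wet_ratio, 4),
        dry_aliquot_g = l$dry_aliquot_g,
        extracted_lipid_g = round(conc * l$dry_aliquot_g /
                                    l$dry_wet_ratio, 5),
        lipid_conc_wet = lipid_concentration_wet(
          .data$extracted_lipid_g, .data$dry_aliquot_g,
          .data$combined_dry_mass_g, .data$combined_wet_mass_g)
      )
  })
}

#' Generate overwinter outcomes and the spring population truth
#'
#' Every fish alive at ice-on carries a lipid concentration drawn from its
#' environment's mass-lipid law; its fate is [classify_overwinter()] against
#' the environment's winter parameter set (same intrinsic metabolic rate,
#' different ice-cover duration). Cell-level survival fractions are applied
#' to the true fall population (stocked, times growing-season survival,
#' minus fall removals) to give the true spring abundance; winterkill lakes
#' lose everything regardless of lipid state.
#'
#' @param scenario A scenario configuration.
#' @param cohort Output of [generate_cohort()] (its 2008 fish stand in for
#'   the at-risk population).
#' @param seed Integer seed.
#' @return A list: `outcomes` (per-fish fate tibble) and `spring_truth`
#'   (per-cell `true_n`, `n0_effective`, `winterkill`).
#' @export
generate_winter_outcomes <- function(scenario, cohort, seed = 1) {
  fish <- cohort$fish[cohort$fish$year == min(cohort$fish$year), ]
  winter_by_env <- function(env, lake_id) {
    p <- scenario$winter_params
    p$winter_days <- scenario$lakes$ice_days[match(lake_id,
                                                   scenario$lakes$lake_id)]
    p
  }
  withr::with_seed(seed, {
    conc <- lipid_law(scenario, fish$environment, fish$wet_mass_g,
                      nrow(fish))
    thr <- vapply(seq_len(nrow(fish)), function(i) {
      threshold_concentration(fish$wet_mass_g[i],
                              winter_by_env(fish$environment[i],
                                            fish$lake_id[i]))
    }, numeric(1))
    outcomes <- fish |>
      mutate(lipid_conc = conc,
             outcome = ifelse(conc >= thr, "survive", "starve"))
    frac <- outcomes |>
      group_by(.data$lake_id, .data$strain, .data$environment) |>
      summarise(winter_frac = mean(.data$outcome == "survive"),
                removals = n(), .groups = "drop")
    cells <- scenario_cells(scenario)
    cells <- cells[cells$year == min(cells$year), ]
    truth <- cells |>
      select("lake_id", "strain", "environment", "n_stocked",
             "winterkill") |>
      left_join(frac, by = c("lake_id", "strain", "environment")) |>
      mutate(
        n_fall = round(.data$n_stocked * scenario$survival$growing_season) -
          .data$removals,
        true_n = ifelse(.data$winterkill, 0L,
                        round(pmax(.data$n_fall, 0) * .data$winter_frac)),
        n0_effective = .data$n_stocked - .data$removals
      )
    list(outcomes = outcomes, spring_truth = truth)
  })
}

#' Generate a two-sample mark-recapture census
#'
#' Marking and the second sample are independent binomial draws on the true
#' abundance; the marked count in the second sample is hypergeometric. When
#' fyke effort and a true catchability are supplied, fyke-net recaptures
#' (the activity measure) are an additional binomial draw on the marked
#' fish with per-fish capture probability `q_true * fyke_effort`.
#'
#' @param truth Tibble with `lake_id`, `strain`, `environment`, `true_n`,
#'   `n0_effective`, and optionally `winterkill`.
#' @param p_mark,p_capture First- and second-sample capture probabilities.
#' @param fyke_effort Optional fyke effort, net-nights.
#' @param q_true Optional named vector of true catchability per environment.
#' @param seed Integer seed.
#' @return A count table with `M`, `C`, `R`, `N0` (the effective number at
#'   risk) and, when requested, `F` and `R_fyke`.
#' @export
generate_markrecapture <- function(truth, p_mark, p_capture,
                                   fyke_effort = NULL, q_true = NULL,
                                   seed = 1) {
  withr::with_seed(seed, {
    n <- nrow(truth)
    M <- rbinom(n, truth$true_n, p_mark)
    C <- rbinom(n, truth$true_n, p_capture)
    R <- rhyper(n, m = M, n = truth$true_n - M, k = C)
    out <- truth |>
      mutate(M = M, C = C, R = R, N0 = .data$n0_effective)
    if (!is.null(fyke_effort)) {
      out$F <- fyke_effort
      out$R_fyke <- rbinom(n, M, pmin(q_true[truth$environment] *
                                        fyke_effort, 1))
    }
    out
  })
}

#' Simulate the full lake experiment
#'
#' Runs every generator in sequence from one top-level seed: temperatures,
#' cohorts and stocking, lipid samples, winter outcomes, the spring
#' mark-recapture census (overwinter survival), and the fall census with
#' fyke-net catchability (growing-season survival and activity).
#'
#' @param scenario A scenario configuration (default [default_scenario()]).
#' @param seed Integer seed; fixed seed reproduces the experiment exactly.
#' @param temperatures Set `FALSE` to skip logger-series generation (the
#'   slowest part) when only the biological tables are needed.
#' @return A list with elements `scenario`, `temperatures`, `fish`,
#'   `stocking`, `truth`, `lipids`, `winter`, `counts_spring`,
#'   `counts_fall`.
#' @export
simulate_experiment <- function(scenario = default_scenario(), seed = 1,
                                temperatures = TRUE) {
  seeds <- derive_seeds(seed, 5)
  cohort <- generate_cohort(scenario, seeds[1])
  lipids <- generate_lipids(scenario, cohort, seeds[2])
  winter <- generate_winter_outcomes(scenario, cohort, seeds[3])
  counts_spring <- generate_markrecapture(
    winter$spring_truth,
    p_mark = scenario$capture$spring_p_mark,
    p_capture = scenario$capture$spring_p_capture,
    seed = seeds[4])
  fall_cells <- scenario_cells(scenario)
  fall_cells <- fall_cells[fall_cells$year == max(fall_cells$year), ]
  fall_truth <- fall_cells |>
    mutate(true_n = round(.data$n_stocked *
                            scenario$survival$growing_season),
           n0_effective = .data$n_stocked) |>
    select("lake_id", "strain", "environment", "true_n", "n0_effective")
  counts_fall <- generate_markrecapture(
    fall_truth,
    p_mark = scenario$capture$fall_p_mark,
    p_capture = scenario$capture$fall_p_capture,
    fyke_effort = scenario$capture$fyke_effort,
    q_true = scenario$capture$q_true,
    seed = seeds[5])
  temps <- if (temperatures) generate_temperatures(scenario, seeds[1])
  list(scenario = scenario, temperatures = temps, fish = cohort$fish,
       stocking = cohort$stocking, truth = cohort$truth, lipids = lipids,
       winter = winter, counts_spring = counts_spring,
       counts_fall = counts_fall)
}
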
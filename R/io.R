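#' CSV schemas used by the package
#'
#' Named column specifications for the tabular inputs: `temperature`
#' (logger records), `fish` (individual fall captures), `stocking`
#' (stocking events), `counts` (mark-recapture tallies), `lipid`
#' (extraction records). Each schema lists required columns, their readr
#' types, and row-level validity rules enforced by [read_table()].
#'
#' @return A named list of schema definitions.
#' @export
table_schemas <- function() {
  list(
    temperature = list(
      cols = readr::cols(lake_id = "c", timestamp = "D", depth_m = "d",
                         temp_c = "d"),
      rules = list(
        "temp_c within [-5, 40]" = function(d) {
          d$temp_c >= -5 & d$temp_c <= 40
        }
      )
    ),
    fish = list(
      cols = readr::cols(fish_id = "c", lake_id = "c", year = "i",
                         strain = "c", fork_length_mm = "d",
                         wet_mass_g = "d", capture_date = "D", gear = "c"),
      rules = list(
        "wet_mass_g > 0" = function(d) d$wet_mass_g > 0,
        "fork_length_mm > 0" = function(d) d$fork_length_mm > 0
      )
    ),
    stocking = list(
      cols = readr::cols(lake_id = "c", year = "i", strain = "c",
                         mean_mass_g = "d", n_stocked = "i", date = "D",
                         density_per_ha = "d"),
      rules = list(
        "mean_mass_g > 0" = function(d) d$mean_mass_g > 0,
        "n_stocked > 0" = function(d) d$n_stocked > 0
      )
    ),
    counts = list(
      cols = readr::cols(lake_id = "c", strain = "c", M = "i", C = "i",
                         R = "i", N0 = "i"),
      rules = list(
        "0 <= R <= min(M, C)" = function(d) {
          d$R >= 0 & d$R <= pmin(d$M, d$C)
        },
        "N0 > 0" = function(d) d$N0 > 0
      )
    ),
    lipid = list(
      cols = readr::cols(sample_id = "c", lake_id = "c", year = "i",
                         strain = "c", fish_a_length_mm = "d",
                         fish_b_length_mm = "d", combined_wet_mass_g = "d",
                         combined_dry_mass_g = "d", dry_aliquot_g = "d",
                         extracted_lipid_g = "d"),
      rules = list(
        "length-matched within 2 mm" = function(d) {
          abs(d$fish_a_length_mm - d$fish_b_length_mm) <= 2
        },
        "extracted lipid below aliquot mass" = function(d) {
          d$extracted_lipid_g < d$dry_aliquot_g
        }
      )
    )
  )
}

#' Read and validate a CSV input
#'
#' Reads a CSV against one of the package schemas, coercing columns to their
#' declared types. A missing required column is an immediate error naming
#' the column; rows violating the schema's validity rules are an error
#' listing the first 10 offending line numbers.
#'
#' @param path Path to a CSV file.
#' @param schema Schema name; one of `names(table_schemas())`.
#' @return A validated tibble.
#' @export
read_table <- function(path, schema) {
  schemas <- table_schemas()
  if (!schema %in% names(schemas)) {
    abort_input("unknown schema `%s`; available: %s", schema,
                paste(names(schemas), collapse = ", "))
  }
  if (!file.exists(path)) abort_input("file not found: %s", path)
  sc <- schemas[[schema]]
  required <- names(sc$cols$cols)
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  missing_cols <- setdiff(required, header)
  if (length(missing_cols)) {
    abort_input("%s: missing required column(s): %s", basename(path),
                paste(missing_cols, collapse = ", "))
  }
  d <- readr::read_csv(path, col_types = sc$cols, show_col_types = FALSE)
  bad <- integer(0)
  msgs <- character(0)
  for (rule in names(sc$rules)) {
    ok <- sc$rules[[rule]](d)
    ok[is.na(ok)] <- FALSE
    if (!all(ok)) {
      rows <- which(!ok)
      bad <- union(bad, rows)
      msgs <- c(msgs, sprintf("%s (rows %s)", rule,
                              paste(head(rows + 1L, 10), collapse = ", ")))
    }
  }
  if (length(bad)) {
    abort_input("%s: %d invalid row(s):\n  %s", basename(path), length(bad),
                paste(msgs, collapse = "\n  "))
  }
  d
}

# Assemble a simulated-experiment-shaped list from schema CSVs on disk.
# Environments come from the scenario's lake table; winter outcomes are
# reconstructed by classifying the lipid samples against the environment's
# winter parameters.
load_experiment <- function(input_dir, scenario) {
  p <- function(f) file.path(input_dir, f)
  temps <- read_table(p("temperature.csv"), "temperature")
  fish <- read_table(p("fish.csv"), "fish")
  stocking <- read_table(p("stocking.csv"), "stocking")
  lipids <- read_table(p("lipid.csv"), "lipid")
  counts_spring <- read_table(p("counts_spring.csv"), "counts")
  counts_fall <- read_table(p("counts_fall.csv"), "counts")
  env_of <- function(lake_id) {
    i <- match(lake_id, scenario$lakes$lake_id)
    if (anyNA(i)) {
      abort_input("lake `%s` not in the scenario lake table",
                  lake_id[which(is.na(i))[1]])
    }
    scenario$lakes$environment[i]
  }
  add_env <- function(d) {
    if (!"environment" %in% names(d)) d$environment <- env_of(d$lake_id)
    d
  }
  fish <- add_env(fish)
  lipids <- add_env(lipids)
  lipids$lipid_conc_wet <- lipid_concentration_wet(
    lipids$extracted_lipid_g, lipids$dry_aliquot_g,
    lipids$combined_dry_mass_g, lipids$combined_wet_mass_g)
  counts_spring <- add_env(counts_spring)
  counts_fall <- add_env(counts_fall)
  if (!"winterkill" %in% names(counts_spring)) {
    counts_spring$winterkill <- FALSE
  }
  mass <- lipids$combined_wet_mass_g / 2
  ice <- scenario$lakes$ice_days[match(lipids$lake_id,
                                       scenario$lakes$lake_id)]
  thr <- vapply(seq_along(mass), function(i) {
    pr <- scenario$winter_params
    pr$winter_days <- ice[i]
    threshold_concentration(mass[i], pr)
  }, numeric(1))
  outcomes <- lipids |>
    mutate(wet_mass_g = mass,
           outcome = ifelse(.data$lipid_conc_wet >= thr,
                            "survive", "starve"))
  list(scenario = scenario, temperatures = temps, fish = fish,
       stocking = stocking, lipids = lipids,
       winter = list(outcomes = outcomes),
       counts_spring = counts_spring, counts_fall = counts_fall)
}

#' Run the full analysis pipeline and write a report directory
#'
#' Generates (or loads) a complete experiment and runs every analysis stage
#' in order: thermal summaries and degree days, the per-fish growth table,
#' mark-recapture estimates, the lipid allometry, starvation-threshold
#' classification, and the strain/environment effect tests. Writes tidy
#' CSVs plus a JSON manifest (seed, package version, parameter digest,
#' input hashes, exclusions) sufficient to reproduce every table.
#'
#' @param output_dir Directory to create and fill.
#' @param scenario Scenario configuration for synthetic input (ignored when
#'   `input_dir` is given).
#' @param seed Integer seed governing all randomness.
#' @param input_dir Optional directory of schema-conforming CSVs
#'   (`temperature.csv`, `fish.csv`, `stocking.csv`, `counts_spring.csv`,
#'   `counts_fall.csv`, `lipid.csv`) to analyze instead of simulating.
#' @return Invisibly, a named list of the written file paths.
#' @export
run_report <- function(output_dir, scenario = default_scenario(), seed = 1,
                       input_dir = NULL) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- if (is.null(input_dir)) "simulate" else "load"
  result <- tryCatch({
    sim <- if (is.null(input_dir)) {
      simulate_experiment(scenario, seed)
    } else {
      load_experiment(input_dir, scenario)
    }

    stage <- "thermal"
    lake_years <- distinct(sim$fish[c("lake_id", "year")])
    thermal <- bind_rows(lapply(seq_len(nrow(lake_years)), function(i) {
      li <- lake_years[i, ]
      series <- sim$temperatures[sim$temperatures$lake_id == li$lake_id, ]
      st <- sim$stocking$date[sim$stocking$lake_id == li$lake_id &
                                sim$stocking$year == li$year][1]
      en <- max(sim$fish$capture_date[sim$fish$lake_id == li$lake_id &
                                        sim$fish$year == li$year])
      tibble(lake_id = li$lake_id, year = li$year,
             mean_temp_c = growing_season_mean(series, st, en),
             ice_days = ice_cover_duration(series),
             days = as.numeric(en - st),
             gdd = growing_degree_days(as.numeric(en - st),
                                       growing_season_mean(series, st, en)))
    }))

    stage <- "growth"
    growth <- growth_table(sim$fish, sim$stocking,
                           thermal[c("lake_id", "year", "mean_temp_c")])

    stage <- "mark_recapture"
    est_spring <- estimate_table(sim$counts_spring)
    est_fall <- estimate_table(sim$counts_fall)

    stage <- "lipid"
    allometry <- mass_lipid_regression(sim$lipids)

    stage <- "energetics"
    curves <- threshold_family(scenario$winter_params)
    classification <- sim$winter$outcomes |>
      group_by(.data$lake_id, .data$strain, .data$environment) |>
      summarise(n = n(),
                predicted_survive = sum(.data$outcome == "survive"),
                .groups = "drop")

    stage <- "inference"
    surv_data <- filter(est_spring, !.data$winterkill)
    effects <- bind_rows(
      fit_effect_model(surv_data, "survival", unit = "lake") |>
        mutate(response = "overwinter_survival"),
      fit_effect_model(est_fall, "survival", unit = "lake") |>
        mutate(response = "growing_season_survival"),
      fit_effect_model(est_fall, "q", unit = "lake") |>
        mutate(response = "catchability"),
      fit_effect_model(growth, "msgr_day", unit = "fish"),
      fit_effect_model(growth, "msgr_gdd", unit = "fish"),
      lipid_ancova(sim$lipids)
    )

    list(sim = sim, thermal = thermal, growth = growth,
         est_spring = est_spring, est_fall = est_fall,
         allometry = allometry, curves = curves,
         classification = classification, effects = effects)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage `%s`: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  paths <- list()
  wr <- function(tab, name) {
    p <- file.path(output_dir, paste0(name, ".csv"))
    readr::write_csv(tab, p)
    paths[[name]] <<- p
  }
  wr(result$thermal, "gdd_table")
  wr(result$growth, "growth_table")
  wr(bind_rows(mutate(result$est_spring, census = "spring"),
               mutate(result$est_fall, census = "fall")), "estimates")
  wr(result$allometry, "lipid_allometry")
  wr(result$curves, "threshold_curves")
  wr(result$classification, "threshold_classification")
  wr(result$effects, "effects")

  manifest <- list(
    seed = seed,
    package = "icebound",
    version = as.character(utils::packageVersion("icebound")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    excluded_winterkill_lakes = unique(
      result$est_spring$lake_id[result$est_spring$winterkill]),
    scenario_digest = unname(tools::md5sum(
      local({
        f <- tempfile()
        saveRDS(scenario, f, version = 2)
        f
      }))),
    outputs = lapply(paths, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  mp <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  paths$manifest <- mp
  invisible(paths)
}
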
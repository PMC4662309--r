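#' Mass-specific growth rate per calendar day
#'
#' \deqn{MSGR = \frac{W_2 - W_1}{0.5 (W_1 + W_2) \, days} \times 100\%}
#' where \eqn{W_1} is the strain mean mass at stocking and \eqn{W_2} the
#' individual mass at capture. Negative rates are legitimate: the stocking
#' mass is a batch mean while fall mass is individual, so fish below the
#' batch mean show negative apparent growth.
#'
#' @param w1 Mass at stocking, g (> 0). Typically the strain-year batch mean.
#' @param w2 Mass at capture, g (> 0).
#' @param days Calendar days between stocking and capture (> 0).
#' @return Growth rate in % body weight per day. Vectorized.
#' @export
#' @examples
#' msgr_per_day(0.85, 2.00, 42)
msgr_per_day <- function(w1, w2, days) {
  check_number(w1, "w1"); check_number(w2, "w2"); check_number(days, "days")
  if (any(w1 <= 0) || any(w2 <= 0)) abort_input("masses must be positive")
  if (any(days <= 0)) abort_input("`days` must be positive")
  (w2 - w1) / (0.5 * (w1 + w2) * days) * 100
}

#' Mass-specific growth rate per growing degree day
#'
#' Same formula as [msgr_per_day()] with growing degree days in the
#' denominator, removing the thermal-opportunity difference between
#' environments. Because gdd <= calendar days below the optimum temperature,
#' per-gdd rates are at least as large in magnitude as per-day rates.
#'
#' @param w1,w2 Masses, g (> 0).
#' @param gdd Growing degree days over the span (> 0); see
#'   [growing_degree_days()].
#' @return Growth rate in % body weight per gdd. Vectorized.
#' @export
msgr_per_gdd <- function(w1, w2, gdd) {
  check_number(gdd, "gdd")
  if (any(gdd <= 0)) abort_input("`gdd` must be positive")
  msgr_per_day(w1, w2, gdd)
}

#' Per-fish growth table
#'
#' Joins individual fall captures to their strain-year stocking event and the
#' lake-year thermal summary, and computes growth per calendar day and per
#' growing degree day. `W1` is always the batch mean for the strain-year;
#' days run from the stocking date to each fish's own capture date.
#'
#' @param fish Tibble of fish records: `fish_id`, `lake_id`, `year`, `strain`,
#'   `wet_mass_g`, `capture_date` (Date).
#' @param stocking Tibble of stocking events: `lake_id`, `year`, `strain`,
#'   `mean_mass_g`, `date` (Date).
#' @param thermal Tibble of lake-year season summaries: `lake_id`, `year`,
#'   `mean_temp_c`.
#' @param model A [growth_temp_model()] used for the degree-day conversion.
#' @return A tibble with one row per fish: identifiers plus `days`, `gdd`,
#'   `msgr_day`, `msgr_gdd`.
#' @export
growth_table <- function(fish, stocking, thermal,
                         model = growth_temp_model()) {
  need <- c("fish_id", "lake_id", "year", "strain", "wet_mass_g",
            "capture_date")
  missing_cols <- setdiff(need, names(fish))
  if (length(missing_cols)) {
    abort_input("`fish` lacks columns: %s", paste(missing_cols, collapse = ", "))
  }
  key <- c("lake_id", "year", "strain")
  unmatched <- anti_join(distinct(fish[key]), stocking, by = key)
  if (nrow(unmatched)) {
    u <- unmatched[1, ]
    abort_input("no stocking event for lake %s, year %s, strain %s",
                u$lake_id, u$year, u$strain)
  }
  unmatched_t <- anti_join(distinct(fish[c("lake_id", "year")]), thermal,
                           by = c("lake_id", "year"))
  if (nrow(unmatched_t)) {
    u <- unmatched_t[1, ]
    abort_input("no thermal summary for lake %s, year %s", u$lake_id, u$year)
  }
  out <- fish |>
    left_join(stocking |>
                select("lake_id", "year", "strain", "mean_mass_g",
                       stock_date = "date"),
              by = key) |>
    left_join(thermal |> select("lake_id", "year", "mean_temp_c"),
              by = c("lake_id", "year"))
  out |>
    mutate(
      days = as.numeric(.data$capture_date - .data$stock_date),
      gdd = growing_degree_days(.data$days, .data$mean_temp_c, model),
      msgr_day = msgr_per_day(.data$mean_mass_g, .data$wet_mass_g, .data$days),
      msgr_gdd = msgr_per_gdd(.data$mean_mass_g, .data$wet_mass_g, .data$gdd)
    ) |>
    select(-"stock_date")
}
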
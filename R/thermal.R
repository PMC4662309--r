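#' Quadratic growth--temperature model
#'
#' Mass-specific growth rate (MSGR, % body weight per day) of age-0 rainbow
#' trout as a quadratic function of water temperature,
#' \deqn{MSGR(t) = c_0 + c_1 t + c_2 t^2.}
#' The default coefficients come from published growth trials with age-0
#' rainbow trout, with an optimum temperature of 17.6 degrees C.
#'
#' The optimum is stored explicitly rather than recomputed from the vertex
#' \eqn{-c_1/(2 c_2)}: the default coefficients are rounded to two decimals
#' and their vertex (about 17.95 degrees C) disagrees slightly with the
#' published optimum. Both values are exposed; see [vertex_temperature()].
#'
#' @param c0 Intercept, % per day.
#' @param c1 Linear coefficient, % per day per degree C.
#' @param c2 Quadratic coefficient, % per day per degree C squared. Must be
#'   negative (growth declines away from the optimum).
#' @param t_opt Optimum temperature, degrees C. Growth at `t_opt` must be
#'   positive.
#' @return An object of class `growth_temp_model`.
#' @export
#' @examples
#' m <- growth_temp_model()
#' msgr_at_temp(m, 12.9)
growth_temp_model <- function(c0 = -2.85, c1 = 0.79, c2 = -0.022,
                              t_opt = 17.6) {
  check_number(c0, "c0"); check_number(c1, "c1")
  check_number(c2, "c2"); check_number(t_opt, "t_opt")
  if (c2 >= 0) abort_input("`c2` must be negative (concave growth curve)")
  m <- structure(list(c0 = c0, c1 = c1, c2 = c2, t_opt = t_opt),
                 class = "growth_temp_model")
  if (msgr_at_temp(m, t_opt) <= 0) {
    abort_input("growth at `t_opt` (%g) is not positive", t_opt)
  }
  m
}

#' @export
print.growth_temp_model <- function(x, ...) {
  cat(sprintf("MSGR(t) = %g + %g t %+g t^2  (%%/day; t in degrees C)\n",
              x$c0, x$c1, x$c2))
  cat(sprintf("optimum: %g C (stored), vertex: %.2f C\n",
              x$t_opt, vertex_temperature(x)))
  invisible(x)
}

#' Vertex of the growth--temperature quadratic
#'
#' The temperature maximizing the quadratic, \eqn{-c_1/(2 c_2)}. With the
#' default rounded coefficients this is about 17.95 degrees C, slightly above
#' the stored optimum of 17.6 degrees C.
#'
#' @param model A [growth_temp_model()].
#' @return Temperature in degrees C.
#' @export
vertex_temperature <- function(model) {
  -model$c1 / (2 * model$c2)
}

#' Predicted growth rate at a temperature
#'
#' @param model A [growth_temp_model()].
#' @param t Temperature(s), degrees C. Must be finite.
#' @return Predicted MSGR in % per day; may be negative below the growth
#'   threshold.
#' @export
msgr_at_temp <- function(model, t) {
  check_number(t, "t")
  model$c0 + model$c1 * t + model$c2 * t^2
}

#' Growing degree days
#'
#' Converts a span of calendar days at a mean growing-season temperature into
#' growing degree days (gdd): one gdd is a day of growth at the optimum
#' temperature, and colder days count fractionally,
#' \deqn{gdd = days \times MSGR(t) / MSGR(t_{opt}).}
#'
#' @param days Calendar days, >= 0.
#' @param mean_t Mean temperature over the span, degrees C.
#' @param model A [growth_temp_model()].
#' @return Growing degree days (dimensionless days). Vectorized over `days`
#'   and `mean_t`.
#' @export
#' @examples
#' growing_degree_days(42, 12.9) # 2008 low-elevation season
growing_degree_days <- function(days, mean_t, model = growth_temp_model()) {
  check_number(days, "days"); check_number(mean_t, "mean_t")
  if (any(days < 0)) abort_input("`days` must be >= 0")
  num <- msgr_at_temp(model, mean_t)
  if (any(num <= 0)) {
    abort_input("temperature below growth threshold: MSGR(%g) <= 0",
                mean_t[which(num <= 0)[1]])
  }
  days * num / msgr_at_temp(model, model$t_opt)
}

#' Construct a validated temperature-logger series
#'
#' @param lake_id Lake identifier (scalar).
#' @param timestamp `Date` or `POSIXct` vector, strictly increasing.
#' @param temp_c Temperatures, degrees C, finite and within \[-5, 40\].
#' @param depth_m Logger depth, metres (default 2, the deployment depth).
#' @return A tibble with columns `lake_id`, `timestamp`, `depth_m`, `temp_c`.
#' @export
temperature_series <- function(lake_id, timestamp, temp_c, depth_m = 2) {
  if (!inherits(timestamp, c("Date", "POSIXct"))) {
    abort_input("`timestamp` must be Date or POSIXct")
  }
  check_number(temp_c, "temp_c")
  if (length(timestamp) != length(temp_c)) {
    abort_input("`timestamp` and `temp_c` lengths differ")
  }
  if (any(diff(as.numeric(timestamp)) <= 0)) {
    abort_input("timestamps must be strictly increasing")
  }
  if (any(temp_c < -5 | temp_c > 40)) {
    abort_input("temperatures outside [-5, 40] C look like logger faults")
  }
  tibble(lake_id = lake_id, timestamp = timestamp,
         depth_m = depth_m, temp_c = temp_c)
}

#' Mean temperature over a growing-season window
#'
#' Arithmetic mean of logger readings between `start` and `end` (inclusive).
#'
#' @param series A temperature series tibble (see [temperature_series()]).
#' @param start,end Window bounds (`Date` or `POSIXct`).
#' @return Mean temperature, degrees C.
#' @export
growing_season_mean <- function(series, start, end) {
  keep <- series$timestamp >= start & series$timestamp <= end
  if (!any(keep)) {
    abort_input("no readings between %s and %s", format(start), format(end))
  }
  mean(series$temp_c[keep])
}

#' Bridge short gaps in a logger record
#'
#' Loggers are sometimes lost (vandalism) leaving holes in the record. Gaps up
#' to `max_gap_days` are bridged by linear interpolation at the series'
#' median sampling interval; longer gaps are left untouched and flagged.
#'
#' @param series A temperature series tibble.
#' @param max_gap_days Longest gap to interpolate across, days (default 14).
#' @return The series with interpolated readings inserted, plus an attribute
#'   `unfilled_gaps` (tibble of gaps too long to bridge).
#' @export
fill_logger_gaps <- function(series, max_gap_days = 14) {
  ts <- as.numeric(series$timestamp)
  step <- median(diff(ts))
  gaps <- which(diff(ts) > 1.5 * step)
  long <- tibble(start = series$timestamp[integer(0)],
                 end = series$timestamp[integer(0)])
  day <- if (inherits(series$timestamp, "Date")) 1 else 86400
  out <- series
  for (g in gaps) {
    span_days <- (ts[g + 1] - ts[g]) / day
    if (span_days > max_gap_days) {
      long <- bind_rows(long, tibble(start = series$timestamp[g],
                                     end = series$timestamp[g + 1]))
      next
    }
    t_new <- seq(ts[g] + step, ts[g + 1] - step / 2, by = step)
    if (length(t_new) == 0) next
    add <- series[rep(g, length(t_new)), ]
    # Date + numeric and POSIXct + numeric both advance by the native unit
    add$timestamp <- series$timestamp[1] + (t_new - ts[1])
    add$temp_c <- approx(ts, series$temp_c, xout = t_new)$y
    out <- bind_rows(out, add)
  }
  out <- arrange(out, .data$timestamp)
  attr(out, "unfilled_gaps") <- long
  out
}

#' Ice-cover duration from a logger series
#'
#' Detects ice cover as the longest contiguous run of readings at or below
#' `freeze_threshold` that is sustained for at least `min_run` days. At the
#' 2 m deployment depth, water under ice sits near 0-1 degrees C, so a 1 C
#' threshold with a 7-day persistence requirement separates winter ice cover
#' from brief cold snaps.
#'
#' @param series A temperature series tibble.
#' @param freeze_threshold Temperature at or below which the lake is treated
#'   as ice-covered, degrees C (default 1.0).
#' @param min_run Minimum persistence for a run to count as ice, days
#'   (default 7).
#' @return Duration of the longest qualifying run, days. Returns 0 with a
#'   warning when no run qualifies.
#' @export
ice_cover_duration <- function(series, freeze_threshold = 1.0, min_run = 7) {
  cold <- series$temp_c <= freeze_threshold
  if (!any(cold)) {
    warning("no readings at or below the freeze threshold; returning 0 days")
    return(0)
  }
  ts <- as.numeric(series$timestamp)
  day <- if (inherits(series$timestamp, "Date")) 1 else 86400
  step <- median(diff(ts)) / day
  r <- rle(cold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  durations <- vapply(which(r$values), function(i) {
    (ts[ends[i]] - ts[starts[i]]) / day + step
  }, numeric(1))
  durations <- durations[durations >= min_run]
  if (length(durations) == 0) {
    warning("no cold run sustained for `min_run` days; returning 0 days")
    return(0)
  }
  max(durations)
}
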
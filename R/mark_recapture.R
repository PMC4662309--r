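#' Chapman-corrected Petersen abundance estimate
#'
#' Two-sample mark-recapture estimator
#' \deqn{\hat N = \frac{(M+1)(C+1)}{R+1} - 1,}
#' where `M` fish were marked in the first sample, `C` captured in the
#' second, and `R` of those carried marks. The Chapman correction makes the
#' estimator nearly unbiased once the expected number of recaptures exceeds
#' about 7.
#'
#' @param M Number marked in the first sample.
#' @param C Number captured in the second sample.
#' @param R Number of marked fish among `C`. Must satisfy
#'   `0 <= R <= min(M, C)`.
#' @return The abundance estimate (not rounded). Vectorized.
#' @export
#' @examples
#' petersen_estimate(M = 1099, C = 2377, R = 303)
petersen_estimate <- function(M, C, R) {
  check_number(M, "M"); check_number(C, "C"); check_number(R, "R")
  if (any(R < 0)) abort_input("`R` must be >= 0")
  if (any(R > pmin(M, C))) {
    abort_input("`R` cannot exceed min(M, C)")
  }
  if (any(M == 0 | C == 0)) {
    warning("M or C is zero; estimate reduces to (M+1)(C+1)-1")
  }
  (M + 1) * (C + 1) / (R + 1) - 1
}

#' Survival proportion from an abundance estimate
#'
#' \eqn{\hat S = \hat N / N_0}, where \eqn{N_0} is the number initially
#' stocked (less any prior removals, e.g. fall lethal sampling). Estimates
#' above 1 are possible through estimator noise and are reported as-is with a
#' warning, never clamped.
#'
#' @param n_hat Abundance estimate, e.g. from [petersen_estimate()].
#' @param n0 Number at risk (> 0).
#' @return Survival proportion. Vectorized.
#' @export
survival_proportion <- function(n_hat, n0) {
  check_number(n_hat, "n_hat"); check_number(n0, "n0")
  if (any(n0 <= 0)) abort_input("`n0` must be positive")
  s <- n_hat / n0
  if (any(s > 1)) {
    warning("survival estimate above 1 (estimator noise); reported unclamped")
  }
  s
}

#' Catchability from fyke-net recaptures
#'
#' Ricker's effort model \eqn{R/F = qM} gives the catchability coefficient
#' \eqn{q = R / (F M)} per net-night per marked fish. Because fyke nets are
#' passive and unbaited, capture requires fish movement, so `q` doubles as a
#' foraging-activity proxy.
#'
#' @param R Marked fish recaptured in fyke nets.
#' @param F_effort Fyke-net effort, net-nights (> 0).
#' @param M Marked fish at large (> 0).
#' @return Catchability per net-night. Vectorized.
#' @export
catchability <- function(R, F_effort, M) {
  check_number(R, "R"); check_number(F_effort, "F_effort"); check_number(M, "M")
  if (any(F_effort <= 0)) abort_input("`F_effort` must be positive")
  if (any(M <= 0)) abort_input("`M` must be positive")
  R / (F_effort * M)
}

#' Bootstrap interval for a Petersen estimate
#'
#' Percentile interval from parametric resampling of the recapture count:
#' \eqn{R^* \sim} Hypergeometric(\eqn{\hat N} rounded, `M`, `C`), each
#' resample re-estimated with the Chapman formula. When `n0` is supplied the
#' survival proportion is resampled alongside.
#'
#' @param M,C,R Counts as in [petersen_estimate()].
#' @param n0 Optional number at risk for a survival interval.
#' @param n_boot Number of resamples (>= 100).
#' @param conf Coverage (default 0.95).
#' @param seed Optional integer seed; fixed seed gives identical intervals.
#' @return A tibble with rows `n_hat` (and `survival` when `n0` is given):
#'   `estimate`, `lower`, `upper`.
#' @export
petersen_boot_ci <- function(M, C, R, n0 = NULL, n_boot = 1000, conf = 0.95,
                             seed = NULL) {
  if (n_boot < 100) abort_input("`n_boot` must be >= 100")
  n_hat <- petersen_estimate(M, C, R)
  n_round <- max(round(n_hat), M + C - R)
  if (M <= 0 || C <= 0) abort_input("degenerate counts: M and C must be > 0")
  draw <- function() {
    r_star <- rhyper(n_boot, m = M, n = n_round - M, k = C)
    petersen_estimate(M, C, r_star)
  }
  boots <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  alpha <- (1 - conf) / 2
  qs <- quantile(boots, c(alpha, 1 - alpha), names = FALSE)
  out <- tibble(quantity = "n_hat", estimate = n_hat,
                lower = qs[1], upper = qs[2])
  if (!is.null(n0)) {
    out <- bind_rows(out, tibble(quantity = "survival",
                                 estimate = n_hat / n0,
                                 lower = qs[1] / n0, upper = qs[2] / n0))
  }
  out
}

#' Lake-by-strain estimate table
#'
#' Applies the Chapman-Petersen estimator, survival proportion, and (when
#' fyke effort is present) catchability to a tidy count table. Lakes flagged
#' `winterkill = TRUE` (whole-lake anoxic loss, a different mortality
#' mechanism than starvation) are excluded from the survival rows.
#'
#' @param counts Tibble with columns `lake_id`, `strain`, `M`, `C`, `R`,
#'   `N0`, and optionally `F` (fyke effort, net-nights), `R_fyke` (fyke-only
#'   recaptures), `removals` (fish removed before the winter at risk,
#'   default 0) and `winterkill` (logical exclusion flag).
#' @return The table with `n_hat`, `survival`, and `q` columns appended;
#'   winterkill rows keep `n_hat` but have `NA` survival.
#' @export
estimate_table <- function(counts) {
  need <- c("lake_id", "strain", "M", "C", "R", "N0")
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols)) {
    abort_input("`counts` lacks columns: %s",
                paste(missing_cols, collapse = ", "))
  }
  removals <- if ("removals" %in% names(counts)) counts$removals else 0
  wk <- if ("winterkill" %in% names(counts)) counts$winterkill else
    rep(FALSE, nrow(counts))
  out <- counts |>
    mutate(
      n_hat = petersen_estimate(.data$M, .data$C, .data$R),
      survival = ifelse(wk, NA_real_,
                        survival_proportion(.data$n_hat,
                                            .data$N0 - removals))
    )
  r_act <- if ("R_fyke" %in% names(counts)) counts$R_fyke else counts$R
  if ("F" %in% names(counts)) {
    ok <- counts$F > 0 & counts$M > 0
    out$q <- NA_real_
    out$q[ok] <- catchability(r_act[ok], counts$F[ok], counts$M[ok])
  }
  out
}
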
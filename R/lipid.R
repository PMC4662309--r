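#' Pair length-matched fish for lipid extraction
#'
#' Lipid extraction needs about 0.5 g of dry tissue, more than one juvenile
#' provides, so samples are pairs of length-matched fish (within a
#' tolerance, 2 mm by default). Pairs are drawn by stratified random
#' sampling over fork length so that the pairs span the size range of each
#' lake-year-strain group; pairing never crosses group boundaries.
#'
#' @param fish Tibble with `fish_id`, `lake_id`, `year`, `strain`,
#'   `fork_length_mm` (and any carried columns such as `wet_mass_g`).
#' @param n_pairs Pairs requested per lake-year-strain group.
#' @param tolerance_mm Maximum fork-length difference within a pair
#'   (default 2).
#' @param n_strata Equal-width length strata per group (default 5).
#' @param seed Optional integer seed for reproducible draws.
#' @return A tibble, one row per pair: group keys, `stratum`,
#'   `fish_a_id`, `fish_b_id`, `fish_a_length_mm`, `fish_b_length_mm`, and
#'   (when `wet_mass_g` is present) `combined_wet_mass_g`. Strata without a
#'   valid pair are skipped with a warning.
#' @export
pair_fish_for_lipid <- function(fish, n_pairs = 25, tolerance_mm = 2,
                                n_strata = 5, seed = NULL) {
  run <- function() {
    groups <- split(fish, interaction(fish$lake_id, fish$year, fish$strain,
                                      drop = TRUE))
    bind_rows(lapply(groups, function(g) {
      pair_group(g, n_pairs, tolerance_mm, n_strata)
    }))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# pair within one lake-year-strain group: enumerate the disjoint
# length-adjacent pairs available in each stratum, take an even allocation,
# then top up any shortfall from strata with spare pairs
pair_group <- function(g, n_pairs, tolerance_mm, n_strata) {
  if (nrow(g) < 2) {
    warning(sprintf("group %s/%s/%s has < 2 fish; skipped",
                    g$lake_id[1], g$year[1], g$strain[1]))
    return(NULL)
  }
  rng <- range(g$fork_length_mm)
  # small groups cannot support the full stratification
  n_strata <- max(1L, min(n_strata, floor(nrow(g) / 4)))
  breaks <- seq(rng[1], rng[2], length.out = n_strata + 1)
  if (rng[1] == rng[2]) breaks <- c(rng[1] - 0.5, rng[2] + 0.5)
  stratum <- cut(g$fork_length_mm, breaks, include.lowest = TRUE,
                 labels = FALSE)
  ord <- order(g$fork_length_mm, runif(nrow(g)))
  g <- g[ord, ]
  stratum <- stratum[ord]
  # disjoint length-adjacent candidate pairs per stratum, as row indices
  avail <- lapply(seq_len(n_strata), function(s) {
    idx <- which(stratum == s)
    a <- integer(0)
    i <- 1
    while (i < length(idx)) {
      if (abs(g$fork_length_mm[idx[i + 1]] - g$fork_length_mm[idx[i]]) <=
          tolerance_mm) {
        a <- c(a, i)
        i <- i + 2
      } else {
        i <- i + 1
      }
    }
    cbind(idx[a], idx[a + 1])
  })
  capacity <- vapply(avail, nrow, integer(1))
  for (s in which(capacity == 0)) {
    warning(sprintf(
      "no length-matched pair in stratum %d of group %s/%s/%s",
      s, g$lake_id[1], g$year[1], g$strain[1]))
  }
  if (all(capacity == 0)) return(NULL)
  take <- pmin(diff(round(seq(0, n_pairs, length.out = n_strata + 1))),
               capacity)
  while (sum(take) < n_pairs && any(capacity > take)) {
    s <- which.max(capacity - take)
    take[s] <- take[s] + 1
  }
  sel <- do.call(rbind, lapply(which(take > 0), function(s) {
    keep <- sample.int(capacity[s], take[s])
    cbind(avail[[s]][keep, , drop = FALSE], s)
  }))
  a <- g[sel[, 1], ]
  b <- g[sel[, 2], ]
  out <- tibble(lake_id = a$lake_id, year = a$year, strain = a$strain,
                stratum = sel[, 3],
                fish_a_id = a$fish_id, fish_b_id = b$fish_id,
                fish_a_length_mm = a$fork_length_mm,
                fish_b_length_mm = b$fork_length_mm)
  if ("wet_mass_g" %in% names(g)) {
    out$combined_wet_mass_g <- a$wet_mass_g + b$wet_mass_g
  }
  if ("environment" %in% names(g)) out$environment <- a$environment
  out
}

#' Wet-mass-basis lipid concentration
#'
#' The extraction protocol weighs the lipid recovered from a fixed dry
#' aliquot (0.5 g), i.e. lipid per gram of dry tissue; multiplying by the
#' sample's own dry-to-wet ratio converts to the per-wet-gram basis used in
#' the allometry:
#' \deqn{L = \frac{lipid}{aliquot} \times \frac{dry}{wet}.}
#'
#' @param extracted_lipid_g Lipid mass recovered from the aliquot, g.
#' @param dry_aliquot_g Dry-tissue aliquot mass, g (default 0.5, > 0).
#' @param combined_dry_mass_g Whole-sample dry mass, g.
#' @param combined_wet_mass_g Whole-sample wet mass, g.
#' @return Lipid concentration, g per g wet mass. Vectorized.
#' @export
lipid_concentration_wet <- function(extracted_lipid_g, dry_aliquot_g = 0.5,
                                    combined_dry_mass_g,
                                    combined_wet_mass_g) {
  check_number(extracted_lipid_g, "extracted_lipid_g")
  if (any(dry_aliquot_g <= 0)) abort_input("`dry_aliquot_g` must be positive")
  if (any(combined_dry_mass_g <= 0) || any(combined_wet_mass_g <= 0)) {
    abort_input("sample masses must be positive")
  }
  (extracted_lipid_g / dry_aliquot_g) *
    (combined_dry_mass_g / combined_wet_mass_g)
}

#' Log-log mass--lipid allometry
#'
#' Ordinary least-squares fit of log lipid concentration on log wet mass,
#' per group (e.g. per environment). The per-fish mass is taken as half the
#' combined pair mass. Slopes compared across environments summarize the
#' size-by-environment interaction: a shallower high-elevation slope means
#' small fish carry relatively more, and large fish relatively less, lipid
#' at high elevation.
#'
#' @param samples Tibble with `combined_wet_mass_g` and `lipid_conc_wet`
#'   (or the raw extraction columns, from which the concentration is
#'   computed), plus the grouping column.
#' @param grouping Name of the grouping column (default `"environment"`).
#' @return A tibble per group: `n`, `intercept`, `slope`, `slope_se`,
#'   `slope_lo`, `slope_hi` (95% CI).
#' @export
mass_lipid_regression <- function(samples, grouping = "environment") {
  if (!grouping %in% names(samples)) {
    abort_input("grouping column `%s` not found", grouping)
  }
  if (!"lipid_conc_wet" %in% names(samples)) {
    samples$lipid_conc_wet <- lipid_concentration_wet(
      samples$extracted_lipid_g, samples$dry_aliquot_g,
      samples$combined_dry_mass_g, samples$combined_wet_mass_g)
  }
  groups <- split(samples, samples[[grouping]])
  bind_rows(lapply(names(groups), function(nm) {
    g <- groups[[nm]]
    if (nrow(g) < 3) {
      abort_input("group `%s` has fewer than 3 samples", nm)
    }
    x <- log(g$combined_wet_mass_g / 2)
    if (stats::var(x) < .Machine$double.eps) {
      abort_input("group `%s` has no mass variation", nm)
    }
    fit <- lm(log(g$lipid_conc_wet) ~ x)
    ci <- confint(fit)["x", ]
    res <- tibble(group = nm, n = nrow(g),
                  intercept = coef(fit)[[1]], slope = coef(fit)[[2]],
                  slope_se = sqrt(diag(vcov(fit)))[[2]],
                  slope_lo = ci[[1]], slope_hi = ci[[2]])
    names(res)[1] <- grouping
    res
  }))
}
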
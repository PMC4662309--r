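#' Strain-by-environment effect tests
#'
#' Tests environment, strain, and their interaction on a response, using the
#' error stratum appropriate to each effect's unit of replication — the
#' classical decomposition of degrees of freedom for the nested design.
#'
#' Lake-level responses (survival and catchability proportions, one value
#' per lake-by-strain cell in a single year) are tested by ordinary ANOVA
#' with the lake-by-strain residual as the error term; proportions are
#' analyzed untransformed, treating values between 0 and 1 as approximately
#' normal (a `logit` option exists). Fish-level responses (growth, lipid)
#' are fit as a split-plot: year and lake-within-year are random strata,
#' environment (constant within a lake) is tested against the
#' lake-within-year stratum, and strain and strain-by-environment (varying
#' within lakes) against the strain-by-lake stratum. Strain-stratum cell
#' means are inverse-variance weighted (within-cell variance pooled per
#' environment-year) because degree-day scaling makes sampling variance
#' differ between thermal regimes; under homogeneous variance the weights
#' are near-constant and the classical unweighted test is recovered. With
#' data from a single year the year stratum is dropped with a warning.
#'
#' @param data Tibble with columns `environment`, `strain`, the response,
#'   and for fish-level fits `year` and `lake_id`.
#' @param response Name of the response column.
#' @param unit `"lake"` (one row per lake-by-strain) or `"fish"`
#'   (individual rows, nested design).
#' @param logit If `TRUE`, logit-transform a proportion response before
#'   testing (default `FALSE`, the untransformed convention).
#' @return An effect table: `response`, `effect`, `numDF`, `denDF`, `F`,
#'   `P`. Attribute `note` records any dropped random term. No
#'   multiple-testing correction is applied.
#' @export
#' @examples
#' d <- expand.grid(lake_id = c("a", "b", "c", "d"),
#'                  strain = c("BW", "PN"))
#' d$environment <- ifelse(d$lake_id %in% c("a", "b"), "low", "high")
#' d$survival <- runif(8)
#' fit_effect_model(d, "survival", unit = "lake")
fit_effect_model <- function(data, response, unit = c("lake", "fish"),
                             logit = FALSE) {
  unit <- match.arg(unit)
  need <- c("environment", "strain", response,
            if (unit == "fish") c("year", "lake_id") else "lake_id")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort_input("`data` lacks columns: %s",
                paste(missing_cols, collapse = ", "))
  }
  data <- as.data.frame(data)
  y <- data[[response]]
  if (logit) {
    if (any(y <= 0 | y >= 1)) {
      abort_input("logit transform needs responses strictly inside (0, 1)")
    }
    y <- log(y / (1 - y))
  }
  data$.y <- y
  for (v in intersect(c("environment", "strain", "year", "lake_id"),
                      names(data))) {
    data[[v]] <- factor(data[[v]])
  }
  if (unit == "lake") {
    fit <- lm(.y ~ environment * strain, data = data)
    tab <- anova(fit)
    den <- tab["Residuals", "Df"]
    out <- tibble(
      response = response,
      effect = c("Environment", "Strain", "Env.-by-strain"),
      numDF = tab[c("environment", "strain", "environment:strain"), "Df"],
      denDF = den,
      F = tab[c("environment", "strain", "environment:strain"), "F value"],
      P = tab[c("environment", "strain", "environment:strain"), "Pr(>F)"]
    )
    attr(out, "note") <- "lake-level ANOVA; no random terms"
    return(out)
  }
  out <- split_plot_anova(data, response)
  out[match(c("Environment", "Strain", "Env.-by-strain"), out$effect), ]
}

# Classical split-plot decomposition shared by the growth and lipid
# analyses. Effects are tested in the stratum where they are replicated:
#   lake-year means            -> environment (residual: lakes within years)
#   lake-year-strain cell means-> strain, strain-by-environment
#                                 (residual: strain-by-lake variation)
#   individual residuals       -> covariate terms, cell factor absorbed
# Cell means enter the coarser strata unweighted, the standard approximation
# for near-balanced designs.
split_plot_anova <- function(data, response, within_terms = character(0)) {
  note <- NULL
  multi_year <- nlevels(data$year) > 1
  if (!multi_year) {
    note <- "single year: year random term dropped"
    warning(note)
  }
  data$cell <- interaction(data$year, data$lake_id, data$strain,
                           drop = TRUE)
  data$lake_year <- interaction(data$year, data$lake_id, drop = TRUE)

  # covariate designs: factor effects are tested on cell means adjusted to
  # the grand-mean covariate value, using the within-cell slope of the
  # fish's own environment (the model carries a size-by-environment
  # interaction, so each environment owns its slope); the covariate itself
  # keeps its individual-level df
  data$.y_adj <- data$.y
  if (length(within_terms)) {
    centre <- mean(data$log_mass)
    for (e in levels(data$environment)) {
      idx <- data$environment == e
      b_e <- coef(lm(.y ~ cell + log_mass,
                     data = data[idx, , drop = FALSE]))[["log_mass"]]
      data$.y_adj[idx] <- data$.y[idx] - b_e * (data$log_mass[idx] - centre)
    }
  }

  cells <- data |>
    group_by(.data$cell, .data$lake_year, .data$year, .data$strain,
             .data$environment) |>
    summarise(m = mean(.data$.y_adj), v = stats::var(.data$.y_adj),
              n = n(), .groups = "drop")
  # sampling variance of a cell mean differs between thermal regimes
  # (degree-day scaling changes both the response scale and its spread), so
  # strain-stratum cells are weighted by n over the within-cell variance
  # pooled across each environment-year; under homogeneity the weights are
  # near-constant and the classical unweighted test is recovered
  pooled <- cells |>
    group_by(.data$year, .data$environment) |>
    summarise(v_pool = sum(.data$v * (.data$n - 1)) /
                max(sum(.data$n - 1), 1), .groups = "drop")
  cells <- left_join(cells, pooled, by = c("year", "environment"))
  cells$w <- cells$n / cells$v_pool
  if (any(!is.finite(cells$w))) cells$w <- rep(1, nrow(cells))
  ly <- cells |>
    group_by(.data$lake_year, .data$year, .data$environment) |>
    summarise(m = mean(.data$m), .groups = "drop")

  grab <- function(fit, terms, stratum_labels) {
    tab <- anova(fit)
    rn <- trimws(rownames(tab))
    res <- match("Residuals", rn)
    bind_rows(lapply(terms, function(tm) {
      i <- match(tm, rn)
      if (is.na(i)) return(NULL)
      tibble(response = response, effect = unname(stratum_labels[tm]),
             numDF = tab$Df[i], denDF = tab$Df[res],
             F = tab$`F value`[i], P = tab$`Pr(>F)`[i])
    }))
  }

  env_fit <- if (multi_year) {
    lm(m ~ year + environment, data = ly)
  } else {
    lm(m ~ environment, data = ly)
  }
  env_rows <- grab(env_fit, "environment",
                   c(environment = "Environment"))

  strain_fit <- lm(m ~ lake_year + strain + strain:environment,
                   data = cells, weights = w)
  strain_rows <- grab(strain_fit, c("strain", "strain:environment"),
                      c(strain = "Strain",
                        "strain:environment" = "Env.-by-strain"))

  within_rows <- NULL
  if (length(within_terms)) {
    fml <- stats::as.formula(paste(".y ~ cell +",
                                   paste(within_terms, collapse = " + ")))
    within_fit <- lm(fml, data = data)
    # anova() canonicalizes interaction labels to first-appearance order
    pretty <- c(log_mass = "Size", "log_mass:strain" = "Size-by-strain",
                "log_mass:environment" = "Size-by-env.",
                "log_mass:strain:environment" = "Size-by-strain-by-env.",
                "log_mass:environment:strain" = "Size-by-strain-by-env.")
    tab_terms <- trimws(rownames(anova(within_fit)))
    within_rows <- grab(within_fit, intersect(tab_terms, names(pretty)),
                        pretty)
  }

  out <- bind_rows(env_rows, strain_rows, within_rows)
  attr(out, "note") <- note
  out
}

#' Lipid allometry ANCOVA
#'
#' Mixed ANCOVA of log lipid concentration with log wet mass ("size") as a
#' covariate: fixed effects size, environment, strain, and all their
#' interactions; random year and lake-within-year strata as in
#' [fit_effect_model()]. Size and its interactions vary between individual
#' samples, so they are tested against the within-cell residual; the
#' environment and strain main effects and their interaction are tested in
#' the lake and strain-by-lake strata.
#'
#' @param data Tibble with `year`, `lake_id`, `environment`, `strain`, and
#'   either `log_mass` + `log_conc` or `combined_wet_mass_g` +
#'   `lipid_conc_wet` (per-fish mass is half the pair mass).
#' @return An effect table (`response`, `effect`, `numDF`, `denDF`, `F`,
#'   `P`) with rows Size, Environment, Strain, Size-by-strain, Size-by-env.,
#'   Env.-by-strain, Size-by-strain-by-env.
#' @export
lipid_ancova <- function(data) {
  data <- as.data.frame(data)
  if (!"log_mass" %in% names(data)) {
    data$log_mass <- log(data$combined_wet_mass_g / 2)
  }
  if (!"log_conc" %in% names(data)) {
    data$log_conc <- log(data$lipid_conc_wet)
  }
  for (v in c("environment", "strain", "year", "lake_id")) {
    data[[v]] <- factor(data[[v]])
  }
  data$.y <- data$log_conc
  out <- split_plot_anova(
    data, "log_conc",
    within_terms = c("log_mass", "log_mass:strain", "log_mass:environment",
                     "log_mass:environment:strain"))
  ord <- c("Size", "Environment", "Strain", "Size-by-strain",
           "Size-by-env.", "Env.-by-strain", "Size-by-strain-by-env.")
  out[match(ord, out$effect), ]
}

#' Reaction norms across environments
#'
#' Per-strain means in each environment plus the interaction contrast
#' \eqn{(\bar y_{s_1,high} - \bar y_{s_1,low}) - (\bar y_{s_2,high} -
#' \bar y_{s_2,low})}. Parallel norms (contrast near 0) indicate additive
#' strain and environment effects; a nonzero contrast is
#' genotype-by-environment interaction.
#'
#' @param data Tibble with `strain`, `environment`, and the response.
#' @param response Name of the response column.
#' @return A list: `means` (tibble strain x environment), `contrast`
#'   (named scalar; sign follows the strain sort order).
#' @export
reaction_norms <- function(data, response) {
  cells <- data |>
    group_by(.data$strain, .data$environment) |>
    summarise(mean = mean(.data[[response]]), n = n(), .groups = "drop")
  strains <- sort(unique(cells$strain))
  envs <- sort(unique(cells$environment))
  if (length(strains) != 2 || length(envs) != 2 || nrow(cells) != 4) {
    abort_input("need both strains observed in both environments")
  }
  get <- function(s, e) cells$mean[cells$strain == s & cells$environment == e]
  contrast <- (get(strains[1], envs[2]) - get(strains[1], envs[1])) -
    (get(strains[2], envs[2]) - get(strains[2], envs[1]))
  names(contrast) <- sprintf("(%s) vs (%s), %s - %s", strains[1], strains[2],
                             envs[2], envs[1])
  list(means = cells, contrast = contrast)
}
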
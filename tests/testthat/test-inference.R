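test_that("lake-level designs use the lake-by-strain residual df", {
  out3 <- fit_effect_model(lake_design(1, 2), "survival", unit = "lake")
  expect_equal(out3$denDF, rep(2, 3))
  out4 <- fit_effect_model(lake_design(2, 2), "survival", unit = "lake")
  expect_equal(out4$denDF, rep(4, 3))
  expect_equal(out3$effect, c("Environment", "Strain", "Env.-by-strain"))
  expect_true(all(out3$P >= 0 & out3$P <= 1))
})

test_that("fish-level split plot reproduces the classical denDF bookkeeping", {
  sim <- suppressWarnings(simulate_experiment(seed = 31,
                                              temperatures = FALSE))
  g <- growth_table(sim$fish, sim$stocking, season_thermal(sim))
  out <- fit_effect_model(g, "msgr_day", unit = "fish")
  # 9 lake-years in 2 years: environment residual 9 - 2 - 1 = 6;
  # 18 strain cells: strain residual 18 - 9 - 2 = 7
  expect_equal(out$denDF[out$effect == "Environment"], 6)
  expect_equal(out$denDF[out$effect == "Strain"], 7)
  expect_equal(out$denDF[out$effect == "Env.-by-strain"], 7)
})

test_that("effect magnitudes are invariant to strain relabeling", {
  sim <- suppressWarnings(simulate_experiment(seed = 32,
                                              temperatures = FALSE))
  g <- growth_table(sim$fish, sim$stocking, season_thermal(sim))
  out1 <- fit_effect_model(g, "msgr_gdd", unit = "fish")
  g2 <- dplyr::mutate(g, strain = ifelse(strain == "Pennask",
                                         "ZPennask", strain))
  out2 <- fit_effect_model(g2, "msgr_gdd", unit = "fish")
  expect_equal(out1$F, out2$F, tolerance = 1e-9)
  expect_equal(out1$P, out2$P, tolerance = 1e-9)
})

test_that("split-plot F agrees with an REML mixed-model fit", {
  skip_if_not_installed("nlme")
  sim <- suppressWarnings(simulate_experiment(seed = 33,
                                              temperatures = FALSE))
  g <- growth_table(sim$fish, sim$stocking, season_thermal(sim))
  ours <- fit_effect_model(g, "msgr_gdd", unit = "fish")
  d <- as.data.frame(g)
  d$year <- factor(d$year)
  d$regime <- interaction(d$year, d$environment)
  # the REML counterpart: nested random intercepts down to the
  # strain-in-lake level, residual variance free per thermal regime
  fit <- nlme::lme(msgr_gdd ~ environment * strain,
                   random = list(year = ~1, lake_id = ~1, strain = ~1),
                   weights = nlme::varIdent(form = ~1 | regime),
                   data = d, control = nlme::lmeControl(opt = "optim"))
  ref <- as.data.frame(nlme::anova.lme(fit))
  expect_equal(ours$denDF[ours$effect == "Environment"],
               ref["environment", "denDF"])
  expect_equal(ours$denDF[ours$effect == "Strain"],
               ref["strain", "denDF"])
  for (pair in list(c("Environment", "environment"),
                    c("Strain", "strain"),
                    c("Env.-by-strain", "environment:strain"))) {
    f1 <- ours$F[ours$effect == pair[1]]
    f2 <- ref[pair[2], "F-value"]
    expect_lt(abs(log(f1 / f2)), log(1.15))
  }
})

test_that("null lake-level designs give uniform P-values", {
  ps <- vapply(1:200, function(s) {
    fit_effect_model(lake_design(2, 2, seed = 5000 + s), "survival",
                     unit = "lake")$P[1]
  }, numeric(1))
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("lipid ANCOVA reports the published row layout", {
  sim <- suppressWarnings(simulate_experiment(seed = 34,
                                              temperatures = FALSE))
  out <- lipid_ancova(sim$lipids)
  expect_equal(out$effect,
               c("Size", "Environment", "Strain", "Size-by-strain",
                 "Size-by-env.", "Env.-by-strain",
                 "Size-by-strain-by-env."))
  n <- nrow(sim$lipids)
  cells <- nrow(dplyr::distinct(sim$lipids[c("lake_id", "year",
                                             "strain")]))
  expect_equal(out$denDF[out$effect == "Size"], n - cells - 4)
  expect_equal(out$denDF[out$effect == "Environment"], 6)
  expect_equal(out$denDF[out$effect == "Strain"], 7)
})

test_that("reaction norms expose the interaction contrast", {
  d <- expand.grid(strain = c("A", "B"), environment = c("low", "high"),
                   rep = 1:10, stringsAsFactors = FALSE)
  d$y <- 1
  rn <- reaction_norms(d, "y")
  expect_equal(unname(rn$contrast), 0)
  # additive effects: parallel norms
  d$y <- 2 + (d$strain == "A") * 0.5 + (d$environment == "high") * 1.5
  expect_equal(unname(reaction_norms(d, "y")$contrast), 0)
  # pure programmed interaction is returned exactly (no noise)
  d$y <- (d$strain == "A" & d$environment == "high") * 0.8
  expect_equal(abs(unname(reaction_norms(d, "y")$contrast)), 0.8)
  expect_error(reaction_norms(d[d$environment == "low", ], "y"),
               "both environments")
})

test_that("single-year fish-level data drop the year stratum with a note", {
  sim <- suppressWarnings(simulate_experiment(seed = 35,
                                              temperatures = FALSE))
  g <- growth_table(sim$fish, sim$stocking, season_thermal(sim))
  g08 <- dplyr::filter(g, year == 2008)
  expect_warning(out <- fit_effect_model(g08, "msgr_day", unit = "fish"),
                 "year random term dropped")
  # 5 lakes: environment residual 5 - 1 - 1 = 3; 10 cells: strain 10-5-2=3
  expect_equal(out$denDF[out$effect == "Environment"], 3)
  expect_equal(out$denDF[out$effect == "Strain"], 3)
})
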
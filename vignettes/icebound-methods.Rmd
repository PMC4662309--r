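---
title: "Overwinter bioenergetics of juvenile trout: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overwinter bioenergetics of juvenile trout: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icebound)
```

`icebound` analyses whole-lake common-environment experiments in which two
genetically distinct strains of juvenile (age-0) rainbow trout are stocked
into replicate lakes at low and high elevation, i.e. into short-winter and
long-winter environments. The package covers the full chain from raw
temperature-logger and fish records to strain-by-environment inference:
thermal summaries, growth standardization, mark–recapture survival,
activity (catchability), lipid allometry, starvation thresholds, and the
mixed ANOVA/ANCOVA layer that ties them together. A seeded synthetic-data
generator emulates the stocking design so every stage is testable without
field data.

## The bioenergetic frame

The organizing identity is the daily energy budget $C = G + M + W$:
consumption is partitioned into growth, metabolism, and waste
(`energy_budget()`). In winter, consumption effectively ceases while
metabolism continues, so the winter energy demand must be paid from stored
lipid. Everything in the package serves one of two questions: how do
strains and environments differ in what fish accumulate before winter
(growth, lipid), and does that accumulation cover the winter demand
(thresholds, survival)?

## Thermal standardization

Growth opportunity differs enormously between a 42-day, 12.9 °C season and
a 35-day, 9.8 °C one. The growth–temperature quadratic for age-0 rainbow
trout,

$$\mathrm{MSGR}(t) = -2.85 + 0.79\,t - 0.022\,t^2 \quad (\%/\mathrm{day}),$$

with optimum $t_{opt} = 17.6$ °C, converts calendar days to growing degree
days: $\mathrm{gdd} = \mathrm{days} \times \mathrm{MSGR}(\bar t) /
\mathrm{MSGR}(t_{opt})$. One gdd is a day of growth at the optimum; colder
days count fractionally.

```{r}
growing_degree_days(c(42, 35, 45, 38), c(12.9, 9.8, 15.1, 11.5))
```

Two numerical choices deserve note. First, the published coefficients are
rounded to two decimals, so recomputed degree days differ from the
published 36.9/23.4/43.5/30.3 by 1–2%; the package treats agreement to
2.5% as exact reproduction of this calculation. Second, the vertex of the
rounded quadratic sits at ≈17.95 °C rather than the published 17.6 °C;
`growth_temp_model()` therefore stores `t_opt` explicitly (default the
published value) and exposes the vertex via `vertex_temperature()` rather
than silently recomputing one from the other.

Ice phenology has no published detection rule, so the package uses a
sustained-cold-run heuristic: the ice-covered period is the longest
contiguous run of 2 m readings at or below 1.0 °C lasting at least 7 days
(`ice_cover_duration()`). Water under ice at 2 m sits near 0.5–1 °C, so
this cleanly separates ice cover from cold snaps; the defaults round-trip
the generator's 145- and 204-day winters to ±2 days and are insensitive to
subsampling the record. Logger gaps (vandalized loggers happen) up to 14
days are bridged by linear interpolation; longer gaps are flagged, not
guessed (`fill_logger_gaps()`).

## Growth

Mass-specific growth rate uses the mean-mass denominator

$$\mathrm{MSGR} = \frac{W_2 - W_1}{0.5\,(W_1 + W_2)\,\mathrm{days}}
\times 100\%,$$

where $W_1$ is the strain-year *batch mean* stocking mass (batches of >200
fish are weighed, not individuals) and $W_2$ the individual fall mass.
Because $W_1$ is a mean, individual MSGR can be negative; nothing clamps
it. `growth_table()` computes days from the stocking date to each fish's
own capture night (fall sampling spans five consecutive nights) and
divides by either calendar days or degree days.

## Mark–recapture, survival, and activity

Abundance uses the Chapman-corrected Petersen estimator
$\hat N = (M+1)(C+1)/(R+1) - 1$, which is nearly unbiased once the
expected number of recaptures exceeds about 7 — a property the test suite
verifies by simulation (mean relative bias < 5% at $N = 1000$). Survival
is $\hat S = \hat N / N_0$ with $N_0$ the number stocked minus fish
removed at fall sampling; values above 1 are reported with a warning,
never clamped. Lakes lost to anoxic winterkill (an all-or-nothing
mechanism distinct from starvation) carry an exclusion flag and are
dropped from survival inference but retained in the report manifest.

Catchability follows the effort model $R/F = qM$, using fyke-net
recaptures only: fyke nets are passive, so capture requires movement and
$q$ proxies foraging activity. `petersen_boot_ci()` provides percentile
intervals by resampling $R$ from its hypergeometric sampling distribution.

## Lipid storage and the allometry

Extraction chemistry reports lipid per 0.5 g dry aliquot; the wet-basis
concentration multiplies by the sample's own dry/wet ratio
(`lipid_concentration_wet()`). Samples are pairs of length-matched fish
(±2 mm) chosen by stratified random sampling over fork length; the
per-fish mass used on the allometry axis is half the combined pair mass.
The storage law is log–log linear: $\log L = a_e + b_e \log w$, fit per
environment by OLS (`mass_lipid_regression()`). A shallower high-elevation
slope is the size-by-environment signature: small fish at high elevation
carry relatively more lipid, large fish relatively less.

## Starvation thresholds and depletion

Winter respiration follows the mass–respiration relationship with
intercept 11.16623 (rainbow trout at 0 °C). The publication gives neither
its units nor the mass coefficient, so `metabolic_params()` treats
(intercept, mass coefficient, functional form, oxycalorific coefficient,
lipid energy density, winter days) as an explicit calibrated family:

* form: arithmetic-linear $R(w) = a + b\,w$ by default, per the source's
  wording ("linear relationship between mass and respiration rate"); a
  power law $a\,w^b$ is available since the underlying allometry is often
  fit log–log.
* the absolute scale is pinned by `calibrate_metabolic_params()`, which
  rescales the oxycalorific coefficient so a chosen curve passes through
  an anchor (mass, concentration) point. The bundled scenario anchors the
  multiplier-1, 204-day curve at (2 g, 0.030 g/g), placing the curve
  family inside the observed 0.009–0.045 g/g concentration envelope.
* every quantity the tests assert — curve orderings, duration ratios,
  survivor monotonicity — is a ratio and thus unit-free.

The threshold concentration is

$$L^*(w) = \frac{R(w;\,m\,a)\; D\; k}{\lambda\, w},$$

with winter duration $D$, oxycalorific coefficient $k$, lipid energy
density $\lambda$, and multiplier $m$ applied to the intercept only
(the published sensitivity analysis varies intercepts ±25% and ±50%).
$L^*$ is strictly decreasing in mass and proportional to $D$: the same
intrinsic metabolic rate demands 204/145 ≈ 1.41× more stored lipid per
gram at high elevation. `simulate_depletion()` walks a fasting fish
through winter at fixed structural mass (starvation is defined as lipid
exhaustion; protein catabolism is out of scope) and agrees with
`classify_overwinter()` everywhere except within one time step of the
threshold boundary — a cross-module consistency the acceptance tests
check on a random grid.

## Inference: the split-plot layer

Every response is tested for strain, environment, and strain-by-environment
effects. The design is a split plot: environment is a whole-lake treatment,
strains are crossed within lakes, lakes are nested in years. The package
implements the classical decomposition directly:

| stratum | tested there | denominator df (this design) |
|---|---|---|
| lake-year means | Environment | lake-years − years − 1 = 9 − 2 − 1 = 6 |
| lake-year-strain cell means | Strain, Env.×Strain | 18 − 9 − 2 = 7 |
| individuals (cell factor absorbed) | covariate terms | 466 − 18 − 4 = 444 |
| lake-level 2×2 (one year) | all three effects | 6 − 4 = 2 or 8 − 4 = 4 |

These reproduce the published integer denominator df for every analysis.
For the lipid ANCOVA the bookkeeping 466 − 18 − 4 = 444 resolves how 22 df
disappear between the 466 samples and the individual-level tests: the 18
strain-by-lake-year cells absorb the intercept and all pure factor
effects, and the four size-slope terms take one each. Survival and
catchability are proportions analysed untransformed with lake as the
replicate, values in (0,1) treated as approximately normal; a logit option
exists behind a flag. No multiple-testing correction is applied, matching
the original analysis convention.

Two numerical refinements matter for calibration:

* **Variance weighting.** Degree-day scaling changes both the level and
  the spread of per-fish growth between thermal regimes (within-cell SD
  differs up to ~6× between environment-years). Pooling such strain
  contrasts unweighted makes the 7-df interaction test anticonservative
  (≈8% at nominal 5% in simulation). Strain-stratum cell means are
  therefore weighted by $n_j / s^2_{(year, env)}$ with the variance pooled
  per environment-year; the simulated type-I rate returns to ≈5% in both
  heterogeneous and homogeneous settings, and the weights are essentially
  constant when variance is homogeneous. The environment test is left
  unweighted because shared between-lake variance dominates at that level.
* **Covariate adjustment.** In the lipid ANCOVA the factor strata are
  tested on cell means adjusted to the grand-mean log-mass using the
  within-cell slope of each cell's *own environment* (the model contains a
  size-by-environment interaction, so each environment owns a slope). A
  single pooled slope would leak the strain mass difference into the
  strain test whenever slopes differ between environments.

An independent cross-check: `nlme::lme` with nested random intercepts
(year/lake/strain) and a per-regime residual variance reproduces the same
denominator df and F statistics within a few percent on generator data.

## The synthetic scenario

`default_scenario()` encodes the realized design: five lake units in year
one (three low-, two high-elevation), four in year two (a barrier splits
one high lake into two units), stocking densities 2255 and 2800 fry/ha,
strain-specific stocking masses (0.75/0.85 g, then 0.66/0.65 g), seasons
of 42/35/45/38 days at 12.9/9.8/15.1/11.5 °C, and 145- vs 204-day winters.
Configured truths:

* growth: per-gdd baselines 3.2 (Blackwater) and 2.6 (Pennask) %/gdd, an
  additive +0.35 %/gdd at high elevation, lake-year deviates (SD 0.12),
  and lognormal individual mass variation (sdlog 0.2). The environment
  effect is additive on the per-gdd scale so the per-gdd interaction is
  null by construction. Individual variation is placed on fall mass, not
  on per-fish MSGR: the MSGR formula saturates at $2 \times 100/\mathrm{gdd}$,
  so inverting it per fish would map moderate rate draws into absurd
  masses; mass-level lognormal noise keeps the fall-mass spread
  right-skewed and inside the observed 0.3–7 g envelope.
* lipids: slopes 0.55 (low) and 0.35 (high) crossing at 2.4 g — near the
  grand-mean mass, so the size-adjusted environment effect is null — with
  6% lognormal measurement noise (the extraction's repeatability CV) and a
  dry/wet ratio of 0.25.
* winter: the calibrated parameter set above, applied per environment
  through each lake's ice duration. Two low-elevation lakes are flagged as
  winterkill losses, exercising the exclusion path and reducing the
  overwinter survival design to 3 lakes × 2 strains (denDF 2).
* capture: spring marking/capture probabilities 0.19/0.40 (mirroring the
  published clip totals), fall 0.29/0.30, fyke effort 25 net-nights, true
  catchability 8×10⁻⁴ (low) vs 2×10⁻³ (high) per net-night.

What the generator deliberately does *not* emulate: within-season growth
trajectories (only endpoint masses), gill-net size selectivity, emigration
or tag loss, temperature-dependent winter metabolism beyond the f(T)
scalar, and any spatial structure within lakes. Passing tests therefore
demonstrate that the analysis chain recovers known truths under the
design's sampling structure — not that these simplifications hold in real
lakes.

One emergent property is worth flagging: because winter survival is
threshold-driven and Blackwater fish grow larger, the generator induces a
strain difference in winter survival at high elevation even though no
strain survival effect is configured. That is the mechanism under study
behaving as designed, and it is why survival tests in the acceptance suite
check environmental direction rather than strain nulls.

Problem sizes were chosen to mirror the realized study (1124 + 1962
growth fish, 257 + 209 lipid pairs, mark–recapture counts in the published
range); type-I simulations use a lighter 36-fish-per-cell null scenario
with strain-neutral stocking masses, since strain-specific stocking mass
is itself a strain effect.

## Reproducibility

All randomness flows from one integer seed through per-module derived
streams; identical seeds give byte-identical tables. `run_report()` runs
the full chain (thermal → growth → mark–recapture → lipid → energetics →
inference), writes tidy CSVs, and records a JSON manifest with the seed,
package version, scenario digest, and per-file checksums — enough to
reproduce any table. Schema-validated readers (`read_table()`) make the
same pipeline runnable from on-disk CSVs in place of the generator.
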
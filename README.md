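# icebound

Bioenergetic trade-off analysis for juvenile rainbow trout
(*Oncorhynchus mykiss*) overwintering in seasonal lakes.

Populations spanning an elevation gradient face very different winters: at
high elevation a lake may be ice-covered for 204 days, at low elevation
for 145. Under ice, age-0 trout stop feeding and pay their metabolic bill
from stored lipid, so fall size and lipid concentration decide who sees
spring. `icebound` implements the full analysis chain for whole-lake
common-environment experiments that stock two strains into replicate lakes
at both elevations:

* **thermal** — ice-cover phenology from 2 m temperature loggers, and
  growing-degree-day (gdd) standardization via the age-0 growth quadratic
  MSGR(t) = −2.85 + 0.79 t − 0.022 t² (%/day, optimum 17.6 °C), with
  gdd = days × MSGR(t̄)/MSGR(t_opt);
* **growth** — mass-specific growth rate
  MSGR = (W₂ − W₁) / (0.5 (W₁ + W₂) days) × 100%, per calendar day and
  per gdd;
* **mark–recapture** — Chapman-corrected Petersen abundance
  N̂ = (M+1)(C+1)/(R+1) − 1, survival Ŝ = N̂/N₀, bootstrap intervals, and
  Ricker catchability q = R/(F·M) from fyke-net effort as an activity
  proxy;
* **lipid** — length-matched pair bookkeeping, wet-basis concentration
  from dry-aliquot extractions, and the log–log mass–lipid allometry;
* **energetics** — starvation-threshold curves
  L*(w) = R(w; m·a) · D · k / (λ·w) from the mass–respiration
  relationship (intercept 11.16623 at 0 °C, intercept multipliers
  0.5–1.5×), plus a winter lipid-depletion simulator;
* **inference** — split-plot ANOVA/ANCOVA for strain, environment, and
  strain-by-environment effects with classical denominator degrees of
  freedom (environment tested on lake-year means, strain terms on
  strain-by-lake cell means, covariates on individuals);
* **synthetic data** — a seeded generator reproducing the 2008–2009
  stocking design (5 lake units year one, 4 year two, 2255 and 2800
  fry/ha) so the entire pipeline runs and is tested without field data.

## Worked example

Degree days for the four environment-years (42/35/45/38 days at
12.9/9.8/15.1/11.5 °C):

```r
library(icebound)
growing_degree_days(c(42, 35, 45, 38), c(12.9, 9.8, 15.1, 11.5))
#> [1] 36.45882 22.94475 43.12645 29.80907
```

A short, warm season of 42 days is worth ≈36.5 days of growth at the
optimum temperature; the 35-day high-elevation season only ≈22.9.

A full synthetic experiment, spring survival estimates, and the
strain-by-environment test on degree-day-standardized growth:

```r
sim <- simulate_experiment(seed = 2026, temperatures = FALSE)

est <- estimate_table(sim$counts_spring)
dplyr::filter(est, !winterkill)
#>   lake_id strain         M     C     R  n_hat survival
#> 1 cigar   Blackwater   433   881   175 2174.   0.4818
#> 2 cigar   Pennask      388   837   163 1987.   0.4405
#> 3 pantano Blackwater    68   124    28  296.4  0.04961
#> 4 pantano Pennask       74   157    18  622.7  0.1042
#> 5 spook   Blackwater    58   112    25  255.4  0.07813
#> 6 spook   Pennask       40   109    14  299.7  0.09161
```

Overwinter survival collapses from ≈0.46 in the short-winter lake to
≈0.05–0.10 under the 204-day winters; two winterkill lakes are excluded
by flag.

```r
g <- growth_table(sim$fish, sim$stocking, thermal_summary)
fit_effect_model(g, "msgr_gdd", unit = "fish")
#>   response effect         numDF denDF        F        P
#> 1 msgr_gdd Environment        1     6   15.94   7.18e-3
#> 2 msgr_gdd Strain             1     7 3123.     1.54e-10
#> 3 msgr_gdd Env.-by-strain     1     7    0.0296 8.68e-1
```

The strain effect (Blackwater grows faster per degree day) is tested
against the strain-by-lake stratum with 7 denominator df, the environment
effect against lake-within-year with 6 — the classical split-plot
bookkeeping. The lipid allometry shows the size-by-environment signature
(shallower high-elevation slope):

```r
mass_lipid_regression(sim$lipids)
#>   environment     n intercept  slope slope_se slope_lo slope_hi
#> 1 high          208     -3.93 0.363   0.0156    0.332    0.393
#> 2 low           258     -4.09 0.540   0.0127    0.515    0.565
```

`run_report("out/", seed = 1)` runs every stage in order and writes tidy
CSVs plus a JSON manifest (seed, version, checksums, winterkill
exclusions).

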
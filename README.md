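# echinodrill

Quantitative analysis of drilling predation on Mesozoic–Cenozoic echinoids.

Cassid gastropods (helmet snails) prey on echinoids by drilling through the
test; the holes fossilize, and the proportion of individuals in a fossil
population bearing at least one predatory hole — the **drilling frequency**
— records predation intensity through deep time. This package is for
paleoecologists and macroevolution researchers who want to build and test
stage-binned drilling-frequency time series, locate intensification events,
and check the record for taphonomic bias, with every step scripted and
seeded.

## What it computes

* **Timescale binning** — a pinned chronostratigraphic chart (Aalenian →
  Holocene, 41 stages; Chattian base 28.1 Ma) with midpoint lookup, alias
  resolution and half-open age binning (`load_timescale`, `stage_midpoint`,
  `assign_bin`).
* **Data model and filters** — specimen / trace / population tables with
  validation; visibility filter (strictly > 50% of the test surface),
  population-size filter (≥ 10 individuals), summed four-region taphonomic
  grade, and predatory-vs-parasitic drill-hole classification (≥ 0.5 mm or
  minute-host exception, outline in the cassid set).
* **Frequency series** — per-stage means/medians of population drilling
  frequencies *f*, first differences Δ*f* between occupied bins, bootstrap
  sample-standardized means with 95% percentile intervals, and the
  incomplete-hole (failed attack) fraction.
* **Multi-phase intensification models** — the core inference. For every
  contiguous partition of the B occupied bins into k = 2 or 3 phases
  (B−1 resp. C(B−1, 2) models), a Monte Carlo ensemble resamples
  populations within bins, pools first differences by phase, and grows
  simulated trajectories; model fit is the inverse mean sum of squared
  deviations, 1 / ⟨SSQ⟩, against the observed series. Output: the full fit
  surface (heatmap data), the five best-fit models, interquartile
  prediction bands, and the best transition reported as stage names and
  midpoint ages (`enumerate_phase_models`, `simulate_phase_model`,
  `fit_all_models`, `best_fit_report`).
* **Changepoint dating of radiations** — exact exhaustive mean-shift
  segmentation of predator/prey richness series with a noise-scaled linear
  penalty; the first rising segment is reported as a radiation interval in
  Ma (`detect_changepoints`).
* **Taphonomic-bias partial correlations** — partial Pearson r of drilling
  frequency against mean taphonomic grade, sample age and sample size via
  the inverse-correlation-matrix construction, with t-transform p-values
  (`partial_correlation`).
* **Synthetic data with known truth** — a seeded generator emulating a
  museum-survey compilation: uneven stage sampling, beta-binomial
  overdispersion around a three-phase trajectory, grade-dependent
  drill-hole detection loss, rare incomplete holes, eulimid-type parasitic
  traces, and a literature subset biased toward highly drilled populations
  (`synth_config`, `generate_dataset`, `apply_literature_bias`,
  `generate_diversity_series`).
* **Pipeline** — `run_pipeline()` chains everything (both phase counts,
  EAT-only and combined sources), writing CSV/JSON results plus a manifest;
  reruns are byte-identical.

## Worked example

```r
library(echinodrill)

d    <- generate_dataset(synth_config(seed = 1))   # study-scale synthetic data
pops <- filter_populations(d$populations)          # >= 10 individuals
ser  <- bin_series(pops, d$timescale)
ser
#> Drilling-frequency series (raw; sources: EAT+LIT)
#> 41 occupied of 41 stage bins, 263 populations
#>         stage midpoint n_pops      mean_f    median_f occupied
#>      Aalenian   172.20      1 0.008968610 0.008968610     TRUE
#>      Bajocian   169.30      3 0.005637299 0.006578947     TRUE
#>     Bathonian   167.20      3 0.006227441 0.006024096     TRUE
#>     ...

incomplete_fraction(pops)
#> [1] 0.03497942

surf <- fit_all_models(pops, ser, k_phases = 3, n_iter = 1000, seed = 1)
best_fit_report(surf, d$timescale)
#> 3-phase best-fit model (chart ICS2013):
#>   transition Lutetian (44.5 Ma) -> Lutetian (44.5 Ma)
#>   fit score 1.989, trajectory r 0.96
```

Reading this: 263 populations (201 systematically surveyed, 62 from the
literature-bias model) span all 41 bins; about 3.5% of drill holes are
incomplete (failed attacks are rare, so attacks are usually lethal); the
best of the 780 candidate three-phase models places the start of the
intensification ramp at the Lutetian (midpoint 44.5 Ma) — matching the
generator's planted ramp start — while compressing its end into the same
stage. At realistic noise levels the transition *end* sits in a flat valley
of the fit surface and is the less reliable of the two boundaries, which is
why the report also carries the five best models and why the methods
vignette discusses this estimator property; under the strong-effect
verification scenario both boundaries are recovered reliably.

```r
eat <- pops[pops$source == "EAT", ]
eat$age_ma <- stage_midpoint(d$timescale, eat$stage)
partial_correlation(eat, "drilling_frequency",
                    c("mean_taph_grade", "age_ma", "n_individuals"))
#> Partial Pearson correlations with 'drilling_frequency' (n = 201)
#>        covariate r_partial  p_value
#>  mean_taph_grade     0.116 0.103000
#>           age_ma    -0.240 0.000639
#>    n_individuals     0.101 0.157000
```

Here age carries the dominant signal (older populations are less drilled —
the intensification itself); the grade effect planted by the generator's
detection-loss model is weak at study scale and, at this seed, not
resolvable, an honest illustration of how subtle taphonomic signals are at
n ≈ 200.

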
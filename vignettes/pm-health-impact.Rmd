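---
title: "Methods: particulate-matter health impact assessment with pmhia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: particulate-matter health impact assessment with pmhia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmhia)
```

## The problem

Routine PM10 monitoring networks in many regions run gravimetric
samplers on an intermittent schedule (one 24-h filter every third day),
with occasional invalid samples and no co-located PM2.5 monitor for
most of the record. Estimating the health burden attributable to
particulate exposure from such data requires four linked pieces of
methodology, each of which this package implements and tests in
isolation: exposure quality control, fine-fraction estimation,
concentration–response burden arithmetic, and short-term time-series
regression. A deterministic synthetic-data generator closes the loop by
providing data with known ground truth for every stage.

## Exposure QC

A daily record is valid when its sampling time lies in **[22 h, 24 h]**
(a nominal 23 ± 1 h tolerance band read as an inclusive window — 24 h
is the nominal sample, so the upper bound must be attainable), no
rejection flag is set (a rare nearby emission source, or a power outage
longer than 2 h during collection), and a nonnegative concentration was
reported. Sampling times above 24 h violate the record type itself and
are treated as data errors, not invalid samples.

An annual zone mean is valid with at least
`max(92, ceil(0.75 × n_scheduled))` valid samples. Under the default
1-in-3-day cadence `n_scheduled` is 122, so the floor and the 75 % rule
coincide at 92; the `max` guarantees the rule generalises to denser
cadences without ever dropping below the 92-sample floor. Invalid
zone-years are excluded from burden estimation by default (the
exclusion is logged in the run manifest and can be overridden by
configuration).

Zone-year means pool **all valid daily records in the zone** rather
than averaging station means. This is a package decision where
published practice is ambiguous: pooling weights stations by their
completeness, which is the right behaviour when station dropout is
uninformative; averaging station means would instead equalise stations
regardless of how many valid days each contributed. Daily exceedance
uses a strict `>` comparison ("exceeds" a reference value).

## PM2.5 from PM10 ratios

The monthly PM2.5/PM10 ratio is the **mean of daily quotients**, not
the ratio of monthly means — robust to uneven sampling inside the
month, and again a documented choice where either convention could be
defended. Pairs with PM2.5 > PM10 are physically inadmissible for a
mass fraction; they are excluded and counted, never silently used.

Measured ratios are combined with prior-study values by
**inverse-variance weighting** (combined variance `1/(1/v₁ + 1/v₂)`).
"Statistical weighting" of new against prior ratios is not otherwise
specified in the source literature; inverse-variance weighting is the
standard precision-weighted choice, it is exact under normality, and
its variance never exceeds the smaller input variance — a property the
tests assert. Degenerate inputs (sd = 0) are refused with a request for
an explicit variance floor rather than being given infinite weight.

Annual PM2.5 is the monthly-ratio-weighted mean,
`Σ_m mean_m × ratio_m × n_m / Σ_m n_m`, which is algebraically
identical to applying each month's ratio to every valid daily record;
with a single zone-level ratio it degenerates to `annual mean × ratio`.
Ratios fall back month → zone → global, with each fall-back logged.
Packaged zone ratios are 0.5 ± 0.3 (industrial) and 0.4 ± 0.2
(coastal, mountainous).

## Burden arithmetic

The attributable proportion over an exposure distribution with
categories *c* and population fractions *P(c)* is

$$AP = \frac{\sum_c (RR(c) - 1)\,P(c)}{\sum_c RR(c)\,P(c)},$$

with attributable incidence $IE = I \times AP$ and excess cases
$NE = IE \times N / 10^5$. Design choices:

* **Functional form.** Default `RR(c) = RR^{(c - c_0)/10}` — risk
  compounds per 10 µg/m³, the standard assumption behind published
  per-10-µg/m³ relative risks. A linear form
  `1 + (RR−1)(c−c₀)/10` is available by configuration; the two agree to
  first order in the excess risk (the gap is second order in RR−1, an
  asserted test property).
* **Cutoff semantics.** At or below the counterfactual cutoff
  (15 µg/m³ PM10, 5 µg/m³ PM2.5 — the WHO 2021 annual guidelines) the
  relative risk is exactly 1. No protective extrapolation.
* **CI propagation.** The low/central/high RR bounds are pushed through
  the whole AP → IE → NE chain; incidence and population are treated as
  fixed because they carry no published uncertainty.
* **Exposure distribution.** Default is a single category at the zone
  annual mean (what zone-year burden tables imply); a binned mode
  builds 10 µg/m³ categories from valid daily values.
* **Rounding.** Case counts and proportions are carried at full
  precision everywhere; percentages to one decimal and cases to
  integers appear only in the serialized report tables.
* **Population at risk.** Effective population is
  `count × representativeness`, the share of residents whose exposure
  the network represents (packaged values 58.1 % / 69.3 % / 63.8 % for
  the coastal/industrial/mountainous zones). Age selection is an
  explicit argument: the census age structure resolves to
  0–14 / 15–64 / 65+ bands (22.6 % / 68.3 % / 9.1 %), so "children"
  maps to the 0–14 band and "adults" to 15+, the closest available
  stand-ins for 0–4 and >18 target groups. The packaged per-zone
  population split (45/30/25 % of the 880,560 regional total) is
  synthetic — only the regional total is published — and is labelled as
  such in the fixture file.

Regional roll-up sums zone cases bound-by-bound (exact conservation is
a test invariant) and takes the effective-population-weighted mean of
zone proportions.

## Short-term time-series model

Daily deaths are modelled as
`log E[deaths_t] = α + β · PM_t + s(t)` with `s(t)` a **parametric
natural cubic spline** of the time index (knots at equally spaced
quantiles, columns centered). A penalized smoother would be the other
natural reading of "generalized additive"; the parametric spline GLM is
the standard form of time-series air-pollution models and keeps the
model fully explicit, so that is what is implemented. Fitting is by
IRLS for the log-link Poisson, with convergence declared when the
relative deviance change falls below 1e-8 within 100 iterations
(non-convergence is flagged on the result, never silent; a constant PM
series or rank-deficient basis is an error). Overdispersion is absorbed
by the Pearson dispersion `φ = Χ²/(n − p)`, inflating the Poisson SE by
`√φ`. The implementation is cross-checked in the tests against
`stats::glm` on identical designs (coefficients to 1e-6).

Spline degrees of freedom are selected by quasi-AIC,
`deviance/φ + 2p`, with `φ` estimated once from the richest candidate
model so candidates are compared on a common scale; ties break to the
smallest df. No residual-whiteness test participates in selection: the
homogeneity test mentioned in applied work of this kind is not
specified tightly enough to reimplement, so selection is by QAIC alone.

Effects are reported as `RR = exp(β × increment)` per interquartile
increase (or any stated increment) with Wald 95 % intervals (z = 1.96
throughout; daily series are long enough that small-sample t
corrections would be cosmetic). Zone estimates are pooled on the log
scale by **DerSimonian–Laird** random effects:
`τ² = max(0, (Q − (k−1)) / (Σw − Σw²/Σw))`, re-weighting by
`1/(se² + τ²)`. With τ² = 0 this is exactly fixed-effect
inverse-variance pooling, and with k = 1 the input is returned — both
asserted identities; the tests also cross-check against
`metafor::rma(method = "DL")`. Exposure is single-pollutant, same-day;
no lags and no meteorological confounders are modelled.

## Dust attribution

The annual dust contribution is the 12-month mean of the monthly
dust-PM2.5 series (non-episode months contribute zero); the relative
contribution divides by an **explicitly supplied** ambient annual mean.
Published relative dust increases are ambiguous about their denominator
(PM10 vs PM2.5 annual means), so the package never infers it. The dust
share of the burden compares two runs of the same burden configuration
with and without the dust increment removed from ambient PM2.5:
`100 × (NE_with − NE_without) / NE_with`. The default episode threshold
is 0 µg/m³ (any positive dust-PM2.5 counts as an episode);
reanalysis-derived episode masks can be supplied instead.

## The synthetic generator

What it emulates: three zones with mean PM10 of 28/38/30 µg/m³; one
annual sinusoid of relative amplitude 0.3 peaking on day-of-year 105
(mid-April, the midpoint of a February–July high season) so monthly
means peak in boreal spring and trough in November; multiplicative
lognormal noise with σ = 0.3 parameterised to mean one (so the
configured level is the analytic mean — lognormal because
concentrations are nonnegative and right-skewed); 1-in-3-day sampling;
10 % missingness; 2 % invalid samples (short runs or rejection flags);
June–August dust episodes of 1.1/0.8/0.7 µg/m³ dust-PM2.5 (inside the
published 0.7–1.6 µg/m³ range of such contributions); and daily deaths
drawn Poisson with `log μ = log 5 + 0.002·PM` (optional seasonality and
gamma-frailty overdispersion, both off by default so the recovery
studies are correctly specified). All draws flow from a mandatory
integer seed of the Mersenne–Twister generator with inversion sampling,
and a truth ledger records every scheduled day, its injected value and
its fate, so QC counts reconcile exactly.

What it does **not** emulate — and hence what passing tests do not
show about real data: spatial correlation between stations,
meteorology-driven dispersion, instrument drift, multi-pollutant
confounding, temperature–mortality interactions, and
informative missingness (drops are independent of concentration).

## Problem sizes and numerical tolerances

The test suite runs the slope-recovery study at 500 replicates of
1000-day series (the scale at which Monte-Carlo error on 95 % CI
coverage is about one percentage point), the QAIC selection studies at
40 replicates of 400–730 days, and the brute-force equivalence of the
attributable-proportion engine at 1000 random 1–20-category
distributions with agreement required to 1e-12. Exact identities
(roll-up conservation, point-mass AP, pooling reductions) are asserted
without tolerance. These sizes are the package's choices for tight,
reproducible statistical checks at interactive runtimes.

## Known limitations

* Attributable proportions assume a causal, confounder-free RR from
  external studies; transportability to the assessed population is the
  analyst's responsibility.
* The single-category default exposure distribution ignores
  within-zone exposure variability; the binned mode only partially
  addresses this (bins of observed station days, not of personal
  exposure).
* Ratio-based PM2.5 estimation inherits the measurement period of the
  ratios; historical ratios are assumed stationary.
* No cessation lag, life-table, or years-of-life-lost computation; no
  joint multi-pollutant effects; no distributed-lag short-term models.
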
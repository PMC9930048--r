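# pmhia

Health impact assessment for particulate matter (PM10 / PM2.5) from
routine monitoring data.

`pmhia` is for environmental-health analysts who have daily
filter-based PM10 records from a zoned monitoring network and need
defensible estimates of the mortality and morbidity burden attributable
to particulate exposure — the workflow popularised by WHO-style risk
assessment tools, implemented here as a scriptable, fully tested R
pipeline with explicit QC rules and uncertainty propagation.

## What it computes

**Long-term attributable burden.** Given a relative risk RR per
10 µg/m³ for a health endpoint, a counterfactual cutoff *c₀* (15 µg/m³
for PM10, 5 µg/m³ for PM2.5), and the population's exposure
distribution *P* over concentration categories, the attributable
proportion is

    AP = Σ (RR(c) − 1) · P(c) / Σ RR(c) · P(c)

with `RR(c) = RR^((c − c₀)/10)` (log-linear compounding; a linear form
is available) and RR(c) = 1 at or below the cutoff. The attributable
incidence and excess cases follow as

    IE = I · AP        NE = IE · N / 100 000

where *I* is the baseline incidence per 100 000 and *N* the effective
population at risk (count × monitoring representativeness). Confidence
intervals propagate the RR bounds through the whole chain; zone results
roll up to a region by summing cases bound-by-bound and
population-weighting the proportions.

**Exposure.** Daily 24-h samples pass QC when sampling time is within
22–24 h and no rejection flag is set; an annual zone mean is valid with
at least 92 valid samples (75 % of an every-third-day schedule). PM2.5
is estimated from PM10 through monthly PM2.5/PM10 ratios, optionally
combining measured ratios with prior-study values by inverse-variance
weighting.

**Short-term association.** Daily death counts are regressed on
same-day PM by quasi-Poisson IRLS with a natural-spline adjustment for
time (degrees of freedom chosen by quasi-AIC); results are expressed as
an RR per interquartile increase and pooled across zones with a
DerSimonian–Laird random-effects model.

**Dust attribution.** Monthly dust-PM2.5 series (e.g. reanalysis
estimates of Saharan transport) are apportioned into annual means and
into the share of the attributable burden due to dust.

**Synthetic data.** A deterministic generator reproduces the assumed
data structure — three zones (≈28/38/30 µg/m³), a February–July
seasonal peak, 1-in-3-day sampling, missingness, summer dust episodes,
log-linear PM–mortality counts — with a complete truth ledger, so the
entire pipeline is testable without confidential monitoring or
mortality records.

## Worked example

Annual industrial-zone PM10 of 44 µg/m³ (sd 14), lung-cancer mortality
with baseline incidence 4.91 per 100 000 adults:

```r
library(pmhia)
tabs <- fixture_tables()                       # packaged study configuration
lc   <- fixture_crf("lung cancer mortality", "PM2.5", tabs)
lc
#> CRF: lung cancer mortality [PM2.5], RR 1.1100 (1.0500-1.1800) per 10 ug/m3, cutoff 5 ug/m3, log_linear

ann <- data.frame(zone = "industrial", year = 2015, mean = 44, sd = 14,
                  n_valid = 103, n_scheduled = 122, is_valid = TRUE,
                  exceedance_fraction = 0.24)
est <- estimate_pm25_annual(ann, fixture_ratio_priors(tabs))
est$pm25
#> [1] 22                                       # 44 ug/m3 x industrial ratio 0.5

pop <- fixture_population("industrial", "adults", tabs)
b <- burden_with_ci(exposure_dist(est$pm25, 1), lc, 4.91, pop, year = 2015)
round_burden_report(b)
#>                endpoint       zone year            ap_pct   cases rate_per_100k
#> 1 lung cancer mortality industrial 2015 16.3% (8.0-24.5%) 1 (1-2)           0.8
```

Reading: 22 µg/m³ PM2.5 is 17 µg/m³ above the 5 µg/m³ counterfactual,
so RR = 1.11^1.7 ≈ 1.19 and AP = 16.3 % (95 % CI 8.0–24.5 %) of
lung-cancer deaths are attributable, about one excess death per year in
this zone's monitored adult population.

Pooling published zone mortality RRs (per-IQR, with their CIs):

```r
se <- (log(c(1.014, 1.022, 1.021)) - log(c(1.006, 1.015, 1.012))) / 3.92
pool_random_effects(log(c(1.0104, 1.0195, 1.0165)), se)
#> Pooled RR (random effects, k=3): 1.0155 (1.0100-1.0210), tau2 = 1.87e-05
```

A command-line wrapper ships in `inst/exec/pmhia`
(`simulate`, `qc`, `burden`, `tsrr`, `dust`, `run` subcommands).

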
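---
title: "Methods: dose, risk and hazard modelling in aquarisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose, risk and hazard modelling in aquarisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquarisk)
```

## Scope and assumptions

aquarisk implements the deterministic drinking-water branch of the US EPA
Superfund risk-assessment procedure: hazard identification (screening
against standards), dose-response (slope factors and reference doses taken
as fixed inputs, never estimated), exposure assessment (ingestion doses),
and risk characterisation (cancer risk, population burden, noncancer
hazard). The modelled pathway is oral ingestion of tap water only; dermal
and inhalation routes are out of scope, and gastrointestinal absorption is
taken as complete (absorption coefficients of 1), which together with the
maximal exposure-frequency default makes the assessment conservative —
it overestimates rather than underestimates dose.

The pipeline is a pure function of its inputs: identical monitoring
records, scenario and configuration reproduce every output byte for byte.

## From monitoring records to exposure-point concentrations

Raw records are per-sample determinations (site, date, analyte, ng/dm³)
with a below-LOQ flag. Aggregation is two-staged: a per-site arithmetic
mean per analyte, then the unweighted arithmetic mean of the per-site means
over the *supply* sites. The unweighted site mean (rather than a pooled
mean over all samples) treats each well as an equal contributor to the
blended supply regardless of sampling intensity; sampling cadence is
therefore metadata only, and irregular campaigns need no interpolation.
Sites flagged non-supply (the packaged study's river) are summarised but
excluded from exposure.

Below-LOQ values are kept *as reported* by default: trace determinations
carry real information and the doses they produce are negligible, whereas
substitution distorts sensitivity analyses. `zero` and `half_loq`
substitution policies are provided for exactly those sensitivity runs; for
a fixed record set the three policies order as
mean(zero) ≤ mean(half_loq) ≤ mean(as_reported) whenever reported censored
values are at least half the LOQ.

PCB congeners are totalled before any toxicology is applied, because the
available slope factor and reference dose describe the Aroclor-type
congener mixture, not individual congeners; the mixture travels through the
pipeline under the registry key `SUM-PCB`. Pesticides are assessed
individually. One consequence of computing from unrounded means: the PCB
class total evaluates to 451.95 ng/dm³, while summing the per-analyte
averages after rounding them to two decimals (as printed reference tables
do) gives 451.96 — the package never rounds intermediates, and all
downstream cells agree with four-significant-figure references within 0.1%.

## Doses

Both dose measures are the standard ingestion product

LADD or ADD = c̄·10⁻⁶ · FI · IR · EF · ED / (BW · AT) mg/(kg·day),

differing only in the averaging time AT. Defaults (all overridable through
`population_groups()`-shaped tibbles and `exposure_context()`):

| parameter | children 0–6 | children 7–17 | adults | units |
|---|---|---|---|---|
| N (group size) | 934 | 2,046 | 8,140 | persons |
| BW | 15 | 46 | 70 | kg |
| IR | 0.3 | 1.0 | 1.4 | dm³/day |
| ED | 6 | 11 | 30 | years |
| AT, carcinogenic | 25,550 | 25,550 | 25,550 | days |
| AT, noncarcinogenic | 2,190 | 4,015 | 10,950 | days |

FI = 0.65 (roughly 65% of consumed water is plain tap water, the rest
bottled), EF = 365 days/year. Adult ED is the EPA upper-bound residential
value of 30 years, not the 70-year lifetime; passing ED = 70 recovers the
lifetime variant. The noncarcinogenic AT always equals ED in days, so
ADD/LADD = AT_cancer/AT_noncancer exactly — an identity the test suite
checks algebraically.

### Averaging-time conventions

`exposure_context(convention = )` selects how carcinogenic doses are
averaged. `epa_lifetime` (default) divides by 25,550 days for every group,
per Superfund guidance. `duration_matched` instead sets AT equal to ED·365
for the groups listed in `duration_matched_groups` — the convention some
authors prefer when concentrations are approximately constant, which
inflates risks for short-exposure groups. The package parameterises the
matched set per group rather than globally because the packaged study's
alternative-convention headline (≈ 0.091 expected cases) is reproducible
only when the two children groups are duration-matched while adults keep
lifetime averaging; that reconstruction is a documented inference, not a
stated rule, so it is explicit in configuration rather than hard-coded.

## Cancer risk and population burden

The one-hit model ELCR = 1 − exp(−dose·CSF) is the default; the linear form
dose·CSF is valid below risk 0.01 and available as `linear`, with `auto`
switching between them at that threshold. Per-substance risks add
(`cumulative_risk()`), individual risks scale by group size into expected
extra cancer cases (`extra_cancer_cases()`), kept real-valued — an
expectation meaningful only for large populations — and classifications use
half-open bands with inclusive lower bounds: < 10⁻⁶ negligible, [10⁻⁶,
10⁻⁴) acceptable range, [10⁻⁴, 10⁻³) remediation desirable, ≥ 10⁻³
protective measures required.

### Slope-factor configurations

The registry stores per-analyte slope factors (PCB mixture 2.0, gamma-HCH
1.10, DDE 0.34, DDD 0.24, DDT 0.34 (mg/(kg·day))⁻¹). The packaged study's
printed risk tables, however, are consistent only with the PCB mixture
factor 2.0 applied to *all five* analytes — every printed ELCR equals twice
its LADD, including the pesticides. Which the study authors intended cannot
be determined from the text, so `risk_table()` exposes both as named
configurations: `table5` (per-analyte registry factors; the package
default, and the toxicologically defensible choice) and `as_published`
(uniform 2.0; reproduces the reference tables and is used by the acceptance
runs). Neither is silent: the configuration in force is recorded in the
report bundle's audit trail.

gamma-HCH carries no EPA carcinogen class (`unclassified`) but keeps its
slope factor and participates in risk computation regardless of class,
matching regulatory practice of using best-available potency values.

## Noncancer hazard

HQ = ADD/RfD against chronic reference doses, summed per group into HI.
The packaged RfDs are chronic values although the children's exposures are
subchronic; matching RfDs to exposure period would be preferable but no
subchronic values are available in the registry, so chronic RfDs are used
for all durations (conservative). Analytes lacking an RfD are excluded
from HQ and HI with a prominent warning rather than silently treated as
zero hazard.

## Synthetic campaign generator

`generate_campaign()` emulates the study design: repeated sampling at three
supply wells and one river, by default 10 fortnightly dates (a five-month
campaign; the study's methods and results sections disagree on weekly
versus fortnightly cadence, so cadence and the number of dates are
parameters, and 20 weekly dates is one flag away). Individual
determinations are log-normal — concentrations are nonnegative and
right-skewed — parameterised so the distribution's mean equals the target
per-site mean and its coefficient of variation equals `cv` (default 0.3, a
typical relative spread for repeated trace-level water analyses; the study
states no dispersion). `cv = 0` degenerates to constants at the target
means, which is the deterministic end-to-end reproduction path used by the
tests. Draws below the analyte's LOQ (1 ng/dm³, 5 ng/dm³ for DDE) are
flagged censored with the drawn value retained. Site cells reported absent
("–") and zero in the reference tables are treated identically as zero
target means — the generator emits the constant 0 there without drawing.

The generator does *not* emulate temporal autocorrelation, seasonality or
spatial transport (the study found no trends), nor analytical measurement
bias. Passing tests on synthetic campaigns therefore demonstrate the
correctness of the aggregation and risk arithmetic under the stated
statistical structure, not the behaviour of the pipeline under drifting or
correlated real-world concentrations.

## Numerical choices

- The one-hit expression is evaluated as `-expm1(-x)`: below x ≈ 10⁻⁸ the
  naive `1 - exp(-x)` loses the entire risk-gap to cancellation.
- Concentrations are converted ng/dm³ → mg/dm³ exactly once (factor 10⁻⁶);
  no intermediate is ever rounded. Reference cells printed to four
  significant figures are matched within 0.1–0.5% relative, the
  accumulation of their printed rounding.
- Classification bins are half-open with inclusive lower bounds; a measured
  concentration exactly equal to a standard complies (a maximum contaminant
  level is a maximum permitted value).
- The generator seeds a private RNG stream and restores the caller's
  `.Random.seed`, so campaigns are reproducible without side effects.
- Test problem sizes: deterministic checks run on single-date cv-0
  campaigns (68 records); Monte-Carlo checks of the generator use 5,000 to
  10,000 draws, sized so that three-standard-error bounds are decisive while
  the whole suite stays in seconds.

## Known limitations

- Single exposure pathway and single medium; no multi-route aggregation.
- Deterministic point estimates only: parameter uncertainty is handled by
  conservative inputs, not by probabilistic propagation.
- Slope factors and RfDs are treated as exact constants; no age-dependent
  adjustment factors or congener-specific TEF weighting.
- The population burden is a lifetime expectation over a static population;
  no demographic dynamics.
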
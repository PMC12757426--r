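---
title: "Disproportionality signal detection for spontaneous reports: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection for spontaneous reports: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous-report databases such as FAERS collect adverse-event reports
with no exposure denominator: we observe how often a drug-event pair is
*reported*, never how often the event *occurs* among users. Signal
detection therefore rests on disproportionality — comparing the observed
reporting frequency of a drug-event pair against the frequency expected if
drug and event were reported independently. `faersignal` implements the
full working pipeline for one focal drug: ingestion and cleaning of the
quarterly ASCII tables, case deduplication, primary-suspect selection,
2x2 contingency construction per MedDRA Preferred Term (PT) and System
Organ Class (SOC), four disproportionality statistics with conventional
positivity thresholds, serious/non-serious contingency testing,
demographic stratification, and time-to-onset modelling.

## Data model and cleaning rules

A *report* is the counting unit throughout. The cleaning stage applies
the field's standard conventions:

* **Units.** Age codes DEC/YR/MON/WK/DY/HR are converted to years
  (decade x 10, months / 12, weeks / 52.1775, days / 365.25,
  hours / 8766); weight codes KG/LBS/GMS to kilograms
  (lbs x 0.45359237, g / 1000). Values outside plausibility bounds
  (age 0–120 y, weight 1–500 kg) are set missing and counted.
* **Drug names** are uppercased, characters outside `[A-Z0-9 ]` removed,
  and whitespace collapsed, so `"Voquezna® (vonoprazan)"` becomes
  `"VOQUEZNA VONOPRAZAN"`. Target matching is by whitespace token, which
  captures salt forms (`"VONOPRAZAN FUMARATE"`); exact matching is
  available.
* **Deduplication.** FAERS cases accrue follow-up versions under one
  CASEID; per case only the record with the latest FDA_DT survives, ties
  broken by the largest PRIMARYID. Partial dates (YYYY, YYYYMM) are
  zero-padded *only* for this ordering; they are treated as missing for
  any interval arithmetic.
* **Seriousness** is derived from outcome codes: a report is serious iff
  it carries at least one of DE, LT, HO, DS, CA, RI; OT alone is
  non-serious. This is the standard FAERS reading of "death,
  life-threatening event, hospitalization, disability, or other severe
  consequence".
* **Weight imputation** runs only when fewer than 10% of weights are
  missing, filling each hole with the median of its (sex, age-band) cell.
  At realistic FAERS missingness (~80%) the rule never triggers; it
  exists for the low-missingness regime.

## The four disproportionality statistics

For a PT with 2x2 cells `a` (focal drug with event), `b`, `c`, `d` and
`N = a+b+c+d`, with `E = (a+b)(a+c)/N` the expected count under
independence:

* **ROR** `= ad/bc`, Woolf interval
  `exp(ln ROR ± 1.96 sqrt(1/a+1/b+1/c+1/d))`; positive when the point
  estimate is ≥ 3 and the CI lower bound exceeds 1 (the conventional
  a ≥ 3 rule is available instead). Any zero cell triggers the
  Haldane–Anscombe correction (+0.5 on all four cells), and such rows are
  flagged.
* **PRR** `= [a/(a+b)] / [c/(c+d)]` with the uncorrected Pearson
  chi-square of the same table; positive when PRR ≥ 2, chi-square ≥ 4 and
  a ≥ 3.
* **BCPNN information component**, closed form:
  `IC = log2((a+0.5)/(E+0.5))` with the Norén approximation
  `IC025 = IC − 3.3 (a+0.5)^{-1/2} − 2 (a+0.5)^{-3/2}`; positive when
  IC025 > 0. Published signal tables sometimes print the IC as
  log2(EBGM); an `ic_from_ebgm` mode mirrors that convention while
  keeping the closed-form credible bound, because no closed form exists
  for a credible bound of that hybrid.
* **MGPS / EBGM** (DuMouchel's multi-item gamma-Poisson shrinker): the
  relative reporting rate λ of each cell carries the mixture prior
  `P·Gamma(α₁, β₁) + (1−P)·Gamma(α₂, β₂)`; with `a | λ ~ Poisson(λE)` the
  marginal is a two-component negative-binomial mixture, maximized over
  all cells by multi-start bounded quasi-Newton (L-BFGS-B on log/logit
  scales) from the DuMouchel default start `(0.2, 0.1, 2.0, 4.0, 1/3)`.
  The posterior is again a gamma mixture; `EBGM = 2^{E[log2 λ | a]}` and
  EBGM05 is the 5th posterior percentile, solved by bisection to
  `|CDF − 0.05| < 1e-8`. Positive when EBGM05 > 2 (the companion
  condition EBGM > 0 holds for every cell and is recorded as vacuous).

A PT is **cross-validated** when all four flags fire,
**hypothesis-generating** when at least one fires but not all four, and
**negative** otherwise. Benjamini–Hochberg adjustment (Bonferroni
available) is applied to the PRR chi-square p-values across the family of
PTs with a ≥ 3.

### On the MGPS prior family, and a known limitation

The mixture prior can be fitted on two families: the focal drug's own
per-PT tables (default), or every drug crossed with every PT
(`mgps_prior_source = "all_drugs"` via `mgps_cells()`), the null-dominated
family of classical MGPS practice. Neither makes shrinkage a *monotone*
map: the posterior mean moves toward the fitted mixture, not toward 1.
When the database contains a handful of strong signals, the flexible
component centres on them, and a *weak* elevated cell can be pulled
slightly above its raw `a/E` (toward the component mean) — or, under the
null-dominated family, absorbed into the null spike and shrunk marginally
below 1. Both behaviours are correct maximum-likelihood empirical Bayes;
users should read EBGM as "stabilized toward the database's signal
structure", not as a value guaranteed to sit between 1 and the raw ratio.
For strong signals (raw ratio ≥ ~3 with dozens of cases) the classical
ordering `1 < EBGM < a/E` holds in practice.

## Severity testing

Serious and non-serious report groups are compared per PT on 2x2 tables
whose denominators are the *PT-occurrence totals* of each group (all
reaction rows), not the case counts — this is the margin convention that
reproduces published per-term statistics. The test is chosen by the
classical expected-count rule: Fisher's exact test (two-sided, sum of
small p, no mid-p) when any expected cell `row·col/N` is below 5, else
the chi-square test with the Yates continuity correction
`N(|ad−bc| − N/2)² / [(a+b)(c+d)(a+c)(b+d)]`, clamped at zero. Both the
threshold and the correction are reconstructions verified numerically
against published statistics (e.g. counts (4, 32) on margins
(1137, 1509) give 15.11 uncorrected but 13.827 corrected, matching the
printed value); an uncorrected mode is provided.

## Time-to-onset and the Weibull shape parameter

TTO is the whole-day interval from the earliest focal-drug start date to
the event date; records with a missing start, missing event, or event
before start are excluded and tallied (same-day onset, day 0, is legal).
The two-parameter Weibull is fitted by maximum likelihood
(`survival::survreg` under the hood — every observation is an event, as
spontaneous reports carry no at-risk denominator). Because Weibull
support is positive, day-0 events would be inadmissible: with
`offset = "auto"` all values are shifted by +0.5 day *for fitting only*
whenever a zero is present. Dropping day-0 events instead would bias the
shape upward. Confidence intervals are Wald on the log-parameter scale
(the observed-information route); a seeded nonparametric bootstrap is
available. The failure type follows the interval, not the point
estimate: `early_failure` when the shape CI lies entirely below 1
(decreasing hazard), `wear_out` entirely above 1, `random_failure`
otherwise — this gives "β = 1" a testable meaning. The log-rank
comparison between sexes treats every observation as an event for the
same reason.

Note that day-resolution rounding biases a continuous-Weibull shape
estimate upward when the scale is small relative to one day of rounding;
fitted shapes on day-rounded data should be compared against the
day-discretized law, which is what the package's own tests do.

## The synthetic report generator

`synthetic_config()` / `generate_reports()` emulate a focal-drug
spontaneous-report database with known ground truth, in exactly the
schema the parser reads. Defaults encode a realistic study condition for
an acid-suppressant cohort: 20,000 reports with a 10% focal-drug share
(large enough that planted cells carry ≥ 60 expected counts); sex mix
62.0% / 29.6% / 8.4% (female/male/unknown) and age bands 8.1% / 36.6% /
25.3% / 2.8% with 27.2% missing, mirroring the descriptive structure of a
real post-approval cohort; ~81% missing weight; onset intervals
Weibull(scale 19.73 d, shape 0.49) — an early-failure hazard — rounded to
whole days with day 0 retained; three planted drug-event associations at
relative reporting ratios 2, 5 and 10 on background probabilities 0.015,
0.008 and 0.005. Each PT occurs independently per report with probability
`background x (ratio if focal and planted)`, capped at 1 with a warning.
A report that draws no event receives one fallback PT sampled
proportional to background probability (a spontaneous report always
carries at least one reaction); with the default panel the fallback fires
for under ~10% of reports and perturbs cell probabilities negligibly.
Duplicates (same CASEID, earlier FDA_DT, smaller PRIMARYID), partial
dates, and negative onset intervals are injected at configurable rates so
every cleaning branch is exercised end to end.

What the generator does *not* emulate: reporting-behaviour biases
(stimulated reporting, channeling), correlated event co-occurrence,
indication-dependent prescribing, or country-specific coding habits.
Passing recovery tests on synthetic data therefore demonstrates that the
statistical machinery is correct under the generative model, not that
real-database signals are unbiased — disproportionality on real
spontaneous reports remains hypothesis-generating.

## Numerical choices and problem sizes

* All randomness flows from one run seed recorded in the manifest; a
  fixed seed yields byte-identical report bundles.
* Human-readable tables print ratios at 2 decimals and chi-square at 3;
  machine TSVs keep full precision.
* The MGPS optimizer uses the DuMouchel start plus six perturbed
  restarts; a line-search abort at a numerically flat gradient
  (max |grad| below 1e-2 relative) is accepted as converged.
* EBGM05 bisection brackets from component gamma quantiles and refines to
  `|CDF − 0.05| < 1e-8`.
* Validation simulations use 20,000-report databases with 100 seeded
  replicates for recovery and type-I-control checks, 5,000 draws for
  Weibull parameter recovery, and exhaustive Fisher enumeration for all
  margins with N ≤ 60 — sizes chosen so each property is tested with
  comfortable statistical resolution while a full run stays in the
  minutes range on one CPU.

## Known limitations

* The comparator is "all other reports in the ingested window"; no
  active-comparator restriction is implemented.
* SOC analysis counts a report once per SOC (configurable conceptually,
  but once-per-report is the implemented default) and relies on a
  user-supplied PT→SOC table rather than a licensed MedDRA hierarchy.
* EBGM shrinkage is non-monotone for weak signals (see above).
* With ~80% missing weight the imputation rule is intentionally inert;
  weight-based analyses on such data describe the observed subset only.
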
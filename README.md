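# faersignal

Disproportionality signal detection for spontaneous adverse-event
reports, for pharmacovigilance analysts and biostatisticians working
with FAERS-style quarterly ASCII data.

Spontaneous-report databases have no exposure denominator, so drug
safety signals are screened by *disproportionality*: for each drug–event
pair, the observed report count `a` in the 2×2 table

|            | event | no event |
|------------|-------|----------|
| focal drug | a     | b        |
| all others | c     | d        |

is compared with its expectation `E = (a+b)(a+c)/N` under independence.
`faersignal` implements the full pipeline around one focal drug:

* **Ingestion** of the seven `'$'`-delimited FAERS tables (DEMO, DRUG,
  REAC, OUTC, THER, INDI, RPSR), unit standardization, drug-name
  normalization, case deduplication (latest `FDA_DT`, ties by largest
  `PRIMARYID`), primary-suspect selection, and conditional weight
  imputation.
* **Four disproportionality statistics** with conventional positivity
  thresholds: reporting odds ratio `ROR = ad/bc` (CI lower bound > 1,
  estimate ≥ 3), proportional reporting ratio
  `PRR = [a/(a+b)]/[c/(c+d)]` (PRR ≥ 2, χ² ≥ 4, a ≥ 3), the BCPNN
  information component `IC = log2((a+0.5)/(E+0.5))` with the Norén
  credible bound (IC025 > 0), and DuMouchel's multi-item gamma-Poisson
  shrinker (gamma-mixture empirical Bayes; EBGM05 > 2). Signals are
  tiered *cross-validated* (all four), *hypothesis-generating* (some),
  or *negative*, with Benjamini–Hochberg adjustment across PTs.
* **Severity testing** per Preferred Term between serious and
  non-serious reports: Yates-corrected χ² or Fisher's exact test, chosen
  by the minimum-expected-cell-below-5 rule.
* **Stratified analysis** by sex and age band, and co-medication
  ranking.
* **Time-to-onset**: exclusion-accounted intervals, median (IQR),
  two-parameter Weibull maximum likelihood with Wald or bootstrap CIs
  and failure-type classification (shape CI < 1 → early failure), onset
  curves, and a between-sex log-rank test.
* **A synthetic report generator** with known ground truth (planted
  reporting-rate elevations, demographic mix, Weibull onset, injected
  duplicates and partial dates), so the whole pipeline is testable
  without external data.

## Worked example

Run the pipeline on a 20,000-report synthetic database with three
planted drug–event associations (relative reporting ratios 2, 5, 10):

```r
library(faersignal)
cfg <- run_config(
  synthetic = synthetic_config(n_reports = 20000, seed = 7),
  seed = 7, output_dir = "faersignal_out")
res <- run_pipeline(cfg)

planted <- c("Abdominal distension", "Gastric polyps",
             "Blood gastrin increased")
res$signals[res$signals$label %in% planted,
            c("label", "n_cases", "ror", "ebgm", "ic025", "tier")]
#> Key: <label>
#>                      label n_cases      ror     ebgm     ic025                  tier
#>                     <char>   <num>    <num>    <num>     <num>                <char>
#> 1:    Abdominal distension      61 1.896804 1.641333 0.3490654 hypothesis_generating
#> 2: Blood gastrin increased     105 9.454305 4.865534 1.9731156       cross_validated
#> 3:          Gastric polyps      81 4.833694 3.389663 1.3849481       cross_validated

res$onset$fit
#> Weibull onset model (n = 1432)
#>   scale alpha = 23.76 d (21.59-26.15)
#>   shape beta  = 0.57   (0.55-0.60)
#>   failure type: early failure
```

Reading the output: the two strong planted signals are recovered by all
four algorithms (`cross_validated`), with empirical-Bayes EBGM shrunk
below the raw reporting ratios; the weak ratio-2 signal is flagged by
some but not all algorithms (`hypothesis_generating` — its ROR of 1.9
fails the ROR ≥ 3 rule, by design). The Weibull shape estimate below 1
with an interval entirely below 1 classifies onset as *early failure*:
the hazard of a new adverse event declines with time on drug. (The
fitted shape 0.57 sits above the generating 0.49 because day-resolution
rounding of onset intervals compresses small values; the vignette
discusses this.) The output directory contains the cleaned case table,
machine- and human-formatted signal tables, severity and stratified
tables, onset curves, co-medication ranking, and a JSON manifest with
stage-by-stage counts; rerunning with the same seed reproduces every
file byte for byte.

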
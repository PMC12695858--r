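# srssignal

Pharmacovigilance analysis of spontaneous reporting system (SRS)
databases. Spontaneous reports — FAERS in the United States, JADER in
Japan — are the main post-marketing source for detecting adverse drug
events that clinical trials missed, but the raw quarterly tables are
messy: follow-up submissions duplicate cases, ages arrive in mixed
units or decade buckets, and dates come at year, year-month or full
precision. `srssignal` turns those tables into a cleaned case-level
model and runs the standard signal-detection workflow on it:

- **Disproportionality on the 2×2 report table.** For a drug *D* and
  adverse-event set *E*, with cells N11 (reports of *D* and *E*), N10,
  N01, N00:

  - reporting odds ratio
    `ROR = (N11/N10) / (N01/N00)` with the log-scale Wald 95% CI
    `exp(ln ROR ± 1.96·√(1/N11 + 1/N10 + 1/N01 + 1/N00))`;
    a signal requires the lower bound to exceed 1.
  - BCPNN information component
    `IC = log₂[(N11+γ11)(N+α)(N+β) / ((N+γ)(N1₊+α1)(N₊1+β1))`]
    with priors γ11 = 1, α1 = β1 = 1, α = β = 2 and the three-term
    closed-form posterior variance; a signal requires
    `IC025 = IC − 2√V > 0`.

- **Weibull time-to-onset.** Days from drug start to event onset are
  fitted on a Weibull probability plot (mean-rank positions for n ≥ 30,
  Benard median ranks below). The shape β classifies the hazard:
  early failure (CI below 1, hazard falls with time on drug), random
  failure (CI spans 1), wear-out failure (CI above 1).

- **Age/sex-adjusted ROR.** Logistic regression
  `log odds(case) = β0 + βD·D + βA·age + βG·sex`; the adjusted ROR is
  `exp(βD)` with a Wald CI, gated by the events-per-variable rule
  (≥ 30 cases) and checked for collinearity with VIFs.

- **A synthetic SRS generator** with known ground truth (planted drug
  effects, Weibull onset models, missing fields, duplicate case
  versions) that emits both the FAERS and the JADER dialect, so the
  whole pipeline is testable without a database download.

The default case definition is the four MedDRA taste-disorder
preferred terms (taste disorder, dysgeusia, hypogeusia, ageusia); any
PT-code set can be passed instead.

## Worked example

```r
library(srssignal)

# published margins: the nirmatrelvir/ritonavir row of a signal table,
# against database totals of 24,485 taste-disorder reports in 10,177,264
ct <- contingency_from_margins(3968, 72107, 24485, 10177264)
ror(ct)
#> ROR 27.04 (95% CI 26.11-27.99)  [signal]
information_component(ct)
#> IC 4.43 (IC025 4.38)  [signal]

# synthetic database round trip
scenario <- srs_scenario(n_reports = 150000, seed = 7)
dir <- tempfile()
simulate_reports(scenario, dir)
raw <- read_faers_tables(file.path(dir, "faers", "DEMO.txt"),
                         file.path(dir, "faers", "DRUG.txt"),
                         file.path(dir, "faers", "REAC.txt"),
                         file.path(dir, "faers", "THER.txt"))
reports <- label_cases(apply_exclusions(dedup_latest_version(raw)))
reports
#> <srs_reports: FAERS> 139666 cleaned reports (462 target-event cases)
#>  excluded: missing_age=7477, anomalous_age=0, missing_sex=2857

head(signal_table(screen_signals(reports)), 3)
#>                     drug atc_code cases non_cases total              ror_ci    ic_ic025
#> 1 nirmatrelvir/ritonavir     <NA>    75      1012  1087 26.46 (20.51-34.15) 4.04 (3.68)
#> 2       sunitinib malate     <NA>     9       388   397   7.11 (3.65-13.85) 2.11 (1.17)
#> 3         clarithromycin     <NA>     8       225   233  10.88 (5.34-22.16) 2.34 (1.35)

onset <- compute_onset(reports, "nirmatrelvir/ritonavir")
set.seed(7)
fit_weibull_plot(onset$time_to_onset_days)
#> Weibull time-to-onset fit (probability plot, mean rank)
#>   n = 54, shape beta = 0.92 (95% CI 0.82-1.12), scale = 3.5 days
#>   median 2.0 days (IQR 0.5, 4.8); pattern: random failure
```

The screen recovers the planted associations (the generator's default
catalog mixes drugs with strong taste-disorder effects and null
comparators): all three flagged drugs were simulated with odds
multipliers above 1, and the estimated RORs sit near the planted
values. The onset fit recovers a shape near the simulated 0.88 with a
median around the simulated 2-day scale.

`run_pipeline()` wires these stages together from a config list and
writes the attrition counts, demographics, signal, time-to-onset and
adjusted-ROR tables to a directory; `verify_printed_tables()` recomputes
every statistic of the packaged published-margins fixture and reports a
cell-by-cell comparison.

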
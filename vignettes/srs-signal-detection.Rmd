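---
title: "Signal detection, onset modelling and adjusted reporting odds ratios for spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal detection, onset modelling and adjusted reporting odds ratios for spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srssignal)
```

## The problem

Spontaneous reporting systems collect voluntary reports of suspected
adverse drug events. They have no denominator — nobody knows how many
patients took each drug without an event — so incidence cannot be
estimated. What can be estimated is *disproportionality*: whether a
drug-event pair is reported more often than the rest of the database
would predict. `srssignal` implements the standard workflow on the two
major databases' table dialects (FAERS quarterly dollar-delimited ASCII,
JADER CSV with Japanese headers), with the four MedDRA taste-disorder
preferred terms (10082490, 10013911, 10020989, 10001480) as the default
case definition.

## Cleaning model and assumptions

FAERS assigns a version number to each follow-up submission of a case;
only the latest version is kept (`dedup_latest_version()`), with ties on
(case, version) resolved to the last-read row. JADER has no versioning;
its duplicate handling is exact-row removal after normalization. Reports
lacking a usable age or sex are excluded and tallied by reason, so that
survivors plus exclusions always reconstruct the input count — the
bookkeeping a data-construction flowchart needs.

FAERS ages come in coded units; we convert to years
(YR = 1, DEC = 10, MON = 1/12, WK = 7/365.25, DY = 1/365.25,
HR = 1/8766) rather than exclude non-year units, and treat
unconvertible codes as missing age. JADER decade buckets map to their
midpoints (e.g. "60歳代" → 65). Drug names are case-folded, trimmed,
whitespace-collapsed and transliterated full-width → half-width before
matching; salt forms remain distinct keys.

Time-to-onset uses four date rules: year-only dates on either side
exclude the record; year-month dates resolve to day 15; onset before
start excludes the record; onset on the start's calendar day counts as
0.5 days. We apply the year-only rule to both the start and the event
date. Intervals are exact day differences on the proleptic Gregorian
calendar. Two consequences worth knowing: two year-month dates in the
same month become the same imputed day and hence 0.5 days; and the
0.5-day convention puts a mass of ties at the minimum, which the
plotting positions handle with stable sequential ranks (no midranks), so
positions stay distinct. No left-truncation correction is applied for
that mass.

## Disproportionality statistics

The unit of observation is one report; a report naming the target drug
twice counts once, and exposure is restricted to accepted roles
(primary suspect in FAERS, suspected drug in JADER). The reporting odds
ratio uses the log-scale Wald interval; any zero cell marks the result
degenerate rather than extrapolating. The BCPNN information component
uses the conventional priors (γ11 = 1, α1 = β1 = 1, α = β = 2) and a
±2-posterior-SD credible interval; the variance is the standard
three-term closed form over the joint and both marginal posteriors,
scaled by 1/ln²2. That combination reproduces published signal tables
cell for cell at two decimals (see `verify_printed_tables()`), which is
why it was adopted. Signal criteria: ROR lower bound > 1 *and*
IC025 > 0, gated at 5 or more target-event cases; drugs whose expected
joint count N1₊N₊1/N₊₊ falls below 5 are flagged, not dropped.
Display rounding is half-up, matching how such tables are printed;
internal values keep full precision.

## Weibull time-to-onset

The shape β of a Weibull fit to onset intervals characterises how the
hazard of the event evolves with time on drug without needing an
unexposed reference population. We fit by the probability-plot method:
regress ln(−ln(1−F)) on ln(t) over plotting positions — mean rank
i/(n+1) at n ≥ 30, Benard's median-rank approximation (i−0.3)/(n+0.4)
below — and read β off the slope, the scale off exp(−intercept/β). The
gate is 20 cases. Quantiles reported alongside (median, IQR) are linear
interpolations of the order statistics, and the reported mean is the
arithmetic mean of the raw days, not a model mean.

The 95% CI of β is a percentile bootstrap of the plot slope (200
resamples, drawn from the current RNG stream — seed before fitting for
reproducibility). The naive alternative, reading the regression slope's
standard error off the least-squares fit, is offered as
`ci_method = "regression"` but is **not** the default: the plot's points
are order statistics and strongly correlated, so that standard error is
far too small and its interval covers the true shape at well below the
nominal rate, misclassifying a true constant hazard as early or
wear-out failure. The bootstrap interval's replicate coverage is near
nominal and the pattern classification recovers the true category in
the clear majority of replicates; the test suite measures both, and the
comparison against the regression interval, directly. Classification is
early failure if the CI lies below 1, wear-out if above, random if it
spans 1 — consistent with the interval by construction. A
maximum-likelihood fit (`fit_weibull_mle()`) is available as an
independent diagnostic cross-check; the plot estimator remains primary
because it is the standard of SRS onset practice. The estimator carries
a small downward finite-sample bias, well inside its sampling spread at
the sample sizes the gate admits.

The Weibull assumption — that events keep accruing over unbounded time —
is itself questionable for drugs taken briefly; results for such drugs
describe the reported intervals, not a biological hazard.

## Adjusted reporting odds ratios

Reporting of taste disorders skews female and rises with age, so the
crude ROR can be confounded. The model is logistic:
log odds(case) = β0 + βD·D + βA·A + βG·G with age continuous in years
(a single slope, the conventional reading of such models) and female
coded 1. The adjusted ROR is exp(βD) with a Wald 95% CI. Eligibility
follows events per variable = 10 with three explanatory variables,
hence ≥ 30 exposed cases; separation (an empty drug-by-outcome cell)
refuses the fit rather than reporting a monotone-likelihood estimate.
Convergence tolerance is 1e−8 with at most 100 IRLS iterations. VIFs
are computed from the correlation matrix of (D, A, G) via the
auxiliary-regression closed form; values ≥ 2 warn but do not fail,
since the diagnostic is advisory. With covariates independent of
exposure and a rare outcome, adjusted and crude estimates coincide;
the drug-only model reproduces the closed-form 2×2 ROR exactly, which
the tests assert to 1e−6 relative error.

## What the generator emulates — and what it does not

`srs_scenario()` defaults describe a FAERS-like population: a 0.24%
background rate of the target event, age normal(60, 15) truncated to
[0, 100], 64.8% female, one primary-suspect drug per report drawn from
a catalog mixing strongly associated drugs (odds multipliers echoing
published reporting odds ratios, e.g. 27 for nirmatrelvir/ritonavir)
with null comparators, per-drug Weibull onset models spanning early-
and random-failure shapes, 5–10% missingness on age and dates, 10%
year-month and 3% year-only date degradation, and a 5% duplicate-version
rate. Case status follows the same logistic model the adjusted-ROR
module estimates, so that module has a recoverable ground truth. A
single master seed expands into per-component substreams, so adding a
field does not reshuffle the others, and output files are
byte-reproducible.

The generator does *not* emulate: multiple drugs per report (so
confounding by co-medication cannot arise), notoriety waves or
reporting-rate drift over calendar time, free-text drug-name noise
beyond width/case variants, or the marginal demographic distributions of
any real quarter. Passing tests therefore demonstrate that the
estimators recover known structure from dialect-faithful files — not
that real FAERS extracts are clean.

## Numerical choices and degenerate inputs

- Rounding for display: half away from zero at the printed precision;
  comparisons against published values use the same rule.
- Zero cells: ROR degenerate (no signal); IC is defined for zero cells
  through its priors; an empty database is a hard error.
- Identical onset times: the plot has zero x-variance and the fit is
  refused rather than returning an unstable slope.
- Empty drug lists, empty report sets and drugs absent from all
  reports produce empty tables, not errors, except where a statistic
  is requested directly.

## Problem sizes in the test suite

Replicate studies in the tests use sizes chosen to make Monte-Carlo
envelopes tight enough to be informative while keeping the suite quick
to run on one CPU: shape recovery at n = 500 across 100 replicates per
true β; adjusted-ROR recovery at n = 200,000 across 50 replicates;
screening checks at n = 50,000–150,000. The recovery criterion is that
the replicate-central estimate (median β̂, mean exp(βD)) lies within
±2 replicate standard deviations of the truth — the estimator's own
sampling spread.

## Known limitations

Disproportionality is a hypothesis-generating screen: no denominator,
no causality. The pipeline inherits every SRS bias (underreporting,
notoriety, variable report quality) and the adjusted model deliberately
includes only age and sex — co-medication and indication are not
modelled, matching the usual practice for drug-screen-scale analyses.
ATC classification is carried as annotation only, and MedDRA codes are
treated as opaque integers (no hierarchy traversal).
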
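---
title: "Methods: screening oral adverse events in spontaneous-reporting data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening oral adverse events in spontaneous-reporting data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oravigil)
```

## The data model

Spontaneous-reporting (ICSR) databases are collections of case reports,
not cohorts: there is no denominator of vaccinated persons, only of
reports. Every quantity in this package is therefore a *reporting*
quantity. Two dialects are modelled. The single-term dialect (as in the
German PEI export) attaches exactly one preferred term — the "chief
complaint" — to each report. The multi-term dialect (as in VAERS)
attaches up to five, with the first term read as the primary symptom;
counting can use any position (`scope = "any_position"`, the default) or
only the first (`"primary_only"`), the latter approximating a chief
complaint when comparing dialects.

Covariates are sex, a five-bracket age group, vaccine platform, schedule
(primer vs booster series) and calendar year, each with an explicit
`missing` category. Duplicate reports are merged by report id; the
published analyses state that merging occurred but not how, so the
package adopts a deterministic rule: non-missing covariate values win,
ties go to the first occurrence, and term lists are unioned in first-seen
order then truncated to the dialect bound. The rule is idempotent, which
the test suite checks as a property.

The oral-AE vocabulary is a packaged frame of 80 preferred terms mapped
to eight anatomical/functional groups, with case-insensitive substring
exclusion keywords screening out terms that mention the mouth without
being oral-cavity AEs (contraception, congenital malformations, oncologic
diagnoses). Term matching is exact on normalised (lower-cased,
whitespace-collapsed) strings: the source analyses describe a keyword
search without a grammar, and exact matching keeps classification
reproducible.

## Reporting rates and trimming

The absolute reporting ratio is `ARR = 1000 · n/N` cases per 1000
reports; reports are the denominator, so ARRs from databases with
different dialects are only loosely comparable (a single-term database
mechanically depresses per-term counts). Terms with fewer than
`min_trim = 3` reports in the single-term database are trimmed before
comparative analysis, and their rows are dropped from the other database
alongside — rates estimated from one or two reports carry no signal and
would dominate ratio statistics. Report-layer rounding is 3 decimals for
ARRs and 2 for ratio metrics, matching the conventions of published
tables; all internal computation is unrounded.

## Cross-database comparison

Per term, the contrast between databases is the odds ratio
`(a/(n1−a))/(b/(n2−b))` with the Woolf log-normal interval. Zero cells
are *not* continuity-corrected: a term absent from one database prints an
infinite or zero OR with undefined CI, which is more honest than a
Haldane-corrected point estimate and matches how such rows appear in
published tables. Terms are tagged `db1_dominant`/`db2_dominant` only
when the whole CI sits on one side of 1.

Characteristic comparisons (sex, age, platform, schedule, year) exclude
the `missing` category from both margins — the same convention under
which the published percentages are computed (category shares are
conditional on non-missing; only the missing share itself uses the full
denominator). The default test is Pearson's χ² without continuity
correction, switching to Fisher's exact test when any expected cell is
below 5 (exact for 2×2; for wider tables a sparse-cell warning is issued
instead, and in the subgroup module a simulated-p Fisher test under a
fixed internal seed is used). The expected-cell rule is the conventional
one; the source analyses cite both tests without a selection rule.

## Hybrid disproportionality

Within the multi-term database, each term is crossed with vaccine class
(COVID-19 vs comparator) into a 2×2 table (`a, b, c, d`). Three
disproportionality statistics are computed:

* `PRR = (a/(a+b)) / (c/(c+d))`, CI via
  `SE = √(1/a − 1/(a+b) + 1/c − 1/(c+d))`;
* `ROR = ad/bc`, CI via `SE = √(1/a + 1/b + 1/c + 1/d)`;
* the shrinkage information component
  `IC = log2((a+0.5)/(E+0.5))` with the expected count taken from the
  within-database margins, `E = (a+c)(a+b)/N`, and
  `IC025 = IC − 3.3(a+0.5)^{−1/2} − 2(a+0.5)^{−3/2}`.

The IC formulation is the standard observed-vs-expected shrinkage
variant; IC025 is the usual two-term approximation to the 2.5th
percentile of the gamma posterior of the observed-to-expected ratio, and
the test suite checks it against a Monte-Carlo draw from that posterior
(agreement within 0.15 at a ∈ {3, 10, 100}). Using within-database
margins (rather than an all-drugs background) means `E ≥ (a+b)/N · a`,
so the IC is bounded above by `log2(N/(a+b))`: when the exposure arm
dominates the database the IC is intentionally conservative. The large
printed ICs of real screens arise when the comparator arm is much larger
than the exposure arm's case counts.

A term **qualifies** when the exposure arm has at least `min_covid = 3`
reports, the comparator arm at least `min_comparator = 1`, and all three
metrics are computable; otherwise it is `disqualified`, mirroring the NA
rows of published screens (whose exact comparator counts are not
printed, so the thresholds are configurable rather than inferred). A
qualified term is an SDR iff PRR ≥ 2 with CI lower bound ≥ 1, ROR ≥ 2
with CI lower bound ≥ 1, and IC > 0 with IC025 > 0. Requiring all three
is what makes the rule conservative: under configured independence of
term and vaccine class the test suite observes well under 5% of
qualified terms flagged across 100 seeds.

## Subgroups and regression

Subgroup ARRs stratify the top-`k` (default 20) terms by sex, the
three-level age regrouping (minors < 18 pooling the three juvenile
brackets, adults 18–59, seniors > 59), year (2021–2023 by default; the
first pandemic year contributes negligibly many reports in the reference
data and is treated as out-of-window), platform, and schedule. Records
missing the stratification variable leave both numerator and
denominator. For vaccine type, strata without any case are excluded from
the homogeneity test (but retained in the table) to avoid degenerate
zero rows. No multiplicity correction is applied by default, matching
the descriptive use of these tables; per-stratum exact binomial CIs are
emitted for forest plots.

Per-term logistic regression uses four predictors — sex, 3-level age,
platform, schedule — dummy-coded against male/adults/mRNA/primer, on
COVID-class reports with listwise deletion of missing predictors. Year
is deliberately not a predictor. Fitting is binomial IRLS via
`stats::glm` (tolerance 1e-8, max 100 iterations) with Wald intervals;
Wald (not profile) intervals are the default because symmetric-on-log
intervals are what published tables show. Non-reference levels with zero
cases are *suppressed*: the column is dropped and the contrast reported
unavailable, with the affected records retained (pooled with the
reference). Dropping records instead would change every other estimate;
since published tables print NA for such cells without stating a rule,
the column-drop is the least invasive choice. Quasi-complete separation
is detected from runaway coefficients or standard errors (|β| > 15 or
SE > 15) and flagged rather than penalised — no Firth correction is
applied by default, since the reference methodology describes none.

## The synthetic generator

`generate_database()` draws covariates independently from configured
marginals, then includes each oral term with probability
`logistic(logit(rate/1000) + covariate offsets)` in the COVID arm and a
flat configured rate in the comparator arm. The single-term database
keeps the *first* included oral term in configuration order (falling
back to a generic non-oral filler so every report has a term); since the
default configuration orders terms by descending real-world frequency,
the chief-complaint competition mildly favours common terms, as a forced
single choice plausibly does in reality. The multi-term database keeps
up to five terms plus one filler.

`default_sim_config()` pins the generator to the study conditions of the
packaged reference tables: published covariate marginals for both
databases (count/total shares, reproducing both the conditional category
percentages and the missing shares), published per-term ARRs as the term
rates of each database, covariate effects at the magnitudes of the
published adjusted ORs for six headline terms, and default database
sizes equal to the published totals. The comparator arm is the one piece
the reference tables do not describe: the package uses a comparator
fraction of 0.3 and derives comparator rates once as
`covid rate / published PRR` (no-signal rates where no PRR was printed),
so the synthetic screen carries the published disproportionality pattern
without further calibration.

What the generator does **not** emulate: within-report term
co-occurrence (terms are sampled independently; real oral AEs co-occur
with systemic and with each other), reporting dynamics over calendar
time beyond a static year marginal (no notoriety-bias ramps), duplicate
reports, and any dependence between covariates (they are drawn
independently, so synthetic data cannot reproduce confounding between,
say, age and platform). Passing tests on synthetic data therefore
demonstrate the estimators' correctness and calibration under the
configured mechanism, not the epidemiological validity of any real-data
conclusion.

## Problem sizes and numerical choices

The test suite runs the pipeline at scaled-down sizes chosen to keep the
estimators in their working regime: rate-recovery at 10^6 reports
(binomial 3-SE tolerance), independence false-positive rates over 100
seeds at 30,000 reports, planted-effect recovery (female odds ratio 2,
term rate 3/1000 — the magnitude of the most-reported gustatory terms —
at 200,000 reports over 20 seeds, acceptance band [1.6, 2.5]), and
pipeline determinism at 8,000 reports. All randomness flows from
per-call seeds; the generator restores the caller's RNG state. Ties in
term ranking are broken lexicographically so that top-k selection is
deterministic.

## Limitations

Everything here quantifies *reporting*, not risk: no causal reading of
an SDR is warranted, and cross-database contrasts confound true
reporting differences with structural ones (single- vs multi-term
annotation being the largest). The packaged reference counts are
transcriptions of printed summary tables, so recomputation checks are
exact only to the printed rounding. Regression coefficients of the real
analyses are not recomputable from summary counts at all — they require
individual-level data — which is why the package validates its
regression machinery on synthetic ground truth instead.
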
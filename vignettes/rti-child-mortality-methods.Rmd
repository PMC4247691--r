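---
title: "Quantifying RTI-related child mortality from linked records: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying RTI-related child mortality from linked records: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Respiratory tract infections (RTIs) are under-recorded as the underlying
cause of death in children, partly because many RTI deaths occur as the
terminal event in children with complex chronic conditions. Counting only
death certificates whose underlying cause is an RTI therefore understates
the burden. `rtimort` implements an analysis that addresses this by
*phenotyping* each death from two linked sources — all codes mentioned
anywhere on the death certificate, and diagnoses on hospital episodes that
began shortly before death — and then asking three questions:

1. Are RTI-related death rates declining over time, and is there a change
   point in the trend?
2. How many deaths does the winter seasonality of RTIs add beyond the
   summer baseline?
3. How often do RTI-related deaths occur in children with chronic
   conditions?

The restricted national microdata behind such analyses cannot be shared, so
the package ships a seeded synthetic generator that emulates the joint
structure the analysis depends on. Every downstream stage is exercised and
tested against that generator.

# Case definitions

## Code clusters

A **code cluster** is a named set of ICD-10 codes and inclusive ranges with
prefix semantics. Three-character members (`A37`) match themselves and all
subcodes; ranges (`J00-J22`) match every stem between their endpoints;
four-character members (`G473`, `Q790`) match themselves and deeper
subcodes only — `G474` is deliberately *not* matched, since listing a
four-character code amid three-character ones signals intent to pick out a
single subcategory. Codes are normalised to uppercase dotless form
(`"J21.9"` → `"J219"`) before matching.

Two clusters drive the analysis:

* **RTI cluster** (`cluster_rti()`): `A37`, `J00-J22` — specific for acute
  respiratory tract infection.
* **Sensitive respiratory cluster** (`cluster_respiratory()`): `A37`,
  `J00-J99`, `R05`, `R06`, `E84`, `P75`, `Q30-Q34`, `Q790`, `G473`,
  `P22-P28` — any respiratory condition. Because it contains the RTI
  cluster, every RTI-related death is also respiratory-related, and
  estimates under this cluster bound the RTI-specific ones from above.

## Time windows

A death is **RTI-related** if an RTI-cluster code appears among the
certificate mentions *or* on a hospital episode whose start date lies in
the closed window `[dod - 30 days, dod]`. The window is closed at both ends
because same-day admissions plainly belong in it; an episode starting 31
days before death does not count, and post-death episode starts never
count. Widening the window can only turn flags on, never off (a tested
monotonicity invariant).

**Chronic conditions** — any condition needing a year or more of medical
follow-up — are detected from certificate codes (always eligible) or from
episodes starting within `[dod - 365 days, dod]`. Whether the lookback
should anchor on episode start or end dates is genuinely open; we anchor on
the start date, consistent with the 30-day RTI window, and expose
`chronic_lookback_days` as a parameter. Chronic codes are grouped into
eight fixed categories (mental/behavioural, cancer/blood, chronic
infection, respiratory, endocrine/metabolic/renal/digestive/genitourinary,
musculoskeletal/skin, neurological/sensory, cardiac). The authoritative
published code-to-group list is not redistributable, so the package ships
*exemplar* ranges per group (`chronic_groups_default()`), editable through
the configuration; all group-level outputs are functions of that
configuration and should be read as illustrative.

## Cohort eligibility

Linkage is emulated as exact child-key equality (the real deterministic
multi-field matching happens service-side before data release). The
eligible cohort keeps resident children dying of non-injury causes —
underlying cause not in ICD-10 chapters XIX–XX, i.e. codes starting S, T,
V, W, X, Y (configurable) — aged at least 28 days and before the 19th
birthday ("18 completed years"), with death inside the study window. Age
bands are 28–364 days, 1–4 years (day 365 up to the 5th birthday) and 5–18
years (5th to the day before the 19th birthday); the 365-day boundary is
defined in days, the later boundaries by birthdays, with a February-29th
birthday resolving to March 1st in non-leap years.

# Statistical methods

## Annual trends

Annual band-level death counts are modelled by Poisson regression with
calendar year as a linear term and log-population offset; the year
covariate is centred for numerical stability (reported quantities are
invariant to centring). The trend is tested against the intercept-only
model by a likelihood-ratio test, with significance at p < 0.05. The
annual percent change is `(exp(slope) - 1) * 100`.

Where a significant trend exists, a change point is sought: for every
interior candidate year (at least two years on each side), a piecewise
log-linear Poisson model with a slope change at the candidate is fitted,
and the minimum-AIC candidate is compared with the single-slope model. The
fitted curve is continuous at the change point (hinge term) by default —
the natural reading of "piecewise" for annual rates — with a discontinuous
variant (`continuous = FALSE`) adding a level shift. Over-dispersion is not
modelled, matching the stated Poisson models.

One behaviour worth knowing: because the selection takes the *minimum* AIC
over several candidates, a spurious change point is reported under a
truth-is-linear null far more often than the per-candidate AIC comparison
suggests (roughly a third of replicates in our null simulations, versus
96% power to locate a genuine sharp break to within a year). The
change-point search is therefore gated on the linear trend being
significant, and a reported change point should be read as "the best
supported break location given that a trend exists", not as a hypothesis
test for the existence of a break.

## Winter excess by rate differencing

Winter is ISO weeks 40 through 20 of the following year; summer is weeks
21–39. The two partition every ISO week (week 53, when present, is
winter). The ISO-8601 convention is an explicit choice — the source
analysis does not name one — and matters only at year boundaries.

Person-time is accrued daily: each calendar day contributes that day's band
population divided by 365.25 to the day's season. Daily accrual removes
leap-year bias from pooled rates and handles the partial winters at the
study boundaries (the early first-year winter tail and late final-year
winter head) with their actual person-time. Season rates are
`deaths / person-years x 100,000`, with a log-scale normal-approximation CI
by default and an exact Poisson CI behind `ci_method = "exact"` (zero
counts always get the exact one-sided interval).

The excess is estimated by rate differencing:

* rate difference `RD = rate_w - rate_s`, Wald CI with
  `var(RD) = d_w/PT_w^2 + d_s/PT_s^2` (independent Poisson counts);
* total excess `= RD x PT_w / 1e5`, identically the winter death count
  minus the count expected at summer rates (a tested algebraic identity);
* the excess range propagates the RD CI endpoints through the same
  multiplication, and the annual average divides by the number of calendar
  study years;
* the rate ratio `rate_w / rate_s` gets a log-scale CI.

The exact interval construction used for the published tables is not
documented in the available text, so the Wald construction is a stated
assumption; the test suite cross-checks it against a parametric bootstrap
(10,000 Poisson resamples, endpoints and SE agreeing within 2%).

Weekly and monthly rate series pool deaths by ISO week / calendar month
over the study years and divide by pooled week- or month-level person-time.
The monthly series carries plot-ready polar coordinates
(`angle = 2*pi*(month-1)/12`, `radius = rate`) for circular seasonality
plots; no rendering is done in-package.

## Comorbidity

Among RTI-related deaths, `prevalence_table()` reports per-band counts and
percentages for each chronic group (non-exclusive, so percentages sum past
100), for any-chronic and for multimorbidity (two or more groups).
Proportions are compared with Pearson's chi-squared test without continuity
correction (the correction is available behind a flag; at the table sizes
involved it does not change conclusions). The age gradient in chronic
prevalence uses the Cochran–Armitage trend test with integer scores 1..k —
the conventional default — via `stats::prop.trend.test`, which reduces
exactly to the 2x2 Pearson test for two groups.

# The synthetic generator

`sim_params()` describes the study conditions; `simulate_cohort()` draws a
linked cohort from a single seed. The generator emulates, by construction:

* band x year death counts as Poisson draws around configured expectations
  (defaults ~920/430/900 per year across the three bands, matching a
  ten-year cohort of roughly 22,500 non-injury child deaths);
* a truly-RTI subset (default 28%) whose death dates upweight winter weeks
  by `winter_multiplier` (default 1.74) while other deaths fall uniformly;
* an infant truly-RTI rate declining by `annual_trend` (default 0.977,
  i.e. 2.3%/year), with an optional change point; other bands are flat,
  reproducing the published pattern of decline confined to infants;
* imperfect, partially discordant recording: an RTI code reaches the
  certificate with probability 0.53 and a pre-death episode with
  probability 0.91, independently; with 63% of deaths linked to an episode
  within 30 days, these solve the observed 14.8% certificate-detected and
  22.4% any-route-detected shares;
* chronic-condition enrichment: 89% of truly-RTI deaths versus 80% of
  others carry at least one chronic condition, planted as certificate codes
  and (for linked deaths) on lookback episodes, with group counts drawn as
  `1 + Binomial(4, 0.294)` to produce ~75% multimorbidity among chronic
  RTI deaths;
* optional key corruption (`corrupt_keys()`) so that a configurable
  fraction of episodes fail to link.

What it does **not** emulate: pathogen identity, hospital geography,
certifier behaviour beyond per-source sensitivity, harvesting/displacement
dynamics, non-resident children, or injury deaths (eligibility filtering is
exercised by crafted fixtures instead). Passing tests on this generator
therefore demonstrate that the *estimators* recover known structure — not
that any particular real-world value is correct.

Chronic lookback episodes are generated only for deaths that also have a
30-day-linked episode; this keeps `p_linked = 0` equivalent to "no hospital
data at all" (the pipeline then classifies from certificates alone), at the
cost of slightly coupling chronic hospital evidence to linkage.

# Numerical choices and degenerate inputs

* Dates are drawn and analysed at day granularity; death-week structure
  enters only through the ISO week of the drawn day.
* A zero summer rate leaves the rate ratio undefined (`NA`) while the rate
  difference is still returned; a zero season margin in the
  winter-proportion contrast (all deaths in one season, both groups) yields
  a degenerate null test (statistic 0, p 1) rather than an error.
* A zero underlying-cause count flags the mention-vs-underlying ratio as
  undefined instead of raising.
* Non-converged change-point candidates are skipped and recorded in the
  candidate table.
* Duplicate episode rows are removed with a logged count; duplicate death
  keys are an error naming the key.

# Problem sizes used by the test suite

The stochastic suites run at sizes chosen to balance resolution against
runtime: coverage of the rate-ratio and trend CIs uses 500 replicates of a
one-tenth-scale cohort (annual expected non-injury deaths 92/43/90; infant
trend replicates use 200 expected infant deaths/year), the
likelihood-ratio test's size uses 1,000 direct Poisson replicates, and the
bootstrap cross-check uses 10,000 resamples. The acceptance script runs the
full-scale default cohort once.

# Known limitations

* The shipped chronic code groups are exemplars; group-level prevalence
  outputs depend on them and are not calibrated to any published table.
* Linkage emulation is exact-key; no probabilistic matching, and linkage
  error enters only through key corruption.
* No temperature, pathogen-surveillance or deprivation covariates; the
  winter excess is purely descriptive and does not attribute deaths to
  specific exposures.
* Mortality-rate denominators by chronic-condition status are structurally
  unavailable in this design, so chronic-condition comparisons are
  proportion-based only.
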
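---
title: "Methods: screening EHR laboratory data for pre-event biomarker signals"
author: "ehrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening EHR laboratory data for pre-event biomarker signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ehrscreen)
```

`ehrscreen` screens longitudinal laboratory measurements from electronic
health records (EHR) for signals that precede a clinical event — the
motivating application is ischemic stroke (ICD-10 `I63`). This vignette is
the package's account of the statistical procedure, the choices it makes
where the design was genuinely open, and what its synthetic validation does
and does not demonstrate about real data.

## Cohort model

A *case* is a person whose event is the first `I63`-prefixed diagnosis in
their record; the diagnosis date is the *index date*. Matched controls share
the case's sex and the nearest achievable birth year, have no index
diagnosis, and no mention — at any date — of haemorrhagic-stroke diagnoses
(`I60`–`I62`, `I64`) or medications that signal vascular treatment
(antithrombotics `B01`, NSAIDs `M01A`, `M01BA03`, salicylates `N02BA`).
Whether exclusion medications should be restricted to pre-index records is
ambiguous; `eligible_control()` defaults to any-date screening (the stricter
reading of "no mention") and exposes `before_date` for the other reading.

Matching is a seeded greedy pass in randomised case order: each case takes
the `ratio` unused same-sex candidates with the smallest absolute birth-year
difference, ties broken by smaller person id. Greedy is deterministic,
auditable, and near-optimal when the pool is several times larger than the
case list; the test-suite compares it against exhaustive search on small
instances and confirms it is optimal on the large majority, never better
than the optimum, and occasionally worse — an accepted approximation.

Measurements enter the analysis only when strictly before the index date
and within `window_days` (default 1000; controls inherit their group's
index date). Persons with fewer than `min_codes = 10` distinct analytes are
removed; a matched group that loses its case is dropped whole, a group that
loses controls keeps the remainder and is reported. Sub-groups (`all`,
`men`, `women`, `young` ≤ 60, `old` > 60) transfer whole matched groups by
the case's sex and age at index, with age computed at birth-year resolution:
`floor((index − Jan 1 of birth_year)/365.25)`.

## Normalisation

Each (analyte code, unit) pair is a separate series; no unit conversion is
ever attempted, because multi-unit feeds reflect different laboratories and
conversion would import batch effects. Within a series, ordinary least
squares of value on sex and age (age at the measurement date) yields
z-scores as residuals over the residual standard deviation. The regression
is fitted pooled over cases and controls of the analysed sub-group — the
adjustment targets physiological sex/age structure, which is shared; a
controls-only fit is a defensible alternative and can be obtained by
subsetting before `adjust_zscore()`. The sex term is dropped in single-sex
sub-groups. Series with fewer than 10 observations or without age variance
are skipped (an unstable residual sd would corrupt every downstream z). A
numerically perfect fit (residual sd below 1e-10 of the value scale) yields
exact zero z-scores rather than noise ratios.

Two deterministic tie-breaks matter downstream: `latest_per_person()`
resolves same-day duplicates by the later record ordinal, and
`pair_ratio()` picks the observation pair with minimal date gap, ties going
to the pair with the later maximum date. Reference-range categorisation is
boundary-inclusive into "within" (a value at the limit is not flagged),
matching clinical convention.

## Association-rule mining

Transactions are persons; items are `KEY_HIGH` (z > 1) and `KEY_LOW`
(z < −1) from each person's latest z-score per analyte — strict
inequalities, so z = 1 produces no item, and a person without extreme values
is an *empty* transaction that still counts in every support denominator
(people without extreme values are informative about how common extremes
are).

`fp_growth()` is a from-scratch frequent-pattern-tree miner: items are
ordered by descending support (ties lexicographic, for order-invariance),
transactions are inserted into a prefix-shared tree, and itemsets are
enumerated recursively from conditional pattern bases. Its contract —
exactly the itemsets of size ≤ `max_size` with support ≥ the threshold,
with exact counts — is checked against exhaustive enumeration on random
instances in the test-suite.

The selection null mirrors the case/control design: mine the `N` case
transactions once, then 20 times draw `N` controls without replacement from
the control pool (`M ≈ 5N`) and compute each case-frequent itemset's exact
support in the draw (direct counting — re-mining each draw would leave
rules below the draw's own threshold with unknown support). A rule is
selected only if its case support fraction strictly exceeds all 20 control
fractions; under exchangeability the chance of that is at most 1/21 per
rule, which the suite verifies empirically. Final filtering keeps selected
rules of size ≤ 3 with case support ≥ 0.05, support ratio
`supp(itemset)/∏ supp(item)` ≥ 1.5, and a bootstrap (B = 1000) lower 95%
bound of the ratio above 1. The exact thresholds of the original filtering
protocol are not public; these defaults are declared, configurable, and
produce the qualitative outcome of a handful of small, strong rules on
synthetic data.

## Trajectory trends

For each analyte, *all* measurements (not only the latest) are pooled per
arm as z against days-to-index (a negative axis) and smoothed with R's
classical lowess — span 2/3 of the points, 3 robustifying bisquare
iterations, and no delta-based point skipping, so every distinct abscissa
receives a local fit. Both curves are linearly interpolated onto a daily
grid over the intersection of their ranges; extrapolation never happens.

The original evaluation of such curves was visual; `detect_trend()`
operationalises it:

* **start time** — the earliest grid day from which `case − control` keeps
  a constant nonzero sign through the index date (a single-point suffix
  does not count);
* **direction** — the sign of the case curve's net change over the trend;
* **significance** — net change above `delta_threshold = 0.1` z *and*
  monotone case curve over the trend, where monotone allows per-step
  violations beyond `eps = 0.005` z at no more than 2% of steps (robust to
  smoother wiggle without abandoning the criterion);
* **confidence** — `higher50` when `|case − control| ≥ 0.02` z on at least
  90% of the trend, else `lower50`.

These numeric operationalisations (`eps`, the 2% violation allowance, the
0.02 margin, the 90% coverage) are declared package choices, not inferred
facts about any original protocol. They preserve two structural properties
the tests enforce: negating all curves flips direction while preserving
start and significance, and raising `delta_threshold` never creates
significance.

The validation scenario for trend recovery plants a 0.3 z drift over the
final 1000 days (noise sd 0.05, ~3000 points per arm) observed within a
1000-day window — the same canonical window the association and regression
stages use. The window length matters: with span 2/3, observing the same
drift inside a much longer window smears the fitted onset several hundred
days earlier, which is a property of lowess bandwidths, not of the planted
signal. The generator parameterises drift in units of the noise sd, so this
scenario corresponds to `slope_z = 0.3/0.05 = 6` per 1000 days.

## Per-analyte statistics

Values entering logistic regression are first passed through a rank-based
inverse-normal transform (mid-rank ties, Blom offset 3/8): it is monotone,
bounded, achieves approximate normality for any continuous input and
removes outliers without inventing winsorisation constants — the stated
goals of the original (non-public) transform. The model is a binomial GLM
of case status on transformed value, sex (omitted in single-sex sub-groups)
and age, with the two-sided Wald p-value of the value coefficient.
Non-convergence or quasi-separation (value SE above 50) flags the result
and removes it from the Bonferroni family; the family is the set of
converged analytes within the analysed sub-group (a global family across
sub-groups would be an equally defensible, stricter choice — the per
sub-group family matches how each sub-group is reported).

The survival analysis strata are `(−∞,−1)`, `[−1,1]` (closed), `(1,∞)` on
the latest z-score; `mid` is the reference. The time origin is each
person's latest measurement date — the exposure is the measured value, and
follow-up runs to the event (cases) or to index-date censoring (controls),
so follow-up time equals the `days_before` of the latest measurement. Cox
models use Efron tie handling. Hazard ratios are only interpreted when the
Kaplan–Meier curve of the middle stratum runs between the low and high
curves; `proportionality_check()` makes that visual criterion operational:
weak betweenness at the deciles of observed event times, evaluated only
while every stratum keeps at least 10 subjects at risk.

## Representation benchmark

Two tabularisations: *individual-based* (one row per person, the latest
value per analyte, missing when never measured) and *measurement-based*
(one row per measurement, other analytes carried forward from the person's
latest values). Five encodings:

1. `binary` — 1 iff the analyte was ever measured in the window;
2. `balanced_binary` — binary, with positive indicators randomly masked
   (seeded) in the class with the higher per-analyte measurement rate until
   the class rates differ by under 1%; a 0 is never flipped to 1;
3. `reference_category` — below/within/above the laboratory reference
   range, plus unknown/missing;
4. `raw` — raw latest values;
5. `zscore` — sex/age-adjusted z-scores.

Missing cells of the numeric encodings are imputed with training-split
medians and no missingness indicator columns are added — indicators would
re-inject the measurement statement and collapse schemes 4–5 into scheme 1,
defeating the comparison. Splits are person-level and label-stratified, so
measurement-based rows of one person never straddle train and test.
Classifiers are logistic regression, KNN (Euclidean, K = 15 by default) and
random forest (500 trees by default); categorical cells are one-hot
expanded for LR/KNN and left as factors for the forest. The baseline is a
random forest on sex and age alone — note that after exact sex/birth-year
matching these carry no (or slightly negative) information by construction,
so the baseline hovers at or below AUC 0.5 and any lift above it is
attributable to the laboratory features. `cross_validate_grid()` implements
the stricter protocol: hyperparameters by stratified 10-fold CV on a 90%
training partition, one final evaluation on the held-out 10%. Gini
importance reads the forest's mean impurity decrease; permutation
importance is the held-out AUC drop averaged over 10 shuffles per feature.

## The synthetic generator

`sim_population()` draws sexes (male fraction 0.405 by default), ages at
index (normal, 71.3 ± 12.8, truncated to [25, 99]) and anchor dates in the
last study year; every case gets exactly one `I63` event, a configurable
fraction of the pool gets exclusion codes (never `I63` itself — a pool
member with the index diagnosis would be a case, not an ineligible
control), and everyone receives Poisson comorbidity diagnoses.
`sim_measurements()` draws per-(person, analyte) Poisson measurement counts
at the panel rate — multiplied for cases by the analyte's missingness
multiplier — with values `intercept + sex_effect + age_slope·age +
N(0, sd)` and, for cases past the trend onset, an added linear drift of
`slope_z` noise-sd units per 1000 days. Reference ranges sit at the unit
baseline ± 1.5 sd, perturbed by one of three simulated laboratories.
Age within a record is age at index minus `days_before/365.25`.

Defaults (the package's validation conditions): 20 analytes at 0.6
measurements/person-year over a 3650-day horizon, two analytes with a
minority second unit on a ×10 scale, six planted drifts (±0.2–0.5 z per
1000 days, onsets 1000–3000 days, most mass near 2000), and a ×3
missingness multiplier on ten analytes. Pipelines and tests run at
n_cases = 100–200 with a 4–7× pool — large enough that every recovery
property is comfortably powered, small enough that the full suite runs in
minutes on one CPU.

What the generator deliberately does **not** emulate: correlated
multivariate analyte structure beyond shared sex/age covariates (only the
two-item transaction generator `sim_transactions()` offers a correlation
knob, for validating the rule miner), value-dependent missingness, disease
natural history, free-text records, or cross-database reconciliation.
Consequently, passing tests demonstrate that each stage recovers the
structure it is designed to detect under clean conditions — they do not
certify performance on real EHR data, where unit dialects, coding drift and
confounded missingness are harsher.

## Numerical and degenerate-input conventions

* All dates are ISO-8601 externally and integer days internally; every
  window comparison is in whole days, boundaries as stated above.
* Seeded functions save and restore the caller's RNG state (`with_seed`),
  so identical seed + configuration gives byte-identical output tables.
* `fp_growth` orders items by (support desc, name asc); results are
  invariant to transaction order.
* Empty inputs flow through: empty cohorts, empty transaction sets and
  empty rule tables yield empty, correctly-typed results rather than
  errors; genuinely undefined requests (no overlap between curves, zero
  marginal support, fewer than 3 survival strata, constant input to the
  normal transform) raise informative errors.
* The AUC used internally is the exact rank (Mann–Whitney) statistic; the
  test-suite cross-checks it against an independent ROC implementation.

## Known limitations

Greedy matching is not globally optimal (declared, bounded by tests). The
trend-onset estimate inherits lowess bandwidth bias and is reported on a
daily grid, not as an inferential change-point with uncertainty. The
middle-curve proportionality check is a coarse stand-in for residual-based
proportional-hazards diagnostics. The benchmark's KNN uses unscaled
Euclidean distance by design (matching the benchmarked protocol), which
handicaps it on mixed-scale encodings. Deep tabular learners and model
ensembling are out of scope.
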
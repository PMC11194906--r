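---
title: "Methods: a weighted three-level quality index for EMR datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a weighted three-level quality index for EMR datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emrqi)
```

## The model

`emrqi` scores the fitness of an EMR-style tabular dataset for
machine-learning disease-risk prediction with a three-level weighted
index: four quality dimensions (Operability, Completeness, Correctness,
Timeliness), eleven sub-dimensions, and thirty-three computable leaf
indicators. Every leaf indicator is a fraction in $[0,1]$ measured
against two declared standards:

* a **reference schema** — required elements and synonyms, primary keys,
  declared types, canonical units and convertible alternatives, value
  formats, granularity requirements, plausibility ranges, terminology
  bindings, derived-value definitions, required recording intervals, and
  a timeliness window $\tau$;
* a **modeling plan** — predictor and outcome elements, a minimum sample
  size, and required measurement methods.

With $x_i$ the raw score of leaf $i$ and $w_i$ its absolute weight, each
sub-dimension and dimension score is the sum of its children's weighted
scores and the total is the sum of the dimension scores, so

$$\text{total} \;=\; \sum_{i=1}^{33} w_i\,x_i \;\le\; 1 .$$

Additivity is exact by construction. One consequence of publishing
3-decimal rounded weights is that the 33 leaf weights sum to 1.003
rather than 1.000 (two sibling groups round upward by 0.001); the
registry therefore validates weight conservation per parent at a
tolerance of 0.002 and globally at 0.003, and a dataset scoring 1.0 on
every indicator totals 1.003 rather than exactly the level-1 sum. All
scores are carried at full precision and rounded to 3 decimals only for
display.

## The indicator formula ledger

The leaf calculators are registered by name (`indicator_calculators()`)
so alternative formulas can be substituted without touching the engine.
The packaged definitions:

* **Operability.** Primary-key / element / unit-convertibility mapping
  ratios against the schema (synonyms resolve elements; an element with
  no observed unit annotation is assumed canonical). Reliable migration
  is binary: record count and per-column non-missing counts equal to the
  source-extract manifest. Input/output sufficiency and measurement
  selectivity compare available elements and recorded method tags with
  the plan's requirements.
* **Completeness.** Element integrity (share of required plan columns
  present), value integrity (share of non-missing cells over the plan's
  columns; missing = `NA`, empty string, or a configured sentinel code),
  timestamp integrity per record and per value, state availability
  (records flagged `available`; a dataset without a state column is
  treated as fully available with a warning), sample adequacy
  $\min(1, n/n_\text{required})$, and entropy balance: Shannon entropy
  of the observed category distribution over $\log k$, 0 for a single
  class, applied to categorical inputs and to the outcome.
* **Correctness.** Format accuracy (regex match), type accuracy
  (parseability under the declared type), granularity (columns reaching
  the declared decimal precision), plausibility-range conformance
  (unparseable numerics count as non-conforming), element and
  measurement unambiguity, method-tag consistency, derived-value
  consistency (stored target within tolerance of the recomputed
  formula), unit consistency of value-level annotations, terminology
  compliance at element and value level, timestamp-format compliance,
  and temporal-order compliance (parseable anchors, admission $\le$
  measurement $\le$ discharge, nothing after the extraction date;
  records lacking anchors are non-compliant).
* **Timeliness.** Recording timeliness: share of values entered within
  $[0, \tau]$ of measurement, where a value's entry time is its own
  entry timestamp or, failing that, the record's creation timestamp.
  Recording frequency: per monitored element and stay,
  $\min(1, \text{observed}/\lceil \text{stay}/\text{interval}\rceil)$,
  averaged over elements then records (a zero-length stay expects one
  measurement).

**Degenerate inputs.** No calculator ever divides by zero: an indicator
whose denominator is empty, or whose schema section is absent, is
*not evaluable* and is scored by policy — 1.0 with a prominent warning
by default (benefit of the doubt, consistent with a constant Operability
score across cohorts drawn from a single source), switchable to 0.0 or
to exclusion with weight renormalization. Unparseable timestamps count
as invalid but never crash the engine, and every calculator is
property-tested to stay inside $[0,1]$ on randomized malformed input.

## Consultation and weighting statistics

The Delphi module reports response rates (positive coefficient
$\ge 70\%$ satisfactory), the authority coefficient
$C_r = (C_s + C_a)/2$ (acceptable $\ge 0.7$), per-indicator coefficient
of variation using the sample ($n-1$) standard deviation — appropriate
for small expert panels — flagged at $0.25$, and Kendall's $W$ on
within-expert average ranks with the standard tie correction (Likert
data is tie-heavy), tested via $\chi^2 = m(n-1)W$ on $n-1$ degrees of
freedom and flagged acceptable above $0.2$. Experts with missing
ratings are excluded listwise for $W$ and pairwise for the CV. The
familiarity mapping (1.0, 0.8, 0.6, 0.4, 0.2 from very familiar to very
unfamiliar) and the judgment-basis table (practical experience
0.5/0.4/0.3, theoretical analysis 0.3/0.2/0.1, peer knowledge and
intuition 0.1 throughout, for high/medium/low influence) follow the
common published convention and are configurable; the packaged
16-expert panel fixture reproduces the consultation's printed
coefficients ($C_s = 0.8875$, printed 0.88 at two decimals;
$C_a = 0.90$ exactly).

AHP weighting averages the experts' importance ratings per indicator
and compares siblings through rating ratios, which yields an exactly
consistent positive reciprocal judgment matrix; an optional snap to the
Saaty 1–9 scale reintroduces the realistic inconsistency the
consistency test guards against (off by default because the plain ratio
is the intended construction). Relative weights are the normalized
principal right eigenvector, computed by power iteration (tolerance
$10^{-10}$, at most 1000 iterations; non-convergence is an error
reporting the last residual), with the row-geometric-mean estimator
exposed as a cross-check — the two agree on consistent matrices.
Consistency uses $CI = (\lambda_{\max} - n)/(n-1)$ and $CR = CI/RI$
with the standard Saaty random-index table (0, 0, 0.58, 0.90, 1.12,
1.24, 1.32, 1.41, 1.45, 1.49 for orders 1–10, extended to 15);
$CR < 0.1$ accepts, orders $\le 2$ are consistent by convention, and
weight derivation fails closed naming any group at $CR \ge 0.1$.
Levels 1–2 are weighted by AHP; level-3 siblings use the percentage
rule (mean rating over the sibling sum), matching how the published
weights were produced. Because the original expert ratings are not
public, the derivation path is validated by round-trip (weights →
proportional latent importances → synthetic panel → derived weights,
recovered within 0.02) rather than by re-deriving the published table.

## Association analysis

Dataset totals are correlated with per-model performance metrics.
Both correlation coefficients are implemented directly: Pearson as the
centered sum-of-products ratio, Spearman via
$1 - 6\sum d_i^2 / (n(n^2-1))$ on tie-free ranks and as Pearson on
average ranks under ties. Method choice runs through a Shapiro–Wilk
gate at $\alpha = 0.05$: Pearson only when **both** series pass — the
conservative reading when one passes and one fails, which the source
protocol leaves unspecified. Significance is right-tailed via
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom (the same
approximation for $\rho$), with an exact permutation option for
$n \le 8$. At $r = +1$ the p-value is 0 by convention; at $r = -1$ it
is 1, since the test is right-tailed. With only five cohorts the
normality test has almost no power, and Pearson on the printed values
reproduces all nine published coefficients within rounding, so the
fixture reproduction bypasses the gate (`gate = FALSE`) while the gate
remains the default for user data.

The evaluation harness mirrors the published protocol: median
imputation, undersampling of the majority class to 1:1, a seeded random
80/20 split, standardization by training statistics, then logistic
regression, an RBF-kernel SVM with $C = 1$, and a 10-tree random forest
with maximum depth 7 (ranger, which exposes the depth cap directly).
Accuracy and precision are taken at a 0.5 threshold; AUC from the ROC
curve. Cross-validation is omitted because no hyperparameter is tuned —
the preset models are evaluated once on the held-out fifth.

## The synthetic cohort generator

The generator emulates what the indicators measure on an ICU-style
sepsis cohort: per-admission demographics and laboratory values,
4-hourly vital-sign series at exactly the schema's required cadence (so
recording frequency is 1.0 before thinning), a stored BMI derived from
height and weight, ISO-8601 UTC timestamps, and a binary sepsis-like
outcome from a logistic model on five standardized predictors (age,
white-cell count, creatinine, lactate, albumin; default coefficients
0.5, 0.7, 0.6, 1.1, −0.6) whose intercept is solved numerically for the
requested prevalence. The default prevalence is 0.3 — a realistically
enriched high-risk ICU population that still requires the protocol's
1:1 undersampling — and the default effect sizes give a clean
2,500-admission cohort a held-out logistic-regression AUC of about
0.85, leaving headroom for defect-driven degradation. Lengths of stay
are log-normal (median 3 days, clamped to 6–720 h); admissions span a
fixed four-year window with a fixed extraction date so nothing is
future-dated.

Defects are per-opportunity probabilities injected in a fixed order —
element dropout, series thinning, cell missingness, timestamp loss,
recording delays, range/format/unit/derived corruption, temporal-order
violations, state flags, label noise — so rates compose predictably
(e.g. range violations apply only to cells that survived missingness).
Realized counts are recorded in the ground truth rather than forced
exact, and each defect is drawn by comparing one uniform deviate per
opportunity against the rate, so sweeping a single axis under a fixed
seed produces *nested* defect sets and strictly monotone score
responses. Everything is drawn from one integer seed with no locale or
time dependence, making emitted CSVs byte-identical across runs.

What the generator does **not** emulate: disease progression, realistic
correlation structure between labs and vitals, informative (non-random)
missingness, multi-admission patients, or free-text fields. Passing
tests therefore demonstrate that the indicators recover *planted,
independent* defect rates and that scores track model performance under
controlled degradation — not that the index captures every failure mode
of real clinical extracts. Label noise is deliberately outside the
index's measurement scope, and the test suite documents that it
degrades model AUC while leaving the quality total unchanged — a known
boundary of data-quality scoring.

## Problem sizes and numerical choices

The test suite exercises: planted-rate recovery on a 10,000-admission
cohort (so every ratio indicator sees at least 10,000 opportunities and
is checked within three binomial standard errors), calculator
boundedness on 1,000 randomized adversarial datasets, the power
iteration against a dense eigendecomposition on 100 random reciprocal
matrices of order 3–9 (agreement within $10^{-8}$), panel weight
recovery with 400 synthetic experts, and an end-to-end sweep of six
missingness levels × three seeds at 2,500 admissions whose score/AUC
Spearman correlation must be positive. These sizes were chosen to make
sampling error negligible relative to the tested tolerances while
keeping the default test run comfortably fast on one CPU.

Other numerical conventions: weights are stored as published 3-decimal
absolute values and relative weights are derived (never stored twice);
sibling order is presentation-only; scorecards embed an index-system
content hash so comparisons across different systems fail loudly;
ranking ties keep input order; entropy is clamped to $[0,1]$ against
floating-point overshoot; timestamps parse under a configurable
`strptime` format (ISO 8601 seconds precision by default).

## Known limitations

* The exact published formulas for some leaf indicators are not public;
  the packaged calculators are this package's explicit definitions and
  the registry makes them replaceable.
* The published weights cannot be re-derived exactly without the
  original expert ratings; the AHP path is validated by round-trip
  recovery instead.
* The timeliness window and required recording intervals used in the
  original five-cohort study are unstated; the defaults here
  ($\tau = 24$ h, 4-hourly vitals) are configurable schema fields.
* Scores depend on the declared schema: a permissive schema inflates
  scores, and the benefit-of-the-doubt policy for not-evaluable
  indicators should be switched to `"zero"` or `"exclude"` when a
  dataset is missing the metadata needed for a fair assessment.
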
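---
title: "Methods: cost-minimization analysis of powered vs. manual staplers in VATS lobectomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-minimization analysis of powered vs. manual staplers in VATS lobectomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(staplercma)
```

## The decision problem

Video-assisted thoracoscopic (VATS) lobectomy for lung cancer relies on
endoscopic stapling devices. A powered stapler fires by motor and costs
more to acquire than a hand-fired manual stapler, but its use has been
associated with lower downstream hospital costs (shorter stays, lower
drug expenditure). Under the assumption of clinical equivalence, the
device choice is an economic one, and the appropriate evaluation is a
cost-minimization analysis (CMA): compare the total hospital cost per
episode under a powered-stapler scenario and a manual-stapler scenario,
and quantify the uncertainty of the difference.

`staplercma` implements that analysis end to end for a Chinese
tertiary-hospital setting with costs in CNY: a synthetic patient-level
cohort generator, eligibility filtering and descriptive group
comparisons, per-category cost regressions, and a two-scenario decision
model with one-way and probabilistic sensitivity analyses. The bundled
reference inputs come from a retrospective cost analysis of 388 VATS
lobectomy episodes (296 with the ECHELON powered stapler, 92 with the
ECHELON manual stapler).

## The cost model

Each episode's total cost is the sum of seven components: stapler and
cartridge acquisition, and five regression-driven categories —
disposable supplies, drugs, operation-related, laboratory tests, and
other resources. Acquisition costs are mean devices per episode times
unit price. Each modelled category $c$ carries a log-link linear
predictor

$$\mathbb{E}[Y_c \mid x] = \exp(\beta_{0c} + \beta_c^\top x),$$

so covariate effects act multiplicatively on costs. The covariates are
patient characteristics (sex, age, BMI band, residence, insurance,
marital status, histology, stage, bone-marrow flags, lobectomy site,
comorbidities) plus the stapler-arm indicator, which is the decision
variable: the powered scenario's category cost is the manual baseline
times $\exp(\beta_{\text{arm},c})$.

### Regression family

The reference analysis reports "generalized linear regression" without
naming a family. We fit a **gamma GLM with log link**: hospital costs
are positive and right-skewed, the printed intercepts are consistent
with log-scale means (e.g. a drug-cost intercept of 9.492 corresponds to
about ¥13,254), and the decision model uses the coefficients
multiplicatively, which requires the log link. An OLS fit of
`log(cost)` is available via `family = "lognormal"` as a sensitivity
check; its slopes are comparable but its intercept targets the
log-scale mean rather than the log of the arithmetic mean. Fitting is
by iteratively reweighted least squares (`stats::glm`), with
convergence declared at a relative deviance change below `1e-8` within
100 iterations and non-convergence treated as an error. Dispersion is
estimated by the Pearson statistic over residual degrees of freedom,
and Wald 95% intervals and p-values are computed on the log scale.
Rank-deficient designs are rejected with the offending columns named
rather than silently aliased.

### Covariate coding and screening

BMI bands use half-open intervals $[18.5, 24)$, $[24, 28)$, $[28, 30)$,
$[30, 40)$ and are coded as one-vs-rest 0/1 indicators — exactly the
coding the reference coefficient table uses — rather than as a single
factor. Model selection follows the reference procedure: each candidate
covariate is screened in a single-covariate gamma GLM and retained when
its Wald p-value is below `alpha` (default 0.05); the stapler-arm
indicator is forced into every multivariable equation regardless of
screening, because the decision model needs it in all five categories.
Constant covariates are skipped with a warning. No interactions, no
robust errors, and no multiplicity adjustment are applied, matching the
reference analysis.

## The synthetic cohort generator

Patient-level data for the reference cohort are not deposited, so the
generator emulates its published marginals and is the package's test
bed: it gives every analysis stage data with known ground truth.

* **Covariates** are sampled independently within each group from the
  published marginal prevalences (binary flags) and level frequencies
  (categoricals). Only marginals are published, so no joint structure
  is attempted — synthetic cohorts will not reproduce real covariate
  correlations, and passing tests says nothing about confounding
  structures beyond independent covariates.
* **Age and BMI** are truncated normals (18–100 years, 15–45 kg/m²)
  with the published means and SDs; the BMI band is derived from the
  sampled BMI, so band prevalences are implied, not forced.
* **Device counts** are normal draws (published means/SDs; cartridges
  7.0 powered / 7.5 manual), truncated below at zero and rounded.
* **Costs** are gamma draws with mean $\exp(X\beta)$ from a
  ground-truth coefficient table and fixed shape ("dispersion"). The
  gamma family is a modelling choice — the reference analysis never
  states a noise family — chosen because it is positive, right-skewed,
  and shares its mean model with the log-link GLM, so fitted
  coefficients estimate the generating ones directly. The default
  shape 4.9 makes the simulated drug-cost CV roughly match the
  published SD/mean ratio of about 0.45; it lives in the profile file,
  not in code. `dispersion = Inf` produces noise-free costs
  $\exp(X\beta)$ exactly, which is the inversion oracle used by the
  regression tests.
* **Episode-course fields** (operation minutes, stay, bleeding,
  drainage, surgical death, routine discharge) have no published
  distributions; the defaults in the profile are realistic values for
  VATS lobectomy chosen once (e.g. 180±60 min operations, 9±4 day
  stays) and produce a small, plausible exclusion fraction. They exist
  to exercise the eligibility filter, not to mimic the real exclusion
  flow.
* Comorbidities that appear in the reference equations but have no
  published prevalence (immune-system, breast, cardiovascular,
  vascular, lung infection, tuberculosis) are given assumed low
  prevalences (1–5%), recorded in the profile file.

Identical profile and seed give bit-identical cohorts; the generator
consumes a fixed number of RNG draws per field (truncated normals use
the inverse-CDF method) so truncation bounds cannot desynchronize the
stream.

## Eligibility filtering

Thresholds follow the reference cohort construction: operation time
over 8 hours (stored in minutes, threshold converted internally to 480),
stay over 21 days, bleeding over 600 ml, drainage over 2400 ml,
surgical death, non-routine discharge. All bounds are strict: an
episode exactly at 600 ml bleeding is retained. Exclusions carry every
violated reason. Filtering is idempotent, monotone in each threshold,
and partitions its input; those properties are tested directly.

## Descriptive comparisons

Group tables use Student's t test with pooled variance for continuous
characteristics (Welch available behind a flag), Pearson's chi-square
without continuity correction for categoricals, and the Wilcoxon
rank-sum test for costs. Two departures are deliberate:

* **Fisher fallback.** The reference table prints p = 1.000 for several
  sparse rows, suggesting an exact test was substituted there. We make
  that rule explicit: when any expected cell is below 5 the 2×2
  comparison switches to Fisher's exact test, and the output labels
  which test ran. Without continuity correction the reconstructed
  provincial-capital residence counts (75/296 vs. 13/92) give
  χ² ≈ 5.03, p ≈ 0.025, matching the published row; with Yates
  correction it would not (p ≈ 0.037).
* **Exact rank-sum with ties.** For combined samples up to 25 the exact
  permutation distribution of the rank sum is enumerated by a dynamic
  programme over the doubled mid-ranks, so ties are handled exactly
  (`stats::wilcox.test` has no exact path under ties); larger samples
  use the tie-corrected normal approximation. The two routes agree
  within 0.02 in absolute p at n = 15/15, which is tested.

## The decision model

### Base case

The model compares two scenarios on the same cohort (a paired design —
only the stapler-arm indicator differs). In **aggregate-calibrated
mode** the manual scenario's five category baselines are supplied
directly (the bundled calibration is the published manual column:
disposables 9989, drugs 13,043, operation 7643, laboratory 11,162,
other 2248), and the powered scenario multiplies each by
$\exp(\beta_{\text{arm},c})$. This mode reproduces the published
base case from printed inputs alone and exists because the real
patient-level records are unavailable. In **patient-level mode** the
baseline is the cohort mean of $\exp(x_i^\top\beta)$ with every episode
set to the manual arm; a cohort calibrated to the aggregate baselines
gives identical results, which is tested.

Utilization means are back-solved from the published acquisition cells
(e.g. 8327/6790 ≈ 1.2264 staplers per powered episode) because only
rounded means are printed. The Victor Medical scenario substitutes the
comparator device, keeping all regression-driven categories fixed — the
two manual staplers are assumed to differ only in acquisition costs.
Its published acquisition cells (stapler 4882, cartridge 20,974) are
inconsistent with counts × unit prices (4585 / 22,404); the bundled
product therefore carries the published cells as an
`acquisition_override`, with the price-only arithmetic available by
dropping the override. Internally everything is computed at full
precision; rounding to whole CNY happens only when printing.

### One-way sensitivity analysis

Each parameter in turn moves to its bounds with the rest at base case:
stapler-arm coefficients over their 95% CIs, unit prices and
utilization means by ±20% (a conventional default; the reference
analysis does not state its non-coefficient bounds). Entries are
sorted by swing. Acquisition parameters dominate, and among the
coefficient parameters the drug-cost stapler term has the widest bar,
consistent with the reference findings. The published overall swing
range (¥309–¥2381) is not derivable from the stated inputs and is not
used as a check.

### Probabilistic sensitivity analysis

Only the stapler-arm coefficients are uncertain inputs of the
calibrated difference, so only they are sampled; SEs derive from the
printed CIs as width/3.92. Per iteration each of 388 model patients
receives an independent draw of each category's cost multiplier, and
per-patient costs are averaged — cohort-level sampling (one draw per
iteration, available via `scheme = "cohort"`) would widen the 95%
credible interval by roughly $\sqrt{388}$ to about ±¥1,900, far from
the published ±¥130, so per-patient averaging is the reading consistent
with the reference results.

The draw scale needed one further decision. Drawing $\beta$ normally on
the log scale and exponentiating (lognormal multipliers) displaces each
category's mean by $\exp(\mathrm{se}^2/2)$, which shifts the PSA median
about ¥48 away from the base-case difference; the reference results
show the median essentially at the base case. The default
(`draw_scale = "cost"`) therefore draws the multiplier
$\exp(\beta)$ itself from a normal with SD
$(e^{\text{hi}} - e^{\text{lo}})/3.92$ — the delta-method equivalent —
which is mean-preserving, centring the PSA on the base case. The
lognormal scheme remains available (`draw_scale = "log"`), and the
difference between the two is itself a tested property. Draws are
untruncated (a negative multiplier would require a draw ~16 SDs out).

## Numerical and degenerate-input conventions

* Convergence: IRLS relative deviance `1e-8`; regression is seed-free.
* Zero-variance responses fit an exact intercept (log of the mean) with
  zero SE and undefined p-values rather than NaN propagation.
* Zero-width CIs make the tornado and PSA collapse exactly onto the
  base case; `probability_saving` is then exactly 0 or 1.
* Cost totals must equal their component sums within 1e-6 relative
  tolerance at I/O boundaries and are exact sums internally.
* Constant covariates: screened out with a warning; in recovery fits a
  constant generating covariate (possible because the manual group is
  100% married) is dropped as unidentifiable, leaving other
  coefficients unchanged.

## Problem sizes used by the tests

The test suite regenerates all data programmatically: cohorts of 30–400
episodes for behavioural tests, one 10,000-episode group for
convergence of sampled prevalences, 200–500 replicate cohorts at the
reference size (296/92) for bias and coverage of the drug-cost
stapler coefficient, and PSAs of 200–10,000 iterations. The coverage
check runs over 500 replicates because the Monte Carlo SE of a coverage
proportion at 200 replicates (about ±1.5%) is large relative to the
93–97% band being verified.

## Known limitations

* Synthetic cohorts share only the published marginals with the real
  cohort: no covariate correlations, no real exclusion flow, and no
  attempt to match published cost medians or quartiles (several printed
  quartile pairs are internally inconsistent; medians are treated as
  authoritative).
* The candidate covariate list entered into the reference screening is
  not published, so screening is validated against synthetic truth
  only.
* The reference coefficient table contains internal discrepancies (a
  BMI band labelled differently in table and text; two comorbidity
  rows cited in text but absent from the table). The bundled fixture
  transcribes the table as printed.
* Coefficient-table inputs are consumed at 3 printed decimals, which
  bounds agreement of recomputed totals with the published ones at
  roughly ±¥20.
* Cost-effectiveness (QALY/ICER) modelling, currency conversion and
  discounting are out of scope: the design is cost minimization over a
  single admission.
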
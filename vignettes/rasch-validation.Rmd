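---
title: "Validating short rating scales with raschval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating short rating scales with raschval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raschval)
```

raschval implements a five-step psychometric validation protocol for
short polytomous Likert questionnaires -- the kind of 10-to-15-item
agreement scales used to screen staff perceptions such as patient
safety climate. The package was built around the 11-item HSE
safety-climate screening instrument (five agreement categories,
complete responses enforced by the survey platform), but every stage
is generic over the number of items and categories.

## The measurement model

All stages condition on the Andrich rating-scale model. Person $n$
has a measure $\theta_n$ (logits), item $i$ a difficulty $\delta_i$,
and all items share one set of step thresholds
$\tau_1, \dots, \tau_K$ with $\sum_j \tau_j = 0$. The probability of
responding in category $k \in \{0, \dots, K\}$ is

$$
P(X_{ni} = k) =
\frac{\exp\!\big(\sum_{j \le k} (\theta_n - \delta_i - \tau_j)\big)}
     {\sum_{m=0}^{K} \exp\!\big(\sum_{j \le m} (\theta_n - \delta_i - \tau_j)\big)},
$$

with an empty sum for $k = 0$. Adjacent-category probability curves
cross exactly at $\theta - \delta = \tau_j$, so the thresholds are
directly interpretable on the latent continuum
(`category_curves()`). The rating-scale (rather than partial-credit)
form is deliberate: a shared response format across items is the
design assumption of agreement questionnaires, and it keeps the
category-functioning diagnostics of step 1 well defined at the scale
level.

Key model assumptions, each policed by a protocol step:

* **Unidimensionality** -- one latent dimension drives all items
  (steps 2b, 2c).
* **Local independence** -- items are conditionally independent given
  the measure (step 2a).
* **Invariance** -- item difficulty does not depend on group
  membership at equal trait levels (step 5, DIF).
* **Monotone category structure** -- higher measures make higher
  categories more likely (step 1).

## Estimation

`fit_rsm()` estimates all parameters by joint maximum likelihood
(JMLE): damped, alternating Newton-Raphson updates of $\theta$,
$\delta$ and $\tau$, each block step capped at 1 logit and halved
until the joint log-likelihood does not decrease, so the reported
trajectory is monotone. Convergence is declared when the largest
absolute parameter change in a cycle falls below $10^{-4}$ logits
(configurable via `estimation_settings()`), with a 200-cycle cap and
a diagnostic error -- including the likelihood trajectory -- on
failure. Identification uses the conventional double constraint
(difficulties centered over non-extreme items, thresholds summing to
zero); every centering is paired with the compensating shift of the
other parameter blocks so it never changes the likelihood.

Persons and items with minimum or maximum raw scores carry no
information about their own location. They are excluded from
estimation and afterwards placed at their raw score moved inward by
`extreme_adjust` (default 0.3 score points), the usual
fractional-score device for reporting finite measures at the floor
and ceiling. Standard errors are the information-based
$1/\sqrt{\sum W}$, with $W$ the model score variance per encounter.

JMLE is used deliberately -- it is the estimator family behind the
software tradition this protocol comes from -- and it carries a known
multiplicative bias in the item-difficulty spread at small item
counts, roughly $L/(L-1)$ for $L$ items. The default estimates are
reported uncorrected, matching that tradition; the
`bias_correction = TRUE` flag applies the $(L-1)/L$ shrinkage and is
the right choice when the goal is recovering generating parameters,
which is exactly how the package's own parameter-recovery study uses
it (correlation with the generating difficulties $\ge 0.99$ and RMSE
well under 0.12 logits at $N = 1000$, $L = 10$).

An unobservable configuration is refused up front: if some category
is never used among non-extreme responses, the shared thresholds are
not estimable and the error message points to
`collapse_categories()`.

## The five steps and their criteria

All thresholds live in `analysis_config()` and are overridable from
YAML/JSON; the defaults encode the screening conventions for short
rating scales.

1. **Rating-scale functioning** (`category_diagnostics()`): average
   measures per category must advance monotonically and every
   category outfit mean square must stay below 2.0. Average measures
   are pooled across items under the shared rating scale; a per-item
   breakdown is available (`by_item = TRUE`) because the monotonicity
   question can also be asked item by item. Categories are never
   collapsed automatically -- `collapse_categories()` exists as an
   explicit transformation only.
2. **Local independence** (`local_independence()`): the largest
   absolute pairwise correlation between standardized-residual
   columns must stay below 0.7, i.e. shared residual variance below
   50%.
3. **Item fit** (`item_fit()`, step 2b): infit mean squares must lie
   in the closed interval [0.7, 1.3]. "Between 0.7 and 1.3" is
   treated as inclusive, so a boundary value counts as fitting;
   boundary cases are visible in the report table. The removal loop
   in `run_protocol()` drops the single worst item per pass (largest
   $|\mathrm{infit} - 1|$ among misfits) and refits, because fit
   statistics are interdependent and removing several items at once
   can overshoot.
4. **Unidimensionality** (`pca_of_residuals()`, step 2c): the
   measures must explain at least 50% of observation variance, and
   the first-contrast eigenvalue of the residual correlation matrix
   must stay below 2.0. Variance explained is defined by the
   decomposition
   $100 \cdot \sum_i \mathrm{Var}_n(E_{ni}) / (\sum_i
   \mathrm{Var}_n(E_{ni}) + \sum_i \mathrm{Var}_n(e_{ni}))$; other
   bookkeepings of "variance explained by measures" exist between
   software versions, and exact numerical parity with any one of them
   is not claimed. The PCA runs on the *correlation* matrix of
   standardized residuals so its eigenvalues sum to the number of
   items, which is what makes the 2.0 cut-off readable as "two items'
   worth of covariation".
5. **Person fit** (`person_fit()`, step 3): a person is flagged only
   when infit $\ge 1.4$ *and* infit $z \ge 2$ -- the conjunction, not
   either alone -- and the scale passes while at most 5% of the
   assessable sample is flagged, the fraction expected to fail by
   chance. Standardized fit values use the cube-root
   (Wilson-Hilferty) transform with the variance built from the
   model's fourth moments. Mean squares are unitless ratios; no unit
   is attached to them anywhere in the package.
6. **Separation/reliability** (`reliability()`, step 4): person
   separation $G = \sqrt{R/(1-R)} \ge 2.0$ (three distinguishable
   trait levels) and person reliability $R \ge 0.7$. $G \ge 2$ is the
   operative criterion; the strata count $H = (4G+1)/3$ is reported
   as supporting information. Extreme persons are excluded from $R$
   and $G$ (their SEs are extrapolations) but included in the floor
   and ceiling counts, which scan raw response patterns directly. A
   raw-score Cronbach alpha is reported alongside because short-scale
   reliability is conventionally quoted both ways.
7. **DIF** (`dif_scan()`, step 5): Mantel chi-square tests for
   polytomous items, one per item x factor x group pair, with
   respondents matched on bands of the total raw score on the
   analysed item set (adjacent scores merged until every band holds
   at least 10 respondents; with complete data the raw score is
   sufficient for the measure, so score-matching is exact
   trait-matching). The Bonferroni family is defined per factor as
   items x group pairs -- the most conservative reading consistent
   with reporting DIF factor by factor -- and adjusted p-values below
   0.01 flag an item. A single pass is run; there is no purification
   loop, matching the single-scan design of the protocol.

After the steps, `mean_value_index()` computes the per-person raw
mean of the index items and rescales it to 0-100 as
$(\bar{x} - 1)/(K - 1) \times 100$. The index defaults to the first
ten retained items; `index_n_items = 9` switches to the
nine-item convention of the instrument's original developer. The
index is correlated (Pearson) with the Rasch measure of the retained
item set, excluding all-minimum patterns (their measures are
extrapolated); with complete data the raw-sum-to-measure map is
strictly monotone, so the Spearman correlation is exactly 1 and the
Pearson coefficient measures only the ogive's curvature.

## The synthetic-data generator

No raw response matrix ships with the package, so
`simulate_responses()` is a first-class module: it draws a cohort
from the rating-scale model and layers controlled violations on top.
Defaults emulate the survey the pipeline was designed around: 761
respondents, 11 items, five categories, difficulties on a uniform
grid spanning one logit, thresholds $(-1.9, -0.9, 0.3, 2.5)$ that
leave the second category squeezed between its neighbours (the
familiar under-used "mild disagreement" option), and abilities
$\theta \sim N(1.6, 2.0^2)$ relative to the mean difficulty.

The ability distribution was calibrated once, before the test suite
existed, against two features a realistic emulation must reproduce
simultaneously: about 5% of respondents at the all-maximum ceiling,
and rating-scale diagnostics that pass step 1 on model-true data. A
mean much above 1.6 reproduces the ceiling but pushes the rare
bottom-category responses onto far-off-target respondents, whose
huge squared residuals drive the bottom category's outfit past 2
even though the model is true; widening the spread to 2 logits
restores genuinely low-trait users of the low categories. The
resulting marginals are right-skewed with modal categories 4-5,
matching the published per-item frequency table of the HSE cohort
(`hse_marginals()`) qualitatively.

Controlled violations:

* **DIF** -- `dif_spec` shifts an item's difficulty by a fixed amount
  for a focal level of a generated background factor. Factors are
  otherwise drawn independently of the responses, so unshifted
  factors are exact type-I-error nulls.
* **Secondary dimension** -- an additive person trait
  $u \sim N(0, sd^2)$ enters the linear predictor of a chosen item
  subset via `loading * u`. The package's violation scenario uses
  loading 0.8 and $sd = 1.5$ on 5 of 10 items: an effective
  1.2-logit perturbation, comparable to the primary trait spread,
  which reliably drives the first-contrast eigenvalue past 2.0 while
  unidimensional nulls stay below it. A markedly weaker trait
  ($sd = 1$) sits near the 2.0 boundary -- the cut-off genuinely
  separates "clear second dimension" from noise, not "any second
  dimension".
* **Careless responders** -- a fraction of persons is overwritten
  with uniform random categories, the canonical target of the person
  fit screen.

`fixture_from_marginals()` builds a matrix whose per-item category
counts match a printed frequency table bit-exactly by shuffling each
item's multiset independently. Its joint structure is random by
construction, so it validates I/O and marginal bookkeeping -- never
fitted statistics.

What the generator does *not* emulate: real response styles
(acquiescence, central tendency), item-specific threshold structure,
clustering of respondents within units, or missing data mechanisms.
Passing the protocol on generated data therefore demonstrates that
the pipeline detects what it claims to detect under the model and
its scripted violations -- not that any particular real instrument is
valid.

## Numerical choices and degenerate inputs

* Category codes are 1-based externally (as printed in survey
  tables) and 0-based internally, where the model's step sums start
  at zero.
* Missing responses are allowed by the data model and excluded from
  every sum; the strict reader mode (`allow_missing = FALSE`)
  rejects them for surveys that enforce completeness. Residual
  correlations use pairwise-complete observations.
* Probability evaluations are log-sum-exp guarded, so measures of
  any magnitude are safe.
* `score_to_measure()` root-finds the monotone score function to
  machine tolerance; extreme raw scores are moved inward by
  `extreme_adjust` first.
* Degenerate situations fail loudly and specifically: unobserved
  categories (error with collapse advice), zero person-measure
  variance (reliability undefined, verdict fail with note), constant
  residual columns (undefined correlations, warning), strata with a
  single group (dropped with warning; undefined when none remain),
  removal below two items (abort with diagnostic).

## Problem sizes in the test suite

The package's own checks run parameter recovery at $N = 1000$ with
10 items, fit-statistic and person-flag nulls over 50 seeds of
761 x 10 cohorts, dimensionality nulls and contaminations over 20
seeds each, DIF type-I over 50 cohort scans and power over 25
two-group draws of 500 + 500 -- sizes chosen to mirror the design
regime the protocol targets while keeping each property estimable
with comfortable margins on a single CPU.

## Known limitations

* JMLE's small-$L$ bias is inherited by design; use
  `bias_correction = TRUE` when generating-parameter fidelity
  matters.
* The rating-scale model shares thresholds across items; instruments
  whose items plainly need item-specific thresholds (partial credit)
  are out of scope.
* Exact numerical parity with any particular commercial
  implementation's variance-explained bookkeeping or standardized
  fit statistics is not claimed; definitions are documented above
  and tested against their own closed forms and oracles.
* The protocol evaluates one administration at a single point in
  time; longitudinal stability of a climate measure needs repeated
  measurements and is not addressed here.

## A minimal session

```{r example, eval = FALSE}
sim <- simulate_responses(simulation_config(seed = 1))
report <- run_protocol(sim$responses, sim$factors)
tidy(report)        # step-by-step verdicts
glance(report)      # headline quantities
autoplot(report)    # index vs measure
autoplot(category_diagnostics(report$final_fit))  # category curves
print(wright_map(report$final_fit))               # targeting
```
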
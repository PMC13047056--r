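---
title: "Evaluating a staggered city-level policy with double machine learning"
author: "dmlpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating a staggered city-level policy with double machine learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmlpanel)
```

## The problem

A binary policy (a "smart city" style pilot program) is rolled out across
cities in waves: once a city adopts, it stays adopted.  We want the causal
effect of adoption on a bounded composite public-health index built from a
handful of health indicators.  Adoption is not random — cities that adopt
differ systematically in economic and social conditions that also drive
health outcomes — and the plausible control set is high-dimensional once
quadratic terms, year dummies, city dummies and auxiliary policy dummies
are included.

The package estimates the partial-linear model

$$Y_{it} = \theta\, D_{it} + g(X_{it}) + U_{it}, \qquad
  D_{it} = m(X_{it}) + V_{it},$$

where $Y_{it}$ is the health index of city $i$ in year $t$, $D_{it}$ the
absorbing policy dummy, and $g$, $m$ are unrestricted nuisance functions
learned by machine learning (random forest by default).  The target
$\theta$ is estimated from the Neyman-orthogonal moment

$$\hat\theta = \frac{\sum_{it} \hat V_{it}\,(Y_{it} - \hat g(X_{it}))}
                    {\sum_{it} \hat V_{it}\, D_{it}},$$

with $\hat V_{it} = D_{it} - \hat m(X_{it})$ acting as the instrument for
the treatment.  Orthogonality makes first-order nuisance estimation error
cancel, and K-fold cross-fitting (every prediction comes from models
trained on the other folds) removes own-observation overfitting bias.
Standard errors use the influence function
$\psi_{it} = \hat V_{it}(\tilde Y_{it} - \hat\theta D_{it})$ summed within
city and sandwiched, i.e. clustered at the city level, because outcomes of
one city are serially dependent.

## What the estimand is

With mediators present in the data-generating process but excluded from
the control set, the partial-linear fit targets the *total* effect
$\theta + \sum_m a_m b_m$ (direct plus mediated).  `true_effects()`
reports direct, per-mediator indirect ($a_m b_m$) and total effects of a
configuration, and the package's recovery experiments switch the
outcome-side paths off ($b_m = 0$) whenever a test compares $\hat\theta$
against the configured direct effect.

## The composite index

The outcome index is built by the entropy weight method
(`composite_index()`): indicators are min-max normalized with direction
reversal for loss-type indicators (disease incidence), each indicator's
entropy $e_j = -\tfrac{1}{\ln n}\sum_i p_{ij}\ln p_{ij}$ is computed from
its share distribution $p_{ij} = (z_{ij}+\varepsilon)/\sum_i
(z_{ij}+\varepsilon)$, and weights are proportional to the information
divergence $1-e_j$.  Conventions the method itself does not pin down, and
which we therefore fixed as package decisions:

* **Pooling.** Normalization and weights use the full pooled city-year
  panel, not per-year slices, so index values are comparable over time.
* **Zero handling.** $\varepsilon = 10^{-12}$ guards $\ln 0$; it perturbs
  entropies by well under $10^{-8}$.
* **Constant columns.** A constant indicator carries no discriminating
  information; it gets weight 0 (and the all-constant table is refused).
* **Normalization variant.** Min-max with direction reversal is the
  dominant convention for bounded composite indices; the weighted sum of
  columns in $[0,1]$ keeps the index itself in $[0,1]$.

## Design preparation

`prepare_panel()` + `build_design()` turn the raw panel into the learner
design: within-city linear interpolation of gaps (edge gaps take the
nearest observed value — no extrapolation), two-sided winsorization at
pooled type-1 (order-statistic) quantiles — order-statistic quantiles make
clipping exactly idempotent — with the treatment always exempt, optional
squares of the controls, one-hot year and city dummies (reference level
dropped), per-province linear trends and verbatim policy dummies.

Fixed effects deliberately enter the learners as one-hot *features*
rather than by pre-demeaning: demeaning a binary absorbing treatment
would destroy its structure, and the whole point of the estimator is that
flexible learners can absorb high-dimensional controls.  Note one
consequence: city dummies make city identity visible to the treatment
learner, which in a staggered design can predict adoption almost
perfectly and destroy residual treatment variation.  The benchmark ladder
therefore adds city fixed effects only in its strictest column, and
recovery experiments rely on year dummies plus controls.

## The synthetic panel generator

`generate_panel()` draws the study world the estimators are validated in:

* ~270 cities over 14 years (defaults), three adoption waves
  (fractions 0.20/0.15/0.15 in years 6–8 of the panel), treatment
  absorbing, wave sizes exactly `floor(fraction * n_cities)` with the
  remainder never treated.
* Confounders $X_{it}$ are a persistent city component (variance share
  0.75) plus transient noise.  Cities are ranked for adoption by an index
  loading on the same (possibly nonlinear) surface of the city components
  that drives the outcome nuisance, plus a standardized historical
  instrument base and an idiosyncratic adoption shock.  The persistent
  share is what makes the propensity learnable from a single year's
  covariates; with much smaller shares the identifying signal in
  $X_{it}$ becomes too weak for any learner at these sample sizes.
* The nonlinear nuisance menu is fixed: centered squares and pairwise
  products of the first three confounders plus a threshold term, rescaled
  so that $\mathrm{sd}(g) = $ `noise_sd`.  This makes naive linear OLS
  visibly biased — the flaw the orthogonalized estimator is there to fix.
* Fixed effects: i.i.d. normal city effects; year effects follow a mild
  linear trend plus noise so province-trend robustness has signal.
* Endogeneity: a city-level outcome shock $\eta_i$ (loading 0.3) is
  correlated with the adoption shock at rate `endogeneity_rho`.  The
  historical instrument base (log-normal, emulating early communication
  infrastructure density) enters *only* the adoption index, so the
  exclusion restriction holds by construction and
  $Z_{it} = \text{base}_i \times (t - t_0)$ is a valid instrument.
* Mediators $M_{mit} = a_m D_{it} + h_m(X_{it}) + e_{mit}$ with
  defaults EEQ $(a=0.30, b=0.15)$, ISL $(0.20, 0.10)$, HWS
  $(0.20, 0.10)$.
* Outcomes are generated on a linear scale by default so closed-form
  OLS oracles apply exactly.  With `index_scale = TRUE` the latent
  outcome is mapped through $0.16\,e^{y}$ and clipped to $[0,1]$,
  reproducing qualitatively the extreme right-skewed bounded shape of
  real composite health indices (mean near 0.16, long right tail); the
  clipped fraction is recorded.

What the generator does *not* emulate: spatial correlation between
cities, migration, epidemic dynamics, serially correlated confounders, or
measurement error in the indicators.  Passing tests show the estimators
work when their assumptions hold and degrade as designed when they are
violated — not that any particular real-world estimate is correct.

## Estimator settings that matter

* `n_folds` — K = 5 by default, i.e. a 4:1 train:holdout ratio per
  cross-fitting round; K = 4 and K = 8 are the 3:1 and 7:1 variants.  The
  "which side is training" ambiguity is resolved as: each fold serves
  once as the held-out prediction set.
* `learner` — `random_forest` (ranger, 500 trees, minimum node size 5,
  depth unrestricted), `gradient_boosting` (xgboost, 100 rounds, depth 3,
  learning rate 0.1) or `linear` (least squares; the exact-oracle
  reference).  The binary treatment nuisance is fit as a *regression*
  (conditional mean) and clipped to $[0,1]$: with staggered binary
  adoption, many training folds would be single-class for a classifier,
  while the conditional mean is always defined.
* `n_repeats` — independent cross-fitting repetitions; the estimate is
  the median of per-repeat $\hat\theta$ and the variance the median of
  per-repeat variances (default 1).
* `cluster_folds` — optionally assigns whole cities to folds, for
  sensitivity to fold leakage through within-city dependence.
* Fold assignment is a seeded permutation cut into near-equal contiguous
  blocks; all randomness (folds, forest seeds, bootstrap draws) derives
  from the configuration seed, so every result is exactly reproducible.

Numerical edge cases: a training fold with constant treatment falls back
to mean prediction with a warning; $\sum \hat V D = 0$ (no residual
treatment variation) is refused; the PLIV denominator below
$10^{-8} n$ triggers a weak-instrument refusal; rank-deficient linear
fits zero out aliased columns.

### A caveat on the orthogonality diagnostic

`dml_plr()` reports $\text{mean}(\hat V)$ and
$\text{cor}(\hat V, \hat m)$.  When the treatment nuisance is estimated
consistently both vanish asymptotically.  But when $\hat m$ *underfits*
(e.g. a small forest facing a weak, partly unlearnable propensity signal)
or when clipping binds, $\hat V$ retains a mechanical positive
correlation with $\hat m$ of order 0.1 regardless of implementation.  The
diagnostic is therefore a calibration check on the treatment learner, not
a validity guarantee; the tests assert near-zero correlation in designs
where the propensity is realizable and only residual centering elsewhere.

## Instrumental-variable variant

`dml_pliv()` residualizes outcome, treatment and instrument on the
controls with cross-fitted learners and forms
$\hat\theta = \sum \tilde Z \tilde Y / \sum \tilde Z \tilde D$, with the
IV influence function clustered by city, and reports the first-stage
residual correlation as a weak-instrument diagnostic.  Decisions the
source analysis leaves open: the trend origin is the year before the
first panel year (so the trend runs 1..T), and the instrument is used
unstandardized — the estimator is exactly invariant to positive scaling.
Because the endogeneity enters as a *city-level* shock, the IV
estimator's sampling noise is governed by the number of cities far more
than by panel length; the package's validation uses 300-city panels,
where the PLIV bias under $\rho = 0.5$ endogeneity is a small fraction of
the PLR bias and the PLIV estimate is closer to the truth in ~9 of 10
replications.

## Mediation

`path_a()` re-runs the partial-linear estimator with the mediator as
outcome.  `path_b()` cross-fits the three nuisances $E[Y|X]$, $E[D|X]$,
$E[M|X]$ and regresses the outcome residual on treatment and mediator
residuals *jointly* (no intercept; residuals are mean-zero up to noise),
mirroring a mechanism regression that includes both policy and mediator
— this stays inside the orthogonalized framework and delivers the b-path
and the direct effect with valid clustered scores in one step, rather
than chaining two package fits whose conditioning sets would disagree.
The indirect effect is the product of coefficients $\hat a \hat b$; the
difference estimator is deliberately not offered.

`bootstrap_indirect()` resamples whole *cities* with replacement
(within-city dependence makes row resampling invalid), re-fits all
nuisances per replicate — by default with a reduced 100-tree forest when
the main learner is a forest, to bound runtime — and reports the
percentile 2.5/97.5 interval of the replicated products.  Resampled
copies of the same city are treated as distinct clusters.  On a linear
single-mediator world, direct + indirect matches the total partial-linear
effect within Monte-Carlo error (an exact decomposition test in the
suite).

## The study pipeline

`run_full_study()` drives everything from one configuration (list or
YAML): simulate or load the panel, optionally rebuild the outcome index
from simulated indicators, prepare the design, then

1. the four-column benchmark ladder (controls; +squares; +year FE;
   +city FE),
2. the robustness suite (winsorization at 1%/99% and 5%/95% — the two
   presets corresponding to the two tail-trim conventions; province
   trends; concurrent-policy dummies; the IV column; K = 4/8; the
   gradient-boosting swap), each tagged with its sign match and distance
   to the benchmark in benchmark-SE units,
3. bootstrap mediation per listed mediator,
4. heterogeneity splits by region, city size, regulation intensity, and
   adoption batch — each batch's adopters compared against *never-treated*
   cities only, so later waves never contaminate the control group.

Stars follow the two-sided normal convention (\*\*\*/\*\*/\* at
1/5/10%).  Every stored table cell traces to a stored fit, and re-running
the same configuration reproduces every output byte-for-byte.

## Problem sizes used in the validation suite

The automated checks run at sizes chosen to keep the full suite
comfortably interactive while leaving the statistical conclusions
unambiguous: exact-arithmetic oracles at $n = 3$ and $4\times 2$;
linear-oracle equivalence at $n = 5{,}000$; RF recovery/coverage over 200
panels of 100 cities $\times$ 14 years with 100-tree forests; type-I
error over 200 linear panels; IV repair over 100 panels of 300 cities;
mediation null-coverage and power over 100 outer replications with 200
bootstrap draws each, using the linear learner on linear worlds — the
correctly-specified nuisance model there, which keeps the bootstrap's
20,000 nuisance re-fits cheap.  Reduced-forest bootstrap refits are
exercised separately in the pipeline tests.

## Known limitations

* No interactive (heterogeneous-effect) DML model and no neural or
  generalized-random-forest learners; subgroup heterogeneity is handled
  by sample splits.
* Single instrument only; no over-identification tests.
* The clustered sandwich uses no small-cluster degrees-of-freedom
  correction; with few cities (tens) the test can be mildly liberal.
* Index construction offers entropy weights (and a debug equal-weight
  mode) only.
* The real-world data pipeline of the emulated study (statistical
  yearbooks, remote-sensing environmental quality) is out of scope;
  mediators are consumed as columns.
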
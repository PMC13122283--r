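---
title: "Scoring longitudinal steroid profiles: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring longitudinal steroid profiles: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asps)
```

## The problem

The steroidal module of the athlete biological passport (ABP) tracks five
urinary steroid ratios — T/E, A/Etio, 5a-ADiol/5b-ADiol, 5a-ADiol/E and A/T —
longitudinally for each athlete. Testosterone doping perturbs several of
these ratios at once, but the ratios vary strongly both between athletes
(stable individual set points) and within athletes over time, so population
reference ranges are blunt instruments. This package condenses a whole
longitudinal profile into a single probability, the abnormal steroid profile
score (ASPS), while keeping the result interpretable: the score decomposes
into per-biomarker contributions that can be flagged individually.

The pipeline has four statistical stages, each exposed as ordinary R
functions and collectively as `run_pipeline()`.

## Stage 1 — sequence probabilities

For each athlete $i$, biomarker $k$ and occasion $t$ we model the log ratio
as

$$\log y_{i,k,t} = \theta_{i,k} + \varepsilon_{i,k,t}, \qquad
\theta_{i,k} \sim N(\mu_0, \tau^2), \quad
\varepsilon_{i,k,t} \sim N(0, \sigma^2_w),$$

a normal–normal conjugate hierarchy with known (estimated) variance
components. After $n$ observations the posterior of $\theta_{i,k}$ is
normal with mean $m_n$ and variance $v_n$ obtained by adding precisions, so
the posterior predictive for the next log measurement is
$N(m_n,\, v_n + \sigma^2_w)$. The *sequence probability* of a new
measurement is the predictive CDF evaluated at it,
$z_{i,k,t} = F_{i,k,t}(y_{i,k,t})$: values near 0 mean "much lower than
this athlete's passport expects", near 1 "much higher".

Two ordering rules matter:

* **Prequential scoring.** Each observation is scored *before* it is
  absorbed (`sequence_probabilities()`), so a measurement never informs its
  own reference range. The first observation is scored under the pure
  population prior — forced by the same rule.
* **Calibration.** Under the generating model the prequential $z$ values
  are i.i.d. Uniform(0,1). The test suite verifies this with a
  Kolmogorov–Smirnov test on $10^4$ simulated athletes; it is the
  property that makes $z$ trajectories comparable across athletes with
  different testing histories.

Hyperparameters (`estimate_prior()`) are method-of-moments on the log
scale: pooled within-athlete variance for $\sigma^2_w$, variance of
per-athlete means minus its sampling contribution for $\tau^2$ (floored at
$10^{-6}$), grand mean for $\mu_0$. The operational passport uses its own
population priors, which are not public; estimating them from the
doping-control pool is the honest substitute and is documented as such.
$z$ is clamped to $[10^{-12}, 1-10^{-12}]$ for numerical safety.
Heteroscedasticity, specific-gravity correction and confounder adjustment
are deliberately not modelled.

## Stage 2 — trajectory features

A whole trajectory (raw ratios or sequence probabilities — one *measurement
kind* per model, never mixed) is summarised by 40 base features: per
biomarker the mean, range, range of first differences and range of second
differences (5 × 4 = 20), plus the 10 pairwise covariances of levels and 10
of first differences; and the square of each, 80 in total
(`compute_feature_vector()`, names in `feature_names()`). Ranges capture
spread and extreme excursions, difference ranges capture abrupt trajectory
changes, covariances capture co-movement of ratios, and the squares let the
logistic model express U-shaped risk.

Choices the recipe leaves open, fixed here:

* sample covariance uses the $n-1$ denominator;
* feature order is means, ranges, Δ-ranges, Δ²-ranges, level covariances
  (biomarker pairs in lexicographic key order), Δ-covariances, then all
  squares in the same order — fixed so serialised models are reproducible;
* occasions with any missing ratio are dropped whole (complete-case by
  occasion) to keep the five series aligned for covariances;
* at least 4 complete occasions are required (more than three measurements),
  which also guarantees the second-difference range exists.

The published description of this feature set states a larger total feature
count (400) than its own enumerated recipe yields (40 base + squares = 80
per measurement kind, 160 over both kinds); the enumerated recipe is what
is implemented, and the discrepancy is surfaced here rather than silently
reconciled.

## Stage 3 — weighted logistic regression

`fit_asps_model()` standardises each feature (training mean 0, sd 1;
zero-variance columns dropped with a warning) and maximises the weighted
Bernoulli log likelihood by Newton/IRLS to gradient norm $10^{-8}$ (max 100
iterations, step-halving). The fitted probability is the ASPS. Design
choices:

* **Weights.** Laboratory athletes are *known* dopers; doping-control
  athletes are labelled only by a later sanction, so their positive label is
  noisy and their negative label noisier. Laboratory athletes therefore
  carry weight 20 in the loss, doping-control athletes weight 1. An
  integer-weighted fit is exactly a fit on replicated rows (tested).
* **Standardisation** is not part of the published recipe but is required
  for stable Newton steps across features whose natural scales differ by
  orders of magnitude; predictions are invariant to it (tested).
* **Ridge.** A tiny ridge ($10^{-8}$, slopes only, switchable) guards
  against perfect separation, which is *likely* on small synthetic cohorts
  with strong injected effects. It is numerical armour, not regularisation:
  with separation the fit still saturates (non-convergence is warned with
  diagnostics) and attribution magnitudes become large; a real doping-control
  cohort of thousands of athletes with noisy labels does not separate.
* **Selection.** `select_variables()` does backward elimination on Wald
  p-values down to a target of 21 regressors (the size of the published
  selected model), refitting at each step; ties — e.g. exact duplicates —
  break by dropping the lexicographically last name. The published work says
  only that "some variable selection" was performed; this mechanism is a
  documented default, not a claim about the original procedure.
* **Cross-validation.** `make_cv_plan()` deals positives and negatives
  round-robin into K = 5 folds after a seeded shuffle, so positives split
  as evenly as integers allow. Laboratory athletes join every training set
  and are never scored; the AUC is computed on out-of-fold doping-control
  athletes only. For per-occasion protocols, `max_score_per_athlete()`
  collapses occasion scores by the maximum.

## Stage 4 — source attribution and thresholds

The linear predictor (minus intercept) is split by `decompose_lc()` into
sources: each single-biomarker feature contributes to that biomarker's LC
(linear combination), every covariance feature to a pooled LC-Cov. The LCs
sum to $\mathrm{logit}(\mathrm{ASPS}) - \beta_0$ exactly; the intercept
belongs to no source. A source is flagged when its LC exceeds 0.8
*strictly* — the published wording is "larger than 0.8" — which corresponds
to an odds multiplier of $e^{0.8} \approx 2.2$.

One deliberate extension: the five-source summary of the published selected
model (which contains no A/T regressor) is completed with an `lc_at` column
so the additivity identity holds for *any* model on the 80-feature schema;
`lc_at` is identically zero whenever A/T features are absent.

`calibrate_thresholds()` chooses, for each false-positive-rate target, the
*smallest* score threshold whose empirical FPR (fraction of negatives
strictly above it) stays at or below the target — the choice that maximises
TPR subject to the FPR cap, and the only reading consistent with
FPR-vs-threshold monotonicity. Targets below $1/n_{\text{neg}}$ are
unattainable and produce a warning row at the zero-FPR threshold.

## The synthetic cohort

No doping-control or laboratory steroid data are shared with the published
work, so the package carries a generative stand-in (`simulate_cohort()`)
built from the same hierarchy Stage 1 assumes plus an additive intervention
model:

$$\log y_{k,t} = \mu_{0,k} + b_k + e_k\, d(t) + \varepsilon_{k,t},$$

with athlete intercepts $b_k \sim N(0, \tau_k^2)$, noise
$\varepsilon \sim N(0, \sigma^2_{w,k})$, and a dosing profile $d(t)$ that is
0 at baseline, 1 while dosing and decays as $2^{-s/h}$ over washout
occasions (half-life $h = 3$ occasions by default — washout is described in
the source studies but given no kinetic form; exponential decay is the
minimal monotone choice). Doped trajectories always include baseline and
washout occasions, mirroring how the laboratory trajectories were used
whole.

The regime effects for the transdermal, placebo and two 200-mg
intramuscular arms are the published mixed-model estimates (e.g. +2.53 on
log T/E for the first intramuscular injection); the three weekly-injection
arms (50/75/100 mg) have no printed estimates and use package defaults that
reproduce the reported dose ordering. Effects are treated as natural-log
additive. The athlete-level response $e_k$ varies around the regime effect
(SD 0.3 for T/E and 5a-ADiol/E, 0.1 otherwise), with the T/E and 5a-ADiol/E
responses correlated at $\sqrt{0.52} \approx 0.72$ — the one response
correlation reported. Population means, between- and within-athlete SDs
(log scale 0.5 / 0.3 around typical ratio levels T/E ≈ 1, A/Etio ≈ 1,
5a-ADiol/5b-ADiol ≈ 0.9, 5a-ADiol/E ≈ 5, A/T ≈ 40) are realistic
order-of-magnitude choices, fixed once and documented here — no printed
variance components exist to copy.

What a green test on this cohort establishes: the machinery is internally
consistent (calibrated sequence probabilities, exact feature definitions,
correct optimisation, additive attribution) and the pipeline detects the
injected effects with chance-level behaviour when effects are zero. What it
does not establish: real-world discriminative performance — the synthetic
world has no label noise in its clean athletes, no confounders (diuretics,
5a-reductase inhibitors, ethanol), no assay drift, and no adversarial
dosing behaviour, all of which depress the published out-of-sample AUCs
(0.67/0.75) well below what strong laboratory effects produce here.
Published results that depend on the unshared laboratory and doping-control
datasets (their AUC tables, fitted coefficients, flag tables and threshold
table) are out of reach at desk scale and are not claimed.

Two testing conventions worth noting: zero-effect (null) worlds match the
trajectory length of doped and clean athletes, because trajectory length
itself is information the classifier would otherwise exploit; and
dose-response comparisons use cohorts large enough (150 positives) that
Mann–Whitney noise cannot swamp the ordering of adjacent effect sizes.

## Numerical conventions

* Sequence probabilities are clamped to $[10^{-12}, 1-10^{-12}]$; the ASPS
  is nudged inside $(0,1)$ only at machine precision (a saturating linear
  predictor would otherwise round to exactly 0 or 1), which preserves the
  score ordering that AUC and threshold calibration rely on. Variance
  estimates are floored at $10^{-6}$.
* IRLS: gradient tolerance $10^{-8}$, 100 iterations, step-halving, weights
  floored at $10^{-10}$ in the working Hessian, Cholesky solve with a
  jittered retry.
* Flags use strict inequality; threshold calibration uses strict
  "score > threshold" flagging throughout, so `n_flagged` always equals the
  direct count.
* All randomness (simulator, fold assignment) flows through explicit seeds;
  package functions restore the caller's RNG state.
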
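---
title: "Rule-set niche models and the Unimportance Index: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-set niche models and the Unimportance Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

garpui models species' geographic distributions from presence-only records
with a genetic algorithm that evolves populations of if/then rules, and then
asks a question most rule-set engines leave unanswered: *which environmental
variables did the model actually use?* Its answer is the Unimportance Index
(UI), computed from the dominant presence rules of a best subset of models.
This vignette explains the model stack, the estimator, the virtual-species
benchmark used to validate it, and the design decisions taken where the
method family leaves details open.

## The rule-set engine

A model is an ordered set of 50 if/then rules over the covariates. Four rule
archetypes are supported:

* **range** — an envelope: fires when every constrained covariate lies inside
  its inclusive `[lower, upper]` interval;
* **negated range** — the complement of an envelope;
* **logit** — a logistic-regression superset over all covariates: fires when
  `plogis(intercept + sum(coef * x)) > 0.5`;
* **atomic** — exact covariate values, matched within half of a binning
  tolerance (covariates are discretised to 254 levels, mirroring the 8-bit
  grids of classic desktop implementations).

Rules carry a consequent (presence or absence). Projection applies the rules
to every cell in stored order, first match wins, and cells matched by no rule
are conservatively predicted absent (with rule index -1, so the deciding rule
of every cell is recoverable).

Training is presence-only. Each generation draws an internal resample — 1,250
presence draws with replacement from the training points and 1,250 uniform
background cells standing in for absences — and scores every rule by a 2x2
chi-square (rule fires x label, no continuity correction). Rules with
chi-square below 3.84 (alpha 0.05 at 1 df) are non-significant. Evolution is
a (mu + lambda) scheme: an oversampled batch of offspring is bred by
crossover (rate 0.25), bound mutation (0.25), constraint insertion (0.1) and
deletion (0.1), with the remainder fresh random rules, and the next
population is truncation-selected from the union of parents and offspring.

Three design choices here deserve explanation, because we found the obvious
alternatives fail quietly:

* **Selection fitness is the chi-square statistic, not raw accuracy.**
  Accuracy-ranked selection converges on narrow rules that are precise on a
  handful of samples; chi-square rewards association *and* coverage, so
  broad informative rules win.
* **Selection honours per-archetype quotas** (range 0.4, logit 0.2, atomic
  0.2, absence-consequent 0.2 of the population). Without quotas the
  all-covariate logit fits — the strongest single classifiers — take over
  the entire population within a few generations, and the ruleset
  degenerates into fifty near-copies of one logistic regression. The quotas
  keep the archetypes in competition, which matters doubly because the
  contribution estimator below reads its signal mostly from envelope rules.
* **A directed refinement operator complements the blind operators.** Each
  generation, the top presence envelopes spawn candidates in which one
  covariate — free or already constrained — is (re)constrained to its 10–90%
  quantile window among the training presences that satisfy the rule. Blind
  insertion discovers the conditional envelope of a second driver with
  probability of only a few percent per attempt, so without this step
  multi-driver envelopes essentially never form and the second and third
  drivers of a species stay invisible to the prevalence term of the UI.
  Refinement candidates enter the same truncation selection as everything
  else and survive only where the added constraint raises the chi-square.
* **Projection order is descending chi-square** (accuracy breaks ties).
  Ordering by accuracy lets atomic micro-rules decide first and fragments
  each model's presence predictions across dozens of rules; significance
  ordering concentrates the decisions in each model's few dominant rules,
  which is both what classic rule listings look like and what the
  contribution estimator needs.

Evolution stops at `max_iterations` (default 1,000) or at convergence
0.01, measured as the change in the whole ruleset's predictive accuracy
(first-match-wins, in fitness order) on a monitor sample drawn once per
model. Two details matter: the population *mean* rule accuracy is useless as
a convergence signal (the retained elite dominates it and it moves by less
than 0.01 after one generation), and measuring on fresh resamples each
generation makes the delta mostly resampling noise (the standard error of an
accuracy on 2,500 points is itself about 0.009). A fixed monitor sample
makes the delta reflect genuine ruleset change.

An experiment trains `n_models` (default 200) independently seeded models,
each with its own internal 75%/25% split of the presences. A model's
*extrinsic omission* is the percentage of its internal test presences it
predicts absent; its *commission* is the percentage of landscape cells it
predicts present. The *best subset* keeps the 20 lowest-omission models at
or below 10% omission, computes their median commission, and retains the 10
with commission closest to that median; their binary maps are summed into a
0–10 agreement raster.

## The Unimportance Index

The estimator reads the best subset's *dominant presence rules*: pool every
rule that decides presence for at least one cell across the 10 projections,
measure each rule's coverage as its share of the pooled presence
cell-decisions (a cell predicted present by 4 models contributes 4
decisions), sort by coverage, and keep the smallest prefix cumulatively
covering *more than* 90% of the presence decisions.

For each covariate *k*:

* **prevalence** = fraction of dominant rules whose condition references
  *k* (a logit rule references every covariate with a fitted coefficient;
  a tolerance can exclude near-zero coefficients);
* **median range** = median of the rules' upper bounds minus median of the
  lower bounds for *k*, where range rules contribute stored bounds, atomic
  rules their atom as a zero-width interval, and logit rules the zonal
  minimum/maximum of *k* over the cells they decide;
* **scaled median range** = median range divided by the covariate's full
  landscape range, clipped to [0, 1] (a min–max alternative across
  covariates is available by configuration);
* **UI** = (1 − prevalence) x scaled median range, then min–max rescaled
  across covariates to [0, 1].

Low UI means important: the model either uses the covariate in most of its
dominant rules, or constrains it tightly, or both. Covariates never
referenced by any dominant rule get prevalence 0 and scaled median range 1 —
the model left them maximally unconstrained. The UI formula uses the
*scaled* median range (the unscaled one is not comparable across covariates
with different spans). Variable selection keeps covariates with rescaled UI
strictly below a threshold (0.5 by default); an empty selection falls back
to the single lowest-UI covariate, with a warning.

## The virtual-species benchmark

Because no real species comes with known drivers, the validation harness
builds species whose drivers are known.

The landscape is a 10.5 x 10.5 degree planar grid carrying ten independent
zero-mean, unit-sill Gaussian random fields: five with an exponential
variogram (range parameter 10 degrees) and five spherical (range 6 degrees),
nugget 0. Fields are simulated by circulant embedding: the covariance is
embedded on a torus with generous padding (six ranges for the exponential
model), its FFT eigenvalues are clamped at zero where the embedding is
numerically indefinite (the clamped mass is kept below 0.1% and the spectrum
renormalised to preserve the sill), and one FFT of complex Gaussian noise
yields an exact draw. Distances are planar Euclidean in degree units — the
landscape is an abstract stage, not a map — and "range" is the model's range
*parameter* (for the exponential model the effective range is about three
times larger).

Each species draws 3 true covariates without replacement and coefficients
from Normal(1, 0.5) (the *weak* scenario) or Normal(5, 0.5) (*strong*); its
occurrence probability is the ridge-shaped niche
`P = exp(-(b1 x1 + b2 x2 + b3 x3)^2)`, maximal where the linear combination
is zero, with no intercept. A cellwise Bernoulli trial realizes the binary
distribution, and 50 presence points are sampled without replacement from
presence-cell centroids. Realizations with fewer than 50 presence cells are
rejected and redrawn with the next derived seed (logged); every species
records its variable, coefficient, realization and sampling seeds.

The simulator emulates smooth, spatially autocorrelated covariates and a
niche with a single ridge. It does **not** emulate observation error,
sampling bias, dispersal limitation, interactions between abiotic and biotic
drivers, or covariates with real-world marginal distributions; a passing
benchmark therefore demonstrates that the estimator recovers known drivers
under clean conditions, not that it is robust to messy survey data.

Two statistical subtleties shaped the simulator's tests. With a range
parameter comparable to the domain, single realizations are far from
ergodic: the sample variance within one field realization is well below the
sill, and two independent fields can show sample correlations of +-0.5. The
tests therefore check marginal moments pooled across replicate seeds, and
check independence either on short-range fields (many effective patches) or
as an average over many pairs.

## Scoring against the random-draw null

For each simulated species the three lowest-UI covariates are compared with
the three true drivers; the overlap *r* (0–3) is tallied over species. If
selection were blind, *r* would follow the hypergeometric distribution of a
random 3-subset of 10 — probabilities (35, 63, 21, 1)/120, so r >= 2 would
occur 18.3% of the time. The tallies are tested with a one-tailed (upper
tail) Pearson chi-square against the *unrounded* expected counts — with
rounded expectations the published statistics are not recoverable — and the
weak and strong scenarios are compared with a 2xR homogeneity chi-square
without continuity correction.

The packaged study runs at desk scale: a 105 x 105 grid at 0.1 degrees (the
same extent as the full 1050 x 1050 benchmark at 100x fewer cells), around
30 species split between the scenarios, and an engine reduced to 50 models
per species capped at 200 iterations. These sizes are the package's default
benchmark configuration; the full-scale study (200 species, 200 models,
1,000 iterations) is available through the same functions. At desk scale the
pooled recovery rate sits around 70% of species with r >= 2 — in line with
the two-thirds headline reported for the full-scale experiment — and the
goodness-of-fit against the random-draw null is decisive.

Accuracy metrics for agreement rasters (total/average omission, total/average
commission, and a trapezoidal ROC/AUC over the 0..10 agreement thresholds)
use the Hanley–McNeil standard error for the AUC, with a z-score against the
chance value 0.5; the method behind the published standard errors is not
named, and Hanley–McNeil is the conventional choice.

## Numerical and interface choices

* Coordinates are cell centroids; matrices store row 1 at the north edge and
  cells are numbered row-major. The one convention is asserted in tests
  because silent row-flips are the classic raster bug.
* Internal and external train/test splits default to round-half-up for the
  training size (`floor(0.75 n + 0.5)`), with a round-down variant. For 657
  points these give 493 and 492 training points; published splits of
  657 into 491/166 match neither convention exactly, so the rounding rule is
  exposed rather than hard-coded.
* Rule significance, operator rates, resample sizes and the subset
  parameters are all exposed in `garp_params()`; the defaults are the
  benchmark configuration.
* Rulesets serialize to JSON (lossless) and to a human-readable
  `IF ... THEN species=PRESENCE` listing with `(lower,upper)` bounds; a
  parser reads the listing back.
* Rasters are read and written as ESRI ASCII grids with a JSON sidecar for
  grid and variogram metadata.
* The chi-square goodness of fit drops categories the null makes impossible
  (relevant only when the covariate set is smaller than twice the number of
  drivers) and reduces the degrees of freedom accordingly.
* Degenerate cases are defined, not left to chance: all-equal UIs rescale to
  all zeros with a warning; a constant covariate is an error for the scaled
  median range; rules firing nowhere are flagged and never significant;
  an empty variable selection returns the lowest-UI covariate with a
  warning; fewer than 10 qualifying models yield a short subset with a flag.

## Known limitations

The engine is a faithful member of the genetic rule-set family, not a
bit-compatible reimplementation of any desktop binary: per-model rulesets,
omission/commission values and published tallies that depend on a specific
binary's private internals are not reproducible run-for-run, and the
validation targets distributional behaviour (recovery rates, test
statistics) instead. The simulator's independence and variogram guarantees
are statistical, verified over replicate seeds. UI inherits the estimator's
blind spots: a driver that acts only through interactions with another
covariate can hide, and strongly collinear covariates share their
contribution. Anisotropic or non-Gaussian fields, map projections, and
niche shapes other than the single ridge are out of scope.
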
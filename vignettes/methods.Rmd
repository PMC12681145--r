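---
title: "Models and methods behind brtsdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind brtsdm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical choices made where the design was genuinely
open. It states no empirical result that the test suite does not itself
compute.

## 1. The modelling problem

Habitat suitability for ectothermic vectors is driven by long-term climate
and by land use. The pipeline models a binary suitability state per grid
cell from:

* **Climatological predictors** — the 19 BIOCLIM variables (monthly means
  of daily mean/min/max temperature and monthly precipitation sums,
  summarized into annual statistics and extreme quarters), 18
  extreme-threshold variables (counts `ND` and longest runs `LP` of days
  beyond fixed temperature/precipitation thresholds), and absolute humidity
  from dewpoint. Each is computed per calendar year and then averaged over
  a 31-year window ending at the target year, because long-term climatology
  — not any single year's weather — governs whether a mobile species can
  establish.
* **Land-use predictors** — 14 class fractions for the target year only:
  land-use change acts locally and immediately, so no windowing.

The response is a presence/pseudo-absence label derived from a
probability-of-presence raster binarized at 0.5 (the boundary counts as
presence). True absences are unobserved; pseudo-absences are a modelling
device, and their selection is one of the two ensemble axes.

## 2. Boosted regression trees

The base learner is stagewise gradient boosting of shallow regression trees
with Bernoulli (logistic) loss, implemented in compiled code:

* trees are grown best-first with a fixed number of splits (the *tree
  complexity*, an interaction-depth control), minimum 10 observations per
  leaf;
* each tree fits the gradient residuals of a bagged half of the calibration
  rows (bag fraction 0.5) and its leaves take one Newton step, scaled by
  the learning rate;
* the number of trees is selected by 10-fold cross-validation: folds grow
  in lockstep in increments of 50 trees, the mean held-out deviance is
  tracked per increment, and growth stops once the running minimum is six
  increments old. The final model is refit on the whole calibration half at
  the deviance-minimizing count.

**The adaptive tuning loop** starts from learning rate 0.15 and tree
complexity 5 and enforces a selected tree count in [1200, 2000]: too few
trees means the model learns too fast, so the learning rate is halved; too
many means it learns too slowly, so the rate is multiplied by 1.5. The
multipliers are design choices (the contract only says
"decreased/increased accordingly"). Tree complexity moves by one step,
clamped to [3, 10], only after three consecutive same-direction failures of
rate-only moves — complexity changes the interaction order of the fitted
surface, so it is the lever of last resort. If the iteration cap is reached
the best model so far is returned flagged, never an exception.

Within a 16-member ensemble, the re-tune of a *reduced* predictor set warm
starts from the full model's tuned rate and complexity (configurable off).
The enforced window is identical either way; the warm start only removes
redundant loop iterations, since a model on a predictor subset of the same
sample almost always lands at a nearby learning rate.

**Contributions** are percent shares of accumulated split-gain.
**Interaction strength** of a predictor pair is 1000 x the residual
variance of a main-effects-only surface fitted to the model's link-scale
predictions on a complete 20 x 20 quantile grid of the pair (other
predictors at training medians). On a complete balanced grid the
main-effects fit is exactly the additive row-mean + column-mean
decomposition, so an additive pair scores numerically zero.
**Response curves** are partial dependence over the 1st-99th percentile
range with co-predictors fixed at training medians (the fast variant;
downstream consumers use response *differences*, which are robust to this
marginalization choice). **Simplification** drops predictors whose removal
barely changes the cross-validated deviance: candidates are assessed in
ascending contribution order by a fixed-hyperparameter CV refit at the
selected tree count, and the process stops at the one-standard-error rule.
Assessing every possible removal each round would cost O(p^2) CV fits;
contribution-ordered candidates are the established practical surrogate.

## 3. Background selection and evaluation

Four pseudo-absence strategies: *random* (any cell with probability <
0.5), *sampled* (stratified so the absence sample's dominant land-use-class
composition matches the domain's, within 1% per class — "dominant class"
operationalizes the contract's undefined "main land-use classes"),
*buffered* (only probability-0 cells; the 0 < p < 0.5 ring is an excluded
buffer), and *sampled+buffered*. Nominal sizes are 10,000 presences and
10,000 absences; with fewer presences available, 75% of them are used and
absences are topped up towards a 20,000 total (additionally capped by the
eligible-cell count, since sampling is without replacement — on a
1,600-cell synthetic domain the cap always binds, with a warning).

The sampled points are split 50/50 into a calibration half and a held-out
evaluation half. The source text conflates this split with the boosting bag
fraction; this package implements both — bag fraction 0.5 inside the
booster *and* an external 50/50 holdout for skill — because skills computed
on training rows would be optimistic.

Skills on the holdout: TSS at the max-TSS threshold; AUC and Cohen's kappa
after spatial-sorting-bias removal by point-wise distance sampling
(each test presence paired with the unused test absence whose
distance-to-nearest-calibration-presence matches its own within a factor
0.33, great-circle on cell centres; kappa shares the max-TSS threshold);
Brier skill against the base-rate reference, floored at 0. The overall
model skill averages TSS, chance-rescaled AUC, kappa and BSS; a
three-metric variant (without BSS) is available because the published
best-model table's footnote describes OMS that way while the displayed
formula includes BSS — the formula wins here, the variant is a switch, and
no acceptance number depends on OMS alone.

The area of applicability follows the dissimilarity-index construction:
contribution-weighted, standardized Euclidean distance in predictor space
to the nearest calibration point, normalized by the mean pairwise
calibration distance; the threshold is Q3 + 1.5 IQR of cross-validated
calibration DIs; AoA is the fraction of unmasked cells at or below the
threshold. The composite SCORE is the Euclidean distance of (OMS, AoA)
from the origin divided by sqrt(2); the best model is its argmax, ties
broken by higher AoA then lower setup id.

## 4. Attribution and per-cell importance

Projections binarize at each model's max-TSS threshold (configurable to
0.5): the observation side is binarized at 0.5, but model predictions are
binarized at the threshold that maximizes TSS, consistently with the skill
computation. The (REF, CLU, VLU) triple classifies each cell into eight
categories; net change counts only flips relative to REF (retention
categories RPLUC/RALUC are reported separately because their status equals
REF's). When only the combined effect flips a cell, the triple logic lands
it in a land-use category — land use acts locally and directly, climate
slowly and at scale.

Per-cell importance: `(CON_N + CON_N * INT_N) * R_N` per predictor, winner
takes the cell. Normalization axes are a documented choice where the
contract says only "feature scaling": CON and INT are per-model scalars
scaled min-max across the group's predictors; |response delta| is scaled
jointly across cells x predictors, anchored at zero (divided by the joint
maximum) rather than min-max, because the construction requires a zero
response change — and only a zero change — to score exactly zero, and the
joint minimum of |delta| is not zero in general. Per-predictor scaling is
the obvious alternative for R; it would erase between-predictor magnitude
information at a cell. Degenerate ranges scale to 1 for
CON (a lone predictor keeps a positive score) and 0 for INT (no interaction
bonus when all sums are equal). The percentage divides the winning score by
the sum of strictly positive scores at the cell; all-zero cells are "no
MIP" — no change, or no important predictor, gives a zero product by
construction. The MIPC adds a sign filter: presence-gaining categories
admit only positive response deltas, absence-gaining only negative;
stable cells rank unsigned. For the retention categories the contract does
not spell the rule out; gain/loss direction is mirrored (RPLUC with the
gaining, RALUC with the losing set) and flagged as a choice. Ties at the
argmax break by higher scaled contribution, then predictor name.

## 5. The synthetic world

The generator emulates the statistical structure the analysis assumes — it
is a stated world, not a fit to any real dataset:

* **Climate**: daily, 365-day calendar (hourly inputs are only ever used as
  daily aggregates, and the leap-day bookkeeping buys nothing); latitudinal
  baseline gradient (~0.7 degC per degree), seasonal amplitude growing
  poleward, linear warming trend (default 0.4 degC/decade, a
  Mediterranean-hotspot-like recent rate), AR(1) daily noise (sd 2 degC,
  rho 0.7), winter-peaked wet-day probability with gamma wet-day amounts
  (realistic dry spells for the extreme variables), dewpoint = temperature
  minus a non-negative depression. Physical orderings (tmin <= tmean <=
  tmax, dewpoint <= tmean, precip >= 0) hold by construction.
* **Land use**: 14 classes from spatially smoothed log-abundance fields,
  normalized per cell; each year moves a fraction `drift_rate` (default
  0.01) towards a fixed target composition, bounding per-year
  total-variation drift by `drift_rate`.
* **Species map**: logistic link over a known truth — a unimodal BIO1
  optimum (15 degC), a saturating BIO12 ramp (500 mm midpoint), an
  increasing urban-fraction ramp — with the intercept bisected so ~40% of
  unmasked cells are presences (both classes populous). Probabilities
  below 0.05 truncate to exact 0, emulating atlas rasters that are exactly
  zero outside the modelled range and giving the buffered background method
  a feasible set. A fixed random sea blob (20% of the domain) is masked.
* **Default domain**: 5W-5E / 35N-45N at 0.25 degrees (1,600 cells), years
  1970-2020 — desk-scale; the full 0.1-degree study domain is a
  configuration choice, exercised only for its geometry.

What a green test does **not** establish: the generator has no spatial
autocorrelation calibrated to any real species atlas (its smoothing scale
is a free parameter), no orography, no hourly processes, no observation
error model beyond logit noise, and the desk-scale domain forces calibration
samples of ~10^3 rather than 2 x 10^4 points. Green means the *procedures*
are correct on a world where ground truth is known — not that real-data
results would be reproduced.

## 6. Numerical choices and degenerate inputs

* Quarters are all 12 wrap-around consecutive 3-month windows from the same
  year's months (the WorldClim convention); ties resolve to the earliest
  start month. BIO3 is set to 0 with a warning where BIO7 = 0 (constant
  climate); BIO temperatures are degrees C, not degrees C x 10.
* Whether extreme variables are window-averaged like the BIOs is not
  stated in the source; they are computed per year and averaged over the
  same 31-year window, consistent with the climatological reasoning, and
  the registry (whose exact published definitions are unavailable) ships
  as an overridable 18-entry default over the named threshold families,
  ordered so the longest wet period (> 20 mm) is EXV15 as the results
  name it.
* Deviance is `-2 * mean(y*f - log(1 + exp(f)))` on the link scale with a
  softplus guard; the null model's deviance equals the closed-form
  Bernoulli deviance at the base rate (tested).
* All randomness derives from one master seed split into named substreams
  (a multiplicative string hash onto [0, 2^31 - 2]), so any stage can be
  reproduced in isolation; identical seeds give bit-identical outputs.
* Exhausted strata in stratified absence sampling reallocate
  proportionally with a message; single-member candidate pools bypass
  `sample()`'s scalar pitfall.
* `remove_ssb` processes presences in ascending distance order and matches
  greedily; if nothing is matchable it errors advising a larger tolerance
  rather than returning an empty evaluation set.

## 7. Known limitations

* The boosting engine is bespoke (no gbm/xgboost in the toolchain):
  algorithmically standard, but without gbm's monotonicity options or its
  exact tie-breaking; all layered procedures (CV tree search, tuning loop,
  simplify, interactions, partial dependence) are this package's own and
  are oracle-tested.
* simplify assesses contribution-ordered candidates (shortlist
  configurable), not every possible drop; inside ensembles the assessment
  uses a 4-fold subset of the 10 folds. Both are runtime levers documented
  above and do not affect the final re-tuned model's contract.
* The area of applicability uses the model's CV folds for its threshold
  rather than refitting fold models, and subsamples the pairwise-distance
  denominator above 1,000 calibration points.
* CLU/VLU attribution inherits the binarization threshold's step
  behaviour: cells near the threshold can flip category under tiny
  probability changes; ensemble quantiles are the intended smoothing.
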
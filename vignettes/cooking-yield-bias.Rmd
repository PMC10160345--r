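---
title: "Modelling cooked-food micronutrient profiles: yield bias, scaling and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cooked-food micronutrient profiles: yield bias, scaling and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutricook)
```

## The problem

Food composition tables report nutrient content per 100 g of the food *as
analysed*. Cooking changes the mass of a food: boiling and steaming add
water (yield Y > 100 g cooked per 100 g raw), roasting, grilling and
broiling drive off water and fat (Y < 100). Because the yield is not
recorded in composition tables, comparing a raw and a cooked record of the
same food confounds two things: the true nutrient retention r (the fraction
of the nutrient's mass that survives the process) and the per-100 g
renormalization 100/Y. For a non-water component X,

cooked[X] = r(X) · raw[X] · 100 / Y .

Under dry heat (Y < 100) this produces the *concentration anomaly*: a
nutrient can read higher per 100 g in the cooked food than in the raw food
even though a tenth of it was destroyed. Under wet heat it produces a
dilution of the same kind in the other direction. Any model trained to map
raw composition to cooked composition inherits this bias, and so does the
standard practice of multiplying raw content by a retention factor (RF)
from a published table.

`nutricook` implements a pipeline for this problem: curation of raw/cooked
single-ingredient pairs from SR-Legacy-style tables, two corrections for
the yield bias, per-nutrient anomaly filtering, per-(process, nutrient)
regression with grid-search cross-validation and sequential feature
selection, RF baselines, and — because the real curated dataset cannot ship
with a package — a synthetic data generator with known yields and
retentions against which every stage is validated.

## The two scaling methods

**Solid-content scaling (SCS)** assumes water and fat contents are
unchanged by cooking and forces the raw profile to match them. For each
equalized component e (water, then total fat) it sets R′[e] = C[e] and
rescales every not-yet-equalized component by

1 + (R[e] − C[e]) / Σ R[X],

where the gram-basis sum runs over the mass-bearing components (protein,
carbohydrate, fiber, fat; water excluded in the water pass) that have not
yet been equalized. Three numerical decisions make this operation exact:

* **Gram basis.** Components are reported in g, mg or µg; the denominator
  is computed in grams, so that the redistributed difference is a mass and
  the gram total of the mass-bearing components is conserved identically.
* **Micronutrients ride along.** They receive the same multiplicative
  factor (their proportions are preserved) but are excluded from the
  denominator — their total mass is sub-gram, so including them changes
  nothing at tolerance while excluding them keeps the conservation proof
  exact.
* **Frozen components.** Once equalized, a component is excluded from all
  later rescaling and denominators. Under this rule the result is
  *identical* for the orders (water, fat) and (fat, water) — without it,
  order invariance and conservation both fail. The package asserts both
  properties to 1e-9 relative over thousands of random pairs.

**Process-invariant nutrient scaling (PINS)** estimates the missing yield
from a component assumed to survive cooking unchanged — cholesterol, which
is bound in muscle-cell membranes and resistant to cooking loss. The
scaling factor is ρ · R[chol]/C[chol] (ρ = assumed retention, 1 by default,
0.95 as a sensitivity variant for a small experimental loss), every cooked
amount is multiplied by it, and 100 × factor is an explicit yield estimate.
On noise-free synthetic data with a conserved invariant this recovers the
true yield exactly; with 5% assay noise on both profiles the yield error
has median ≈ 4.8% (two 5% log-normals compound to √2 · 5% ≈ 7% log-sd,
whose folded median is 0.6745 of that), which is why the package's
validation bound is 8%.

Applying either method twice is a modelling error; both operations warn
when the variant label shows the data are already scaled (SCS is a no-op,
PINS would square the factor).

**Anomaly filtering.** After scaling, a pair is anomalous for a nutrient if
the cooked amount still exceeds the raw amount strictly; ties count as
non-anomalous so that noise-free identity cases are retained. Models on
scaled variants are trained per nutrient on the non-anomalous subset; the
unscaled arm is deliberately left unfiltered, as the reference condition.
Both scaling and filtering are per-pair transformations with no cross-pair
statistics, so applying them before cross-validation leaks nothing across
folds.

## The modelling harness

Every model maps the 27 raw-food components (water, 7 macronutrient
aggregates, 9 vitamins, 10 minerals; cholesterol is used by PINS but is not
a feature) to the cooked amount of one micronutrient, separately per
process class — wet- and dry-heat chemistry differ, and in this kind of
data food source and process are confounded, so pooling is refused rather
than configurable. Fourteen micronutrients are modelled for wet heat; for
dry heat vitamin C is excluded (meats are not a source), giving 27 models
per variant set.

Model selection is an exhaustive grid search over six families — LASSO,
elastic net, decision tree, random forest, gradient boosting, and a small
multilayer perceptron — under seeded k-fold CV with folds shared across
candidates. The compact default grid has 35 candidates and a wider one 144;
the candidate count is always reported, and the per-candidate score table
is persisted so the winner can be re-derived as its argmin (ties break to
the first candidate in deterministic grid order). For the penalized linear
families and the MLP, features and target are standardized *inside* the
training folds (glmnet internally; explicitly for the MLP); tree families
are fit unscaled. The target is standardized for the penalized fits so one
lambda grid serves nutrients whose units differ by three orders of
magnitude.

"Bootstrapped 50 times" is interpreted as 50 repetitions of re-shuffled
k-fold CV (the study conditions use 5 repetitions at desk scale), with a
switch for true bootstrap resampling with out-of-bag evaluation. Metrics
(RMSE, R², Pearson, Spearman) are computed per run on out-of-fold
predictions and summarised as mean ± sd; pooled out-of-fold predictions are
retained because per-category R² on modest group sizes is only meaningful
pooled. R² may be negative (worse than predicting the mean); that is
reported, not clipped.

Sequential feature selection is greedy backward elimination by CV RMSE
(forward available): the rank of a feature is its elimination order
reversed, rank 1 being the last survivor. On synthetic data the planted
dependence — each nutrient's cooked amount is driven by its own raw amount
— is recovered as rank 1.

**Baselines, on the same scale.** RF100 predicts the raw amount unchanged;
the RF-table baseline predicts rf × raw amount with rf looked up per
(group, process, nutrient), and unresolvable keys are omitted and logged,
never silently defaulted to 1. Both baselines take "raw amount" from the
variant's own design matrix (R′ for SCS, R otherwise) and are evaluated
against the variant's own target, so model and baseline always see
identical rows and scales; mixing scales would corrupt the relative-error
comparison. Win/loss tallies and the relative improvement
(baseline − model)/baseline × 100 are recomputed from the persisted
per-nutrient table.

Arm comparisons use a paired two-sided Wilcoxon signed-rank test on
per-nutrient RMSEs (exact for n ≤ 20), with an exact sign-flip permutation
test and a paired t-test as alternatives; anomaly-fraction comparisons use
a two-proportion z-test with Fisher's exact test at small expected counts.

## What the synthetic world emulates

The generator draws, per category, raw profiles with mass closure enforced
by construction: the five mass-bearing components are renormalized onto the
100 g simplex, fat sub-fractions follow total fat, micronutrients are
log-normal with category-specific means. Cooking applies a per-pair yield
drawn uniformly from the process-class support — above 100 for wet heat,
(60, 95) for dry heat — and per-(category, component) retentions; the
cooked water content closes the mass balance at exactly Y grams, so the
cooked per-100 g profile sums to 100 before noise. Nine categories mirror
the curated data (leafy greens, roots, vegetables, legumes, cereals; beef,
lamb, chicken, veal), with plant categories cooked by wet heat and animal
categories by dry heat — reproducing, deliberately, the source/process
confound of the real dataset.

Choices a reader should know about, with their rationale:

* **Dry staples.** The legume and cereal categories are paired from the dry
  state (raw water 20 and 11 g/100 g), as dried pulses and grains are in
  composition tables. This matters: for fresh watery produce the raw–cooked
  water difference is 1–3 g and water equalization carries little signal,
  while for dry staples it is 20–60 g and dominates.
* **Per-component measurement noise.** Reported amounts of both profiles
  are perturbed log-normally with assay-realistic CVs: moisture 1%,
  proximate macronutrients 2–3%, micronutrients 5%, cholesterol 3% (GC
  assay). A uniform 5% CV on water would put ±4.5 g of noise on a ~2 g
  water shift and make SCS a noise amplifier for watery foods — a property
  of the assay model, not of the method.
* **Specimen mismatch.** Composition tables rarely analyse the same
  specimen raw and cooked. The cooked sample's pre-cooking profile is the
  raw profile times per-component log-normal factors: largest for fat (12%,
  shared by the sub-fractions — specimens differ most in trim and
  marbling), moderate for micronutrients (6%), small for water (2%) and for
  membrane-bound cholesterol (3%). This is also the mechanistic reason the
  cholesterol route (PINS) estimates the yield more cleanly than the
  solid-content route (SCS) on dry-heat data, matching the empirical
  ordering on real data.
* **Category-heterogeneous retentions.** Each category scales the base
  per-(component, process) losses by a factor (0.7–1.35), so a
  retention-factor table aggregated at the source level (plant/animal) —
  the coarseness real RF tables have — is systematically wrong per
  category, while the regressor can recover the category from the
  composition itself. The synthetic RF table is the mean of *realized*
  per-pair retentions within a group, at a configurable grouping
  (category, rf_group, or source); the experiment harness uses the source
  level for the baseline arm.
* **Retention values** span 0.8–1.0 for dry heat (mild losses, minerals
  nearly conserved) and 0.5–0.95 for wet heat (leaching of water-soluble
  vitamins, potassium and sodium), in the range of published RF tables.
  Cholesterol's retention equals the configured invariant retention (1.0 by
  default) everywhere — that is the PINS premise, made true by
  construction.
* The per-food composition variance (log-normal CVs of 0.35 for
  micronutrients) is a stated default, not fitted to any dataset: no
  distributional information about cross-food variance is available to fit.

What the generator does **not** emulate: kinetic time–temperature
behaviour (retention is a single fraction per component and process),
leaching into a recoverable cooking-water compartment, correlated
micronutrient structure beyond category membership, multi-ingredient
recipes, and frying (excluded processes). Passing the synthetic validation
therefore shows that the pipeline's machinery is correct and that its
comparisons behave as designed *under the stated assumptions* — it does not
certify effect sizes on real SR data, where the curation counts themselves
are uncertain.

## Study conditions and problem sizes

The packaged experiment trains 67 models — 14 wet-heat nutrients ×
{unscaled, SCS} and 13 dry-heat nutrients × {unscaled, SCS,
PINS-cholesterol} — on 200 pairs per process class with the 35-candidate
compact grid and 5 repetitions of 5-fold CV, which completes in a few
minutes on one CPU; the wider grid and 50 repetitions are configuration
switches. Every stage derives its seed from the experiment's master seed,
and re-running a configuration reproduces byte-identical tables. The
validation suite checks, at fixed seed: mass conservation and order
invariance of SCS (1e-9), exact and noisy PINS yield recovery (8% median
bound at 5% CV), the anomaly asymmetry and its mitigation (two-proportion
p < 0.01), the model-vs-baseline win counts, the variant RMSE ordering with
paired tests, and the argmin/brute-force oracles for the search and the
metrics.

Two outcomes deserve honesty rather than a passing assertion. First, with
5% assay noise on both profiles, nutrients whose true retention is near 1
remain anomalous in roughly Φ(ln r / 0.1) of pairs even after an exact
yield correction, so the mean non-anomalous fraction after PINS settles
near 0.82 under these conditions — a ceiling imposed by the noise model,
not a defect of the scaling. Second, the wet-heat improvement of SCS over
unscaled training holds as an ordering but is concentrated in dry-staple
and mineral nutrients; across 14 nutrients the paired test is
under-powered, and the package reports the p-value as observed.

## Known limitations

Pair curation from free-text descriptions is keyword-based by design; the
preparation-token and multi-ingredient-marker vocabularies are shipped as
editable resources, and curation counts on real SR extracts will vary with
them. The mapping from SR food groups to RF-table groups is likewise an
editable resource. Literature retention factors for specific foods can be
supplied as a per-food RF table CSV, but none are bundled. Models are not
serialized for reuse across sessions; the package's product is the
comparison tables, not a deployable predictor.
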
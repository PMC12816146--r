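---
title: "Methods: simulating and explaining dental workforce distribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and explaining dental workforce distribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A small minority of US dentists practice in underserved settings —
federally qualified health centers (FQHCs), designated dental shortage
areas (fewer than 1 dentist per 5,000 population), and rural shortage
areas. Understanding which individual characteristics (sex, age,
experience, race and ethnicity, specialty, educational debt, practice
ownership) and which dental-school characteristics (diversity index, class
size, state, admissions profile) predict practice in these settings is a
workforce-policy question: the outcomes are rare (on the order of 4.6%,
1.2% and 0.7% of a cohort of roughly 56,000 dentists), the relationships
are nonlinear (debt helps up to a point and then hurts; propensity drops
after 10–15 years of experience), and effects interact (debt sensitivity
differs by race).

`dentshap` implements the full analysis pipeline for this problem:
rare-event classification with imbalance-aware evaluation, global feature
importance by an AUC-based SAGE estimator, local attribution by several
SHAP flavors sharing one removal scheme, and a supervised clustering tree
that partitions dentists in attribution space. Because the underlying
survey data are restricted, the package ships a synthetic cohort generator
that emulates the published sample description and plants the reported
effect shapes, so every stage is testable end to end.

# The synthetic cohort: a stated world

The generator (`cohort_config()`, `generate_cohort()`) draws one row per
dentist. Its defaults are the published full-sample marginals: outcome
prevalences 0.046 / 0.012 / 0.007; age normal (41.2, 6.7); debt
(243,968, 180,254) dollars; race probabilities White .661 / Asian .189 /
Black .033 / Hispanic .032 / Other .085; specialty probabilities led by
general practice at .782; school-level means and SDs for diversity index,
class size, percent male students, percent US citizens, percent in-state
students, GPA/DAT ratio, applications and PhD-program prevalence (0.436).

Design choices where only a mean and SD are published:

* **Truncation.** Continuous draws are truncated to plausible ranges (age
  25–75, experience 0–45 years, debt 0–1.2M dollars, percentages 0–100).
  A mean/SD pair alone would produce impossible values (negative debt in
  particular, since the debt SD is close to its mean).
* **Debt mixture.** 15% of dentists carry exactly zero debt (the
  published SD ≈ mean implies substantial mass at or near zero), 9% are
  drawn from a high-debt component N(\$660k, \$180k), and the rest from
  N(\$250k, \$100k), all truncated to [0, \$1.2M]. The realized mean/SD
  reproduce the published (243,968, 180,254) while leaving real mass
  (≈1.7%) above \$800k; a single truncated normal with SD near its mean
  puts essentially nothing there, and the planted high-debt decline
  would be unlearnable and untestable.
* **Age–experience coupling.** Experience = age − 28 + N(0, 2), clipped to
  [0, 45]. The published means (age 41.2, experience 12.3) are consistent
  with career entry around age 28–29; the exact joint law is not
  published.
* **Schools.** School-level features are drawn once per school (66
  schools, roughly the number of US dental schools) and inherited by
  dentists assigned to schools with probability proportional to class
  size. The real within-school correlation structure is unknown; this
  captures its first-order consequence (dentists from one school share
  school-level features exactly).
* **States.** School state is a 12-level categorical; three states carry
  planted positive effects (0.9, 0.7, 0.5 on the log-odds scale),
  standing in for the reported state-of-school signals.

The outcome model is logistic. Planted effects (see `effect_spec()`):
linear coefficients (female +0.5 — sized from the published FQHC column,
where 57.1% female against 44.8% overall implies a log-odds shift near
0.5; general practice +0.8; non-ownership +0.6; rural practice +0.7; no
diversity main effect, since the published marginal shift is near null); a
piecewise-linear debt effect per outcome — for FQHC, zero below \$200k,
positive (+0.15 per \$100k) in \$200–600k, flat to \$800k, then a steep
decline (−1.5 per \$100k) above, chosen so the *realized* high-debt
prevalence is genuinely below average (≈ 0.03 vs 0.046; shallower slopes
leave the cumulative effect above the population mean through most of
the observable > \$800k band, i.e. they fail to produce a world where
very high debt reduces the likelihood); for the shortage outcomes a mild
monotone increase; an experience decline of −0.08 (FQHC) or −0.05
(shortage) log-odds per year beyond a change-point at 12 years; a
White-by-debt *sensitivity* interaction — Whites receive 1.5× the whole
debt curve, so both the mid-band rise and the high-debt decline are
steeper (an unbounded linear race × debt product would dominate the
decline at the right tail and flip the planted shape); and a high-risk
subgroup — general
practitioners from the three boosted states — receiving +log(5) log-odds,
i.e. roughly five-fold risk at these base rates. The subgroup gives
attribution space a planted, recoverable cluster structure and its
membership is stored in the cohort's ground truth. The intercept of each
outcome is calibrated by monotone bisection (`calibrate_intercept()`) so
the expected prevalence hits the target exactly; empirical prevalences
then deviate only by binomial noise.

What a green test does **not** establish: the generator draws features
independently across dentists given the school assignment, has no
measurement error, no informative missingness (missingness is injected
completely at random by `inject_missingness()`), and its nonlinearities
are exactly the planted ones. Recovery tests certify the estimators, not
the substantive findings.

# Preprocessing

`fit_preprocess()` is fitted on training rows only and records every
statistic it will apply (`apply_preprocess()`): columns with more than 60%
missing are dropped; continuous variables are median-imputed (medians from
observed values only) and greedily filtered at |Pearson r| > 0.8, keeping
the earlier column of a correlated pair; categoricals are one-hot encoded
with **all** levels retained plus an explicit `"<missing>"` level; every
encoded column is z-scored with training means and SDs.

Two deliberate deviations from a naive reading of the filters:

* The collinearity filter runs on **raw continuous variables before
  encoding**. Applied after one-hot encoding it would delete one indicator
  of every binary categorical (complementary indicators have r = −1),
  which contradicts keeping all levels so each level can carry its own
  attribution.
* The `"<missing>"` level always exists, even when the training data had
  no missing values; unseen test levels map there. If unused it is a
  zero-variance column, which (like any zero-variance column) is scaled
  to all zeros rather than dividing by zero.

# The classifier and its evaluation

The classifier (`fit_ensemble()`) is a soft-voting ensemble of

1. a gradient-boosted tree model (logistic loss, histogram split finding;
   defaults depth 4, 300 rounds, learning rate 0.05, class weight equal to
   the negative/positive ratio) whose raw probabilities pass through an
   isotonic map, and
2. a ridge-penalized logistic regression (IRLS; penalty 1 on standardized
   features, intercept unpenalized),

with the ensemble score the unweighted mean of the two member
probabilities. The booster is implemented in compiled code inside the
package; no external boosting library is used, which keeps the split
structure explicit for exact TreeSHAP attribution.

The isotonic map is learned by 5-fold cross-fitting inside the training
split: out-of-fold tree scores are pooled, a single isotonic regression
(pool-adjacent-violators with linear interpolation between knots) maps
score to calibrated probability, and the final booster is refit on the
full training split. Calibrating on the same rows the booster memorized
would systematically overstate confidence.

The decision threshold is the MCC-maximal cutoff on training scores
(`select_threshold()`): candidates are midpoints between consecutive
distinct scores plus both endpoints, classification is score ≥ threshold,
and ties resolve to the smallest threshold. Evaluation
(`evaluate()`) reports AUC (Mann–Whitney with ties at ½, stratified
bootstrap CI with 2,000 resamples), sensitivity, specificity, precision,
lift (precision ÷ test-set prevalence) and MCC (0 by convention when a
confusion marginal is empty). `monte_carlo_cv()` repeats random 80/20
splits (default 30) with preprocessing and threshold selection refit
inside each training split; a split whose training part lacks a class is
resampled with an incremented seed. The threshold is selected per split,
matching selection "on the training data"; there is no global threshold
mode in v1.

# Global importance: AUC-based SAGE

`sage_auc()` estimates the Shapley value of each feature for the game
v(S) = AUC of predictions with features outside S marginalized. Choices:

* **Removal scheme.** Marginal (interventional) substitution from an
  explicit background sample of training rows — the same scheme every
  SHAP flavor uses, so global and local numbers are comparable.
* **v(∅) = 0.5 analytically.** Fully marginalized scores carry no
  information about the labels, so the empty-coalition AUC is fixed at
  0.5 rather than estimated. A side effect worth having: the efficiency
  identity Σ values = AUC_full − 0.5 holds exactly for every sampled
  permutation, not just in expectation.
* **Estimator.** Permutation sampling (default 64 orderings), one
  background draw per permutation (`marginal = "sample"`); an exact
  full-background averaging mode (`marginal = "average"`) exists and is
  what the brute-force oracle tests use. The two modes estimate slightly
  different games (AUC is nonlinear in the scores), so oracle comparisons
  always use "average".
* **Granularity.** The pipeline ranks *parent* features: the one-hot block
  of a categorical enters coalitions as a unit (`groups` argument). This
  matches how the published summary plots name features, and avoids
  splitting one categorical's importance across a dozen indicator
  columns. Per-column ranking remains the API default.
* **Budget.** AUC is computed on an evaluation subsample capped at 2,000
  rows; the cost is permutations × features × one batch prediction.

`coef_importance()` ranks standardized logistic coefficients by absolute
value (ties by declared column order). `inclusion_curve()` refits the
ensemble on top-k features over a single fixed 80/20 split, and
`select_top_k()` returns the smallest k within a tolerance (default
0.005 AUC) of the curve maximum.

# Local attribution: one game, three estimators

All flavors target the marginal-expectation game
v(S) = E_background[f(x with features outside S replaced from b)]:

* `shap_exact()` — subset enumeration (d ≤ 15), the test oracle.
* `shap_linear()` — closed form β_j(x_j − mean_j) on the link scale.
* `shap_tree()` — exact interventional TreeSHAP for the booster:
  per (instance, background row) pair, each root-to-leaf path contributes
  a unanimity-style coalition term whose Shapley weights have a closed
  form in the counts of path features satisfied only by x (set U) or only
  by b (set D); contributions are averaged over the background. Margin
  scale, before calibration.
* `shap_marginal()` — permutation sampling for an arbitrary score
  function, used for the soft-voting ensemble on the probability scale
  (post-calibration, post-vote). One background row per permutation makes
  additivity base + Σφ = f(x) exact by telescoping; per-feature Monte
  Carlo standard errors are reported. Supports the same `groups` argument
  as SAGE.

Default background size is 128 seeded training rows — a
tractability/variance compromise. The probability scale is the default
for ensemble explanations; member models can be explained on their native
scales. One consequence worth knowing when reading dependence plots: the
logistic member is linear on the link scale by construction, so at the
vote level its attribution cannot follow a non-monotone response — a
debt curve that rises then falls is visible in the tree member's
TreeSHAP dependence but is partially averaged away in the vote's
marginal attribution. The pipeline therefore emits the debt dependence
table from both flavors.

# The supervised clustering tree

`build_cluster_tree()` recursively partitions instances in SHAP space: at
each node, PCA on the node's attribution rows (components to reach 90%
variance, capped at 3, mirroring 3-D branch views); seeded k-means (10
restarts) for each candidate k ∈ {2, 3}; the best-silhouette k wins and
the split is accepted only if that silhouette ≥ 0.4 — the gate value
reported for the published tree, exposed as a parameter since it is a
report, not a prescription. Nodes stop at depth 4, below 50 members, at
zero variance, or when any child would have fewer than 3 members. Leaves
are labeled high / average / low when prevalence is ≥ 2×, ≤ 0.5×, or
otherwise, relative to the overall prevalence — the numeric thresholds
are this package's own definition, as none are published.
`summarize_high_prevalence()` ranks features within each high leaf by mean
signed contribution.

Clustering attributions rather than raw features is the point: a feature
that matters for the outcome is amplified in attribution space (its SHAP
magnitude reflects its effect), so outcome-relevant subgroups separate
more cleanly. The test suite demonstrates this supervision advantage on a
planted subgroup, comparing adjusted-Rand recovery from SHAP-space versus
raw-feature clustering under the identical procedure.

# Numerical and engineering choices

* Seeds: every stochastic step takes an explicit seed; pipeline stage
  seeds derive deterministically from one base seed, and all internal RNG
  use is scoped so the caller's RNG state is untouched. Rerunning a
  pipeline config reproduces byte-identical artifact hashes.
* The booster bins features into at most 128 quantile bins (so a
  top-percentile region such as > \$800k debt is resolvable); splits are at
  bin boundaries; leaf values use the standard second-order formula with
  L2 regularization 1; a threshold equal to a column minimum is dropped
  (it would send no rows left). Zero-variance columns can never split.
* Isotonic interpolation is linear between PAVA knots, clamped to [0, 1];
  monotonicity is tested on a dense grid.
* MCC uses the 0-when-degenerate convention; lift uses test-set
  prevalence; the AUC bootstrap is stratified by class.
* Desk-scale budgets: tests run the reference recovery at n = 20,000 with
  10 CV iterations (not 30) and cap explained instances at 4,000; both
  are scale reductions, stated here, that do not change any default a
  user sees.

# Known limitations

* The generator's independence assumptions (above) make recovery easier
  than on real survey data; reported CV performance on synthetic cohorts
  is not comparable to performance published on the restricted data, and
  the package deliberately does not treat those published performance
  numbers as reproduction targets.
* Marginal removal evaluates models off-manifold; conditional
  (on-manifold) removal is out of scope for v1.
* SHAP interaction values (pairwise decompositions) are not implemented;
  dependence tables color by a second feature instead.
* The cluster tree's k-means primitive assumes roughly spherical clusters
  in the projected space; density-based alternatives are out of scope.
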
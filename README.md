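# dentshap

Explainable machine learning for dental workforce distribution: who
practices in underserved settings, and why?

A small minority of US dentists work in federally qualified health
centers (FQHCs, ~4.6% of a ~56,000-dentist cohort), designated dental
shortage areas (~1.2%) or rural dental shortage areas (~0.7%). `dentshap`
implements a complete, tested analysis pipeline for this rare-outcome
prediction-and-explanation problem:

* **Synthetic cohort generator** — the underlying survey data are
  restricted, so the package simulates seeded cohorts whose marginals
  match the published sample description (age 41.2 (6.7); debt \$243,968
  (\$180,254); 66.1% White; 78.2% general practice; school-level
  characteristics) and whose outcome model plants the reported effect
  shapes: a rise-then-fall debt effect, a decline after 10–15 years of
  experience, a race-differential debt sensitivity, school-state effects
  and a high-risk subgroup. Ground truth is stored with every cohort.
* **Preprocessing** — >60% missingness filter, |r| > 0.8 collinearity
  filter, median imputation, full one-hot encoding with an explicit
  missing level, z-scoring; all statistics fitted on training data only.
* **Calibrated soft-voting classifier** — gradient-boosted trees (own
  compiled implementation, explicit split structure) with isotonic
  calibration cross-fitted inside the training split, plus ridge
  logistic regression; scores are the mean of member probabilities. The
  decision threshold maximizes the Matthews correlation coefficient
  (MCC) on training scores. Monte Carlo cross-validation (random 80/20
  splits) reports AUC with bootstrap CIs, sensitivity, specificity,
  precision, lift and MCC — metrics that stay honest under heavy class
  imbalance.
* **Global importance** — SAGE with the value function replaced by AUC
  (Shapley value of each feature for held-out discrimination), logistic
  coefficient ranking, and feature-inclusion curves with top-k selection.
* **Local attribution** — linear SHAP, exact interventional TreeSHAP and
  model-agnostic marginal SHAP, all estimating one marginal-expectation
  game against an explicit background, validated against a `2^d`
  enumeration oracle.
* **Supervised clustering tree** — recursive PCA + seeded k-means on
  SHAP rows, splits gated by silhouette score ≥ 0.4, leaves labeled
  high/average/low by outcome prevalence, with per-cluster driver
  summaries.

## The statistic at the core

For a model score function f and background distribution B, every
attribution in the package estimates the Shapley value of the game

    v(S) = E_{b~B}[ f(x_S, b_{\bar S}) ]          (local, per instance)
    v(S) = AUC( marginalized scores, y )          (global, SAGE)

with additivity `f(x) = base + Σ_j φ_j` holding exactly (enumeration,
TreeSHAP, telescoping permutation estimator) or within reported Monte
Carlo standard errors.

## Worked example

```r
library(dentshap)

res <- run_pipeline(reference_pipeline_config(base_seed = 2026),
                    out_dir = "out")
print(res$results$fqhc$cv)
print(res$results$fqhc$sage)
print(res$results$fqhc$tree)
```

On the reference synthetic cohort (n = 20,000, planted effects, 10 CV
iterations) this printed:

```
Monte Carlo CV over 10 splits
  mean AUC 0.823 (0.815, 0.831)
  best split: AUC 0.841 (0.812, 0.866) | sens 0.624 spec 0.877 prec 0.191 lift 4.29 mcc 0.293 @ thr 0.1023

AUC-SAGE ranking (64 permutations, full AUC 0.823)
   1. school_state                 +0.1444 (se 0.0049)
   2. debt                         +0.0442 (se 0.0042)
   3. specialty                    +0.0381 (se 0.0034)
   4. owner                        +0.0234 (se 0.0030)
   5. rural_practice               +0.0205 (se 0.0025)
   6. sex                          +0.0128 (se 0.0017)
   ...
```

Reading the output: the ensemble separates FQHC dentists from the rest
(mean held-out AUC 0.823) despite 4.6% prevalence; `lift 4.29` means
dentists flagged at the MCC-optimal threshold are ~4.3× more likely than
average to be FQHC dentists. The SAGE ranking recovers the planted
signal: school state, debt, specialty, ownership, rural practice and sex
— every feature given a main effect by the generator — rank at the top
(experience is collinearity-filtered in this world, r ≈ 0.95 with age;
its signal surfaces through `age`). The supervised cluster tree isolates
the planted high-risk subgroup (general practitioners from three boosted
states) into high-prevalence leaves enriched ≈ 4.8× for true subgroup
members, with every accepted split's silhouette ≥ 0.4.

A quick self-contained check of one primitive:

```r
silhouette_score(matrix(c(0, 1, 10, 11), ncol = 1), c(1, 1, 2, 2))
#> [1] 0.8997494
```

## Command line

```sh
Rscript -e 'dentshap::main()' simulate --n 20000 --seed 7 --out cohort/
Rscript -e 'dentshap::main()' run-all --n 20000 --iters 10 --seed 7 --out results/
```

(Subcommands: `simulate`, `preprocess`, `train`, `sage`, `shap`,
`cluster`, `report`, `run-all`; a launcher script is installed at
`inst/cli/dentshap`.)

## Documentation

The methods vignette (`vignettes/methods.Rmd`) documents the model and
its assumptions, every tunable parameter with its default and rationale,
what the synthetic world does and does not emulate, and the numerical
choices (tolerances, tie-breaks, degenerate inputs).
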
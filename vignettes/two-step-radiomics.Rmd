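---
title: "Two-step ensemble feature selection for radiomic marker prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step ensemble feature selection for radiomic marker prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(radsel)
```

## The problem

Breast-cancer management hinges on four immunohistochemical markers —
estrogen receptor (ER), progesterone receptor (PR), HER2 and the Ki67
proliferation index — that are normally obtained by biopsy. Radiomics
tries to predict their status non-invasively from quantitative features
of multiparametric breast MRI (subtracted and post-contrast DCE series,
ADC maps, T2-weighted images). The statistical setting is hostile: a
typical cohort has fewer than a hundred lesions but each lesion yields
over a thousand correlated features, and the marker classes are
unbalanced. `radsel` implements a complete pipeline for this setting:
radiomic feature extraction from 3D volumes, a two-step ensemble
feature-selection procedure with per-fold rank aggregation, SMOTE class
balancing inside every training split, and final model selection by
leave-one-out cross-validation (LOOCV), together with a synthetic-data
module that makes every stage testable with known ground truth.

## The selection model

The core difficulty is merging feature selections made on different
cross-validation folds. Within each of the 10 stratified folds, a
selector ranks all features using only that fold's training rows (after
z-standardization fitted on those rows). Across folds, each feature `f`
is summarized by

* `minpos(f)` — the best (minimum) 1-based rank it attained in any fold;
* `numpos(f)` — the number of folds in which it attained exactly that rank.

Features with `minpos <= t` are kept and ordered by `minpos` ascending,
then `numpos` descending, then stable column index. Because different
folds promote different features, the kept list can be longer than `t`.

Selection runs twice:

1. **Coarse step.** Complete ranker filters — chi-squared, Fisher score,
   Gini index, ReliefF — at thresholds `t1 = 5, 10, ..., 50`. Every
   (selector, t1, classifier) combination is scored by the mean F1 of
   the held-out folds (training splits are SMOTE-balanced before
   fitting). The two best combinations carry their aggregated lists
   forward.
2. **Fine step.** Slower methods — LASSO regression with recursive
   feature elimination (LR-RFE), nearest-neighbour mutual information,
   and correlation-based feature selection (CFS) — are restricted to a
   carried-forward list and filtered at `t2 = 1, ..., 10`. The best
   step-2 combination's aggregated list is the final feature set.

A final LOOCV round compares all six classifiers (KNN, naive Bayes, SVM,
decision tree, single-hidden-layer MLP, random forest) on the final
features; the best positive-class F1 wins and is refitted on all data.
F1 is also reported with the negative class treated as positive
(dual polarity), which matters when one class dominates.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| folds | 10, stratified | small cohorts; stratification keeps both classes in every training split |
| `t1` | 5–50 by 5 | coarse screen leaving a feature count comparable to the sample count |
| `t2` | 1–10 | final models should be small enough to generalize |
| SMOTE neighbours | 5 | classic default; reduced automatically (with a warning) for tiny minorities |
| ReliefF neighbours | 10, all samples, Manhattan on range-normalized features | canonical defaults; the method is otherwise parameter-free here |
| MI estimator | nearest-neighbour (mixed continuous/discrete), k = 3 | avoids bin-count sensitivity of histogram MI |
| LR-RFE penalty | one 5-fold `cv.glmnet` per invocation, then fixed | re-tuning each elimination round is ~50× slower and does not change the ranking at these sizes |
| CFS search | best-first, stop after 5 non-improving expansions | the standard best-first patience rule |
| MLP | 1 hidden layer, 100 units, 1000 iterations | library-default-style configuration |

Chi-squared is defined for non-negative frequencies, so each feature is
min-max scaled to [0, 1] first and treated as a pseudo-frequency; this
also makes the score invariant to positive affine rescaling, like the
Fisher score and (after its internal range normalization) ReliefF.
Zero-variance features receive score 0 and are explicitly placed last in
every ranking; scores are monotone non-increasing along the
non-degenerate part of a ranking (ReliefF weights may be negative, so a
0-scored constant feature would otherwise not be last).

## Feature extraction

Extraction follows the IBSI feature taxonomy with the standard radiomics
naming convention `modality_filter_family_Feature` (e.g.
`T2_wavelet-LLH_firstorder_Skewness`). On the original image: 14 shape,
18 first-order and 75 texture features (24 GLCM, 16 GLRLM, 16 GLSZM,
5 NGTDM, 14 GLDM). Each of the 8 single-level wavelet channels
(LLL…HHH) and 4 Laplacian-of-Gaussian scales (sigma 2–5 mm) yields
18 first-order + 73 texture features — a two-feature exclusion list
(`glcm_SumAverage`, which duplicates `JointAverage` on a symmetric
co-occurrence matrix, and `glcm_MCC`, frequently degenerate on small
filtered-channel ROIs) applies to the filtered channels only — for
91 × 12 = 1092 filtered features.

Numerical choices: grey levels are discretized to a fixed bin count (32)
inside the ROI, which is stable under the whole-image z-normalization
applied to T2/post-contrast volumes; texture matrices use the 26-voxel
neighbourhood (13 unique directions) with counts pooled across
directions before feature computation; the wavelet transform is an
undecimated separable Haar analysis, so each channel stays congruent
with the input grid and mask; the LoG filter is a scale-normalized
separable second-Gaussian-derivative sum with sigma given in mm and
converted per axis through the voxel spacing; shape surface area is the
exposed voxel-face surface and the axis lengths derive from the
principal components of the physical voxel coordinates. Ties in
peak-subtraction-phase selection resolve to the lowest phase index;
constant volumes are rejected by the normalizer (zero variance).
`feature_count_by_family()` predicts all cardinalities in closed form
and is tested against the observed extraction on every profile.

```{r counts}
feature_count_by_family(extraction_profile())
```

## What the synthetic data emulates — and what it does not

`generate_feature_table()` plants `n_informative` features whose class
means differ by `effect_size` standard deviations (informative feature =
standard normal noise + d·label), optional correlated copies
(`rho·parent + sqrt(1-rho²)·noise`), and pure-noise remainders, with
Bernoulli(`class_balance`) labels. The defaults — 80 samples, 1000
features, 10 informative at d = 1.5, balance 0.5 — mirror the scale of a
small radiomic cohort. `generate_phantom_volume()` builds an ellipsoidal
lesion in a 32×32×24 grid observed over 4 dynamic phases with a single
kinetic peak, Gaussian-smoothed noise texture inside the ROI (class 1
doubles the smoothing length and adds a constant intensity offset), and
background noise that is identical between classes for a fixed seed, so
any class signal is confined to the lesion.

What passing tests on these data do **not** show: real radiomic features
are not Gaussian, their correlation structure is block-wise and heavy,
lesion texture is not smoothed white noise, and real contrast kinetics
are pharmacokinetic, not a fixed ramp. The synthetic module validates
the *machinery* (no leakage, correct aggregation, recovery of a known
signal, honest null behaviour), not clinical performance.

## A small worked run

A desk-scale version of the pipeline (smaller table and grids so the
vignette builds quickly; the shape of the output is identical at full
scale):

```{r pipeline}
ft <- generate_feature_table(synthetic_table_spec(
  n_samples = 60, n_features = 120, n_informative = 5,
  effect_size = 1.5, seed = 7))
s1 <- step_config(selectors = c("fisher", "chi_squared"),
                  classifiers = c("knn", "nb"), thresholds = c(5L, 10L, 20L),
                  n_folds = 5, seed = 7)
s2 <- step_config(selectors = c("mutual_information", "cfs"),
                  classifiers = c("knn", "nb"), thresholds = 1:5,
                  n_folds = 5, seed = 7)
res <- two_step_pipeline(ft, s1, s2)
res
mean(res$final_features %in% attr(ft, "informative"))
```

```{r loocv}
loo <- loocv_select_model(ft, res$final_features,
                          classifiers = c("knn", "nb", "dt"), seed = 7)
loo$metrics[[loo$winner]]
```

## Design choices where the design was open

* **SMOTE placement.** Oversampling happens strictly inside each
  training split (including each LOOCV round), never before splitting:
  interpolated copies of evaluation samples in the training set are a
  textbook leak.
* **Model-selection scalar.** Combinations are ranked by the F1 of the
  positive class; the dual-polarity F1 is reported, not optimized.
* **Top-2 carry-forward.** Both step-1 runners-up are re-examined in
  step 2 and the overall winner is decided by step-2 F1 — the second
  step can (and sometimes does) overturn the step-1 ordering.
* **Tie-breaking.** Everything downstream of a tie is deterministic:
  score ties resolve by original column index, aggregation ties by
  (minpos, numpos, stable index), peak-phase ties by lowest index,
  LR-RFE coefficient ties eliminate the later column first.
* **Null calibration.** The "majority baseline" is the F1 of the best
  trivial constant predictor (predict-all-positive), 2q/(1+q) for
  positive prevalence q. On effect-size-0 tables the pipeline's best CV
  F1 stays near this baseline; the residual gap is pure selection
  optimism from maximizing over the configuration grid.

## Problem sizes used by the automated checks

The acceptance checks run the full pipeline on 80 × 1000 tables with the
complete t1/t2 grids, all four step-1 rankers and all three step-2
selectors, and the {knn, nb, dt} classifier subset (the three classifiers
whose fits are effectively instantaneous, keeping a 20-replicate study
within minutes); SVM/MLP/RF are exercised in the LOOCV and unit tests.
The test suite uses 10 replicates per condition, the standalone
acceptance script 5.

## Known limitations

* Feature values are IBSI-*style*, not certified IBSI-benchmark
  reproductions: surface area is voxel-face based (not marching cubes),
  the wavelet is Haar (not coif1), and texture matrices pool directions
  by summation rather than per-angle averaging. Counts, families and
  naming — the taxonomy contract — are exact.
* `lr_rfe_select` refits a model per eliminated feature; on thousands of
  candidate features it is meant to run after the coarse step, not
  instead of it.
* Registration/reslicing across modalities is assumed done upstream; the
  extraction module requires congruent grids and a strictly binary mask.
* HER2 parsing accepts ordinal scores with plus signs (`"2+"`); FISH
  reflex testing of 2+ cases is out of scope.
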
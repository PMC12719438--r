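---
title: "Methods: multi-cohort microbiome classification of endometrial cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cohort microbiome classification of endometrial cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices behind them. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The problem

Several 16S rRNA case–control studies of the vaginal microbiome in
endometrial cancer (EC) exist, but each is small, each was processed
differently, and each recorded a different subset of patient covariates
(age, BMI, ethnicity, vaginal pH). A classifier that is useful across
studies must therefore (a) handle cohort-specific batch effects, (b) cope
with covariates that are entirely absent in some cohorts, and (c) be judged
on cohorts it never saw. The package implements and compares two families
of strategies: **early integration**, which pools all training cohorts into
one feature matrix (optionally after batch correction), and **late
integration**, which trains one local model per cohort and averages their
predicted probabilities.

## The synthetic study

Real cohort data live in sequence archives; every stage here is instead
exercised on a generator whose defaults encode the structure of the five
published cohorts the design targets:

* cohort sizes 22, 149, 36, 27, 31 with 12, 69, 8, 23, 23 EC cases
  (265 samples, 135 EC / 130 benign); the first ("antonio") is the held-out
  evaluation cohort;
* covariates recorded in three cohorts, age-only in "chao", none in
  "gressel"; vaginal pH additionally missing at random within cohorts, at a
  higher rate in EC (matching the label-dependent NA pattern in the
  published cohort tables);
* EC cases older (mean +12 y) and heavier (+5 kg/m²), more often White.

Counts are **Dirichlet-multinomial**: a global base log-composition
(a dominant *Lactobacillus*-like genus of 8 species plus ~100 further taxa),
perturbed per cohort by a log-normal batch effect (`batch_effect_sd`, default
1.0), per sample by linear covariate effects on the log-relative-abundance
scale (defaults 0.3/0.2/0.3 per SD of age/BMI and for non-White ethnicity),
and for EC samples by (i) `ec_log_fold_change` (default 1.5, natural log) on
a 5-species *Peptoniphilus*-like genus and (ii) a flattening of the base
composition (`diversity_shift`, default 0.4), so EC communities are more
even and their expected Shannon index is higher. The Dirichlet total mass
(`theta = 50`) sets 16S-typical overdispersion; library sizes are negative
binomial around 10,000 reads. The Dirichlet-multinomial family was chosen
because multinomial sampling alone cannot reproduce the overdispersion of
amplicon counts. Vaginal pH is generated downstream of composition — a noisy
decreasing function of *Lactobacillus* relative abundance, dichotomized at
4.5 — because pH is biologically a consequence of lactic-acid production,
and this makes the pH covariate deliberately redundant with the microbiome
features. The `covariate_label_shift` switch scales the EC-vs-benign
demographic differences so a *complete* null (no disease signal in
composition or covariates) can be simulated.

A master seed expands into per-cohort child seeds by a fixed affine rule, so
adding a cohort never perturbs earlier cohorts. The generator does **not**
emulate read-level artifacts (chimeras, primer bias, taxonomy-assignment
error) or cross-pipeline variation; passing tests show the statistical
machinery behaves correctly under the stated generative model, not that the
generator reproduces any real cohort.

## Feature engineering

The fixed order is genus aggregation → prevalence filter → CLR. "Fewer than
5% of samples" is read strictly: a taxon present in exactly 5% is kept. The
filter is computed on training data only and the surviving feature list is
frozen and re-applied to test data (absent features become zero counts), so
no test-set information shapes the feature space. The CLR pseudocount
defaults to 0.5 (the half-count convention); CLR scale invariance holds only
in the limit of vanishing pseudocount, which the tests verify at large
counts. For late integration each cohort computes its own filter; for early
integration the filter is computed on the pooled training cohorts.

## Ecology

Shannon entropy uses natural log with `0·ln 0 = 0`. Bray–Curtis and
Jensen–Shannon work on relative abundances, Jaccard on presence/absence.
Jensen–Shannon is returned as the square root of the divergence by default
(the square root is a metric; a switch returns the raw divergence).
Weighted UniFrac is `Σ b_e |A_e − B_e| / Σ b_e (A_e + B_e)` over edges with
length `b_e` and descendant abundance fractions `A_e`; unweighted UniFrac is
unshared over covered branch length.

Marginal PERMANOVA uses the Gower-centered squared-distance matrix and the
trace form: each term's sum of squares is the drop in explained trace when
that term leaves the otherwise-full model, with the full-model residual in
the pseudo-F. P-values come from **free permutation of raw observations**
(not residual permutation) — the conventional default, and no scheme is
dictated by the problem; ties `F* = F_obs` count toward the numerator and
`p = (1 + #{F* ≥ F}) / (1 + n_perm)`, so p is always in (0, 1]. No
multiple-testing correction is applied across terms, mirroring common
practice for marginal community-level tests. Samples with missing values in
any tested term are dropped (complete-case) with a message. For n ≤ 8 an
exhaustive enumeration mode replaces sampling.

## Differential abundance

The covariate-adjusted procedure works on `y = ln(counts + 0.5)` and
alternates per-taxon linear-model fits with median-based re-estimation of a
per-sample offset `δ_j` (the sampling-fraction/bias term). Two medians do
the work: the per-sample median residual updates `δ`, and the per-coefficient
median across taxa is pushed from the coefficients into `δ` each iteration.
The second step matters: offsets and coefficients are only *jointly*
identified (a design-aligned shift can move freely between them), and
anchoring the median coefficient at zero — the assumption that most taxa are
not differential — is precisely the bias correction. Without it the
iteration drifts along the unidentified direction and the test is grossly
anti-conservative. Wald z statistics on the disease coefficient are
Holm-adjusted across taxa. The update is damped when progress stalls because
median-based fixed-point iterations can cycle; the median estimating
equations also have flat regions, so sample-scale invariance is approximate
(the tests bound the leakage of a ×10 library-size change into the
coefficients). By default the DA design adjusts for age, BMI and ethnicity
where available — pH is excluded as a downstream biomarker rather than a
confounder.

## Batch correction

A parametric empirical-Bayes location/scale model: standardize per feature
(protecting a biological design, by default the disease label), estimate
per-batch per-feature means and variances, shrink them toward batch-level
priors (normal on locations, inverse-gamma on scales; hyperparameters by
method of moments, iterated to convergence), and back-transform. The fitted
`batch_model` freezes the grand mean, pooled scales and priors, so a cohort
unseen at training (the held-out study) is adjusted *without its labels*:
its own batch term is estimated from features alone against the frozen
reference. Protecting the disease label is the default because
batch-correcting away genuine case–control differences is the known
overcorrection failure of this approach when cohorts differ in case mix; an
unprotected mode exists for comparison. Adjustment is idempotent only to
sampling-noise tolerance (re-estimated batch moments are never exactly 0/1),
which is what the test asserts.

## Rebalancing and imputation

SMOTE-NC interpolates numeric features between a minority sample and one of
its k = 5 nearest minority neighbours (k clipped to minority−1) and assigns
categorical features by neighbour majority vote, with the standard nominal
penalty (squared median of numeric-feature SDs per differing category) in
the distance. The target ratio defaults to 1:1. Imputation is
chained-equation with a linear model for numeric and one-vs-rest logistic
models for categorical covariates, conditioned on the other covariates plus
the microbiome CLR block reduced to ≤ 5 principal components (full-rank
stability on 20–40-sample cohorts). The completion is the conditional
mean/most-probable class — a deliberate single-completion variant: a
prediction pipeline needs one deterministic completed set, not
multiple-imputation inference, and determinism makes every downstream fit
reproducible. Models and initialization values are frozen at training and
re-applied at prediction. Both rebalancing and imputation run strictly
inside CV training folds; the fold-audit and leakage tests enforce this.
Covariates wholly absent in a cohort are excluded from that cohort's model,
never imputed from other studies. Imputation precedes rebalancing (SMOTE
needs complete numerics; the reverse order would interpolate missingness).

## Ensemble framework

Three base-learner families (bagged trees via randomForest, boosted trees
via xgboost, single-hidden-layer nnet) are consumed through a uniform
fit/predict-probability interface; the framework — grids, repeated
stratified CV, F1-at-0.5 selection, probability averaging, LOSO — is owned
by the package. Tuning is 5-fold × 3-repeat stratified CV; folds degrade to
as-stratified-as-possible round-robin when a class is smaller than the fold
count. Grid ties break toward the simpler model (fewer boosting rounds,
smaller network, fewer trees), then grid order. Per training unit the three
tuned families are averaged ("ensembles of three base models"); a flag
switches to best-single-family. Cross-cohort averaging is an unweighted
arithmetic mean of local probabilities (a weighted-by-out-of-fold-F1 mode
exists behind a flag), and a probability of exactly 0.5 classifies as
positive so the rule is total. Early-integration variants use taxon features
only: covariates are inconsistently available across cohorts, and pooling
them would require the cross-study imputation the leakage policy forbids.
In every fit — including each LOSO round — the covariate set is restricted
to what the held-out cohort records, so a local model never depends on a
feature unobservable at prediction time; a cohort with no usable features
for a variant is skipped with a message.

## Metrics

Proportion metrics carry exact Clopper–Pearson intervals from Beta
quantiles (`lower = qbeta(α/2, x, n−x+1)`, `upper = qbeta(1−α/2, x+1,
n−x)`); zero-denominator metrics are flagged undefined and reported as
`NaN [0, 1]`. AUROC is the rank-based Mann–Whitney statistic with ties
counting ½. Pooled LOSO metrics micro-pool confusion counts and concatenate
scores for AUROC; per-study reports are also emitted. AUROC confidence
intervals are not produced (a bootstrap could be added, but no exact method
applies, and none is claimed).

## Problem sizes and numerical choices

The test suite exercises the generator's default 265-sample study for
ecological and differential-abundance properties; null calibrations use 200
replicates of 20–100-sample single-cohort studies; model-fitting tests use a
compact 4-cohort study (24–40 samples per cohort, 60 taxa) and one-point
grids; the framework-behaviour checks run the full five-cohort study with
one-point grids. These sizes are the package's chosen balance between the
Monte-Carlo resolution the assertions need and a suite that runs in
minutes. Convergence tolerances: DA offset iteration 1e-6 (max 100
iterations, damped); EB shrinkage 1e-8; CLR row-centering asserted to 1e-9.
Degenerate inputs are first-class: zero-total samples error by name,
single-class folds fall back to constant-probability models, single-class
held-out cohorts get flagged undefined AUROC, and zero-variance features in
a batch are floored and logged.

## Known limitations

* The generator's covariate-composition coupling is linear on the log scale
  and its batch effects are location-only on log-abundance; real protocol
  differences (primer region, extraction kit) also distort presence/absence
  structure.
* The DA procedure is a self-contained bias-corrected log-linear model, not
  a reimplementation of any published estimator; it shares the median-based
  identifiability assumption but none of the zero-classification machinery,
  so structural zeros are not distinguished from sampling zeros.
* Single-completion imputation understates covariate uncertainty — accepted
  deliberately for a prediction pipeline.
* Early-integration variants cannot use covariates at all; where covariates
  carry most of the signal this handicaps early integration by design.
* Exact intervals are conservative; at n ≈ 20 they are wide enough that
  most model comparisons on a single held-out cohort are not individually
  significant — the motivation for LOSO pooling.
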
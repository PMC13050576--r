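---
title: "Methods: simulating and modelling first-trimester GDM risk"
author: "earlygdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and modelling first-trimester GDM risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earlygdm)
```

## Scientific problem

Gestational diabetes mellitus (GDM) is usually diagnosed at 24–28 weeks of
gestation, but hyperglycemia is often present much earlier, and early
treatment of high-risk women can improve outcomes. `earlygdm` implements a
complete, reproducible study of first-trimester GDM risk prediction on a
*synthetic* high-risk antenatal cohort: a parameterized cohort simulator, a
leakage-safe preprocessing chain, a seven-method consensus feature-importance
ranking, an eleven-algorithm classification benchmark with support-weighted
metrics, additive (Shapley-value) per-feature attribution of the selected
model, and deterministic clinical tiering of laboratory values.

Everything downstream consumes the simulator's output, so the whole analysis
is reproducible from a configuration object and one root seed.

## The generative model

Each patient is generated hierarchically:

1. **Demographics.** Age ~ Normal(28, 5) years clipped to [18, 45]; BMI ~
   Normal(24, 4) kg/m² for age < 30 and Normal(26, 4) for age ≥ 30, clipped
   to [16, 45]; booking gestational age ~ Normal(10.2, 2.3) weeks clipped to
   [6, 14]; ethnicity ~ Categorical(Caucasian .40, Asian .25, Hispanic .15,
   African .12, other .08). Clipping (censoring) rather than rejection
   sampling is used: it is simpler, and the small boundary mass (≈2% of ages
   at 18) is accepted and shrinks the realized age SD to ≈4.9.

2. **Composite risk score.**
   `S = 0.1 (age − 25) + 0.15 (BMI − 23) + 1.5·familyHx + 2.0·prevGDM +
   1.0·PCOS + 1.2·macrosomia + 0.8·[Asian or Hispanic]`.
   The score may be negative for young, lean patients.

3. **Risk factors.** Each binary factor (family history 25%, previous GDM
   12%, PCOS 15%, previous macrosomia 10%) is Bernoulli with probability
   `plogis(a + 0.3·S_demo)`, where `S_demo` is the demographic part of the
   score and the intercept `a` is solved numerically per cohort so the
   marginal prevalence equals the configured value exactly in expectation.
   The tilt makes risk factors co-occur with demographic risk (monotone in
   the score) without distorting prevalences; tilt 0 recovers independent
   draws.

4. **Laboratories.** Each analyte is Normal(base_mean + shift·S, base_sd)
   clipped to its reference range. The OGTT triple is drawn only for the
   tested subset — the top 29.5% of `S` plus standard-Gumbel noise — which
   emulates selective testing of higher-risk patients; untested patients
   carry missing values in all three OGTT columns.

5. **Outcome.** The GDM probability is
   `p = clip(0.10 + 0.254·S + increments, 0, 0.95)`, where the increments
   come from the shared clinical tier table: RBS ≥140: +0.40 else ≥125:
   +0.20; PPBS ≥180: +0.30 else ≥160: +0.15; HbA1c ≥6.5: +0.50 else ≥6.0:
   +0.25 else ≥5.7: +0.10; and any OGTT diagnostic criterion (fasting ≥92,
   1-h ≥180, 2-h ≥153 mg/dL) adds +0.40. Within one analyte only the single
   highest crossed tier applies — the increments are read as *absolute*
   probability additions (the model is stated as a sum, which a
   multiplicative reading would contradict), and tier non-cumulation
   prevents a single HbA1c of 6.6% from adding 0.85 on its own. The
   diagnosis is one Bernoulli draw from `p`.

Every stage draws from a named substream of the root seed
(`stage_seed(root, "labs")` etc.), so adding or modifying a downstream stage
never perturbs upstream draws, and identical configurations give
byte-identical cohorts.

### Calibration constants and what they mean

The study design fixes the marginal *targets* (RBS 109.1 ± 18.8 mg/dL, PPBS
142.5 ± 24.2, HbA1c 5.72 ± 0.58%, tested-subset OGTT means 98.5/181.4/156.3,
overall ≈65% GDM-positive) but not the underlying constants, so the package
solves them once and ships them as config defaults:

* `base_mean`/`base_sd` per analyte — chosen so the *cohort* marginals hit
  the targets after score-coupling and clipping;
* `shift` per analyte — the score coupling (mg/dL or % per score unit). The
  defaults (HbA1c 0.15, RBS/PPBS 3, OGTT 2/5/4) produce feature–outcome
  correlations of roughly 0.2–0.4, strongest for HbA1c, which as the
  long-horizon glycemia marker should track underlying risk most closely;
* `score_to_prob_coeff = 0.254` — solved so the mean outcome probability is
  0.65. With the increment structure fixed, this coefficient is the only
  free link between the clinical score and the outcome, and the 0.65 target
  pins it.

A note on the positive fraction: the source narrative is internally
inconsistent (≈35% in one place, 65% positive with a 1,318/2,000-positive
test set elsewhere); the package follows the 65% profile because the split
counts, the rebalancing arithmetic and the confusion matrix all corroborate
it. A 35% profile is a one-line config change
(`score_to_prob_coeff` recalibrated against a 0.35 target).

All weights, prevalences, ranges and calibration constants live in
`gdm_config()`; nothing is hard-coded in the generator.

## Preprocessing

The pipeline order is fixed: one-hot encode ethnicity (drop-first, African
as the all-zeros reference) → zero-impute missing OGTT → stratified 80/20
split (seed 42, largest-remainder per-class allocation, ties by class
order) → standardize continuous features with train-fitted parameters →
SMOTE on the training partition only.

Zero-imputation deliberately creates a three-state encoding (elevated /
normal / not-tested), preserving the clinically meaningful signal that the
test was not ordered. Imputation precedes scaling so the OGTT columns are
standardized like every other continuous feature. Binary flags and
ethnicity indicators are excluded from scaling to keep their interpretable
0/1 states.

SMOTE synthesizes minority rows as `x + u (x_nn − x)` with `u ~ U(0,1)` and
`x_nn` one of the k = 5 nearest minority neighbours (Euclidean, in the
post-scaling space). It runs on the fully encoded matrix, including binary
columns, so synthetic rows may carry fractional flag values; this is
accepted and documented — a categorical-aware variant is out of scope. The
minority count must exceed k.

## Consensus feature importance

Seven methods, each min–max normalized to [0, 1] (a method whose raw scores
are all equal normalizes to all-ones): impurity importance from a
100-tree random forest and from a 100-tree extra-randomized forest; one-way
ANOVA F-scores; mutual information (a k-nearest-neighbour estimator with
k = 3 for continuous features, exact plug-in for binary ones, with tiny
seeded jitter to break ties); permutation importance (mean accuracy
decrease over 10 shuffles of each feature, evaluated on a seeded 2,000-row
subsample of the training matrix — a performance choice that leaves the
estimator unbiased); recursive backward elimination on standardized
logistic-regression coefficients, run to completion so every feature
receives an elimination rank (score `(p − rank + 1)/p`); and absolute
Pearson correlation (constant features score 0 with a warning).

The consensus table averages normalized scores across methods and reports
the sample SD of per-method ranks (fractional ranks for ties). Selection
takes the k = 10 features with the highest average, ties broken by lower
rank SD then name. Importance runs on the SMOTE-balanced training matrix,
matching the modelling data; a pre-SMOTE run is a documented switch (pass
the unbalanced matrix).

## The benchmark

Eleven classifiers: random forest and extra-randomized trees (100–200
trees, depth ≤ 15), three gradient-boosting variants (depth ≤ 6, learning
rate 0.1; one classic exact-split configuration, one regularized
deeper-tree configuration, and one histogram/leaf-wise configuration),
ridge-penalized logistic regression, k-nearest neighbours, Gaussian naive
Bayes, an RBF-kernel SVM with Platt-scaled probabilities, an MLP (100, 50)
and a deep network 128→64→32→16→1 with dropout 0.25 and batch
normalization. The two networks are trained by the package's own
matrix-algebra implementation (Adam, batches of 32, 20% internal validation
split, early stopping with patience 20, learning-rate halving on a 10-epoch
plateau, best-epoch weight restoration), since the protocol requires
architectures no installed R package provides.

Hyperparameters are tuned by exhaustive search over small per-model grids
under 10-fold stratified cross-validation on the training partition,
scored by support-weighted F1; singleton grids (naive Bayes, SVM, the two
networks) skip CV and train directly, which the protocol permits. The
decision threshold is fixed at 0.5 throughout.

Evaluation on the untouched, imbalanced test partition reports accuracy,
support-weighted precision/recall/F1, and midrank AUC-ROC. For binary
labels, support-weighted recall is algebraically identical to accuracy;
the package asserts this identity on every metrics row. Zero-denominator
metrics are reported as undefined (NA), never as 0. Models are ranked by
weighted F1, ties broken by AUC then name.

## Attribution

Kernel SHAP estimates Shapley values by weighted least squares over
feature coalitions with the Shapley kernel weight, masking absent features
with the 100 raw background rows (no clustering, matching the plain
sampling design). The additivity constraint — base value plus the sum of
contributions equals the prediction — is imposed exactly in the
regression, so local accuracy holds to numerical precision even with
sampled coalitions (default budget 2,048 per instance; at p ≤ 11 the full
coalition space is enumerated with exact kernel weights, making the result
the exact Shapley value of the masked game). The explain set is a
stratified sample of 50 test instances (33 positive, 17 negative);
global importance is the mean absolute contribution per feature; the
waterfall ledger orders one instance's contributions by magnitude with a
running cumulative sum.

Correctness is checked against a brute-force enumeration oracle (all
subsets, p ≤ 4), the closed form for linear models, and symmetry/dummy
axioms under Monte-Carlo noise.

## Clinical tiers

Tier boundaries (RBS ≥125 borderline / ≥140 concerning; PPBS ≥160 / ≥180;
HbA1c ≥5.7 intermediate / ≥6.0 high / ≥6.5 diagnostic; OGTT fasting ≥92,
1-h ≥180, 2-h ≥153 diagnostic) are all inclusive and live in one shared
table that both the tier classifier and the simulator's outcome model
read, so an increment fires exactly when the matching tier is reached —
this consistency is tested on dense grids.

## What the simulator does and does not emulate

Passing tests show that the package reproduces the *stated* generative
design and its marginals — not that any model here would perform
comparably on real patients. Known departures from real data: laboratory
values are conditionally Gaussian (real glucose distributions are
right-skewed); parity is not modelled, so previous-GDM/macrosomia are
marginal prevalences rather than multiparous-conditional ones; pregnancies
are single time points; no treatment effects; and the outcome is exactly
the stated threshold model plus one Bernoulli draw, so its noise floor is
knowable in a way no clinical outcome is. The published per-model F1/AUC
values and importance averages are seed- and implementation-dependent and
are treated as statistical tendencies, not exact targets.

## Numerical and design choices

* Truncation by clipping everywhere; boundary mass documented above.
* The flag-tilt intercept is solved by `uniroot` to 1e-10 on [−30, 30].
* Ranks use deterministic tie-breaks (feature-name order) in importance
  vectors, fractional ranks in consensus SDs.
* AUC uses midranks, so constant scorers give exactly 0.5.
* The OGTT tested subset has exactly `round(0.295 n)` members (rank-based
  selection), not a Bernoulli count.
* Problem sizes in the test suite: marginal recovery runs 20 cohorts of
  10,000; the benchmark property runs once at n = 10,000 with 10-fold CV;
  the consensus-stability property runs 20 cohorts of 10,000 with a
  1,500-row permutation-importance subsample; attribution oracles run at
  p ≤ 4 with 8–15 background rows. These sizes give per-seed standard
  errors small enough for 3-SE assertions while keeping the suite fast.

## Known limitations

* The consensus ranking places the OGTT columns high: under selective
  testing of high-risk patients plus zero-imputation, "was tested at all"
  is itself strongly informative, and the +0.40 OGTT increment makes the
  tested values genuinely predictive. A published analysis of the same
  design that excludes OGTT from its top features cannot be reconciled
  with that design's own increment structure; the package reports what the
  generative model implies.
* With the outcome probability a deterministic function of observed
  features plus one Bernoulli draw, the Bayes accuracy of the default
  cohort is ≈0.81 (about 39% of patients sit at the 0.95 probability cap —
  a consequence of summing the stated increments under a 65% positive
  target); the strongest learners approach but do not reach it, so the
  achievable F1 ceiling sits near the top of the published range.
* SMOTE on one-hot columns yields fractional indicator values in synthetic
  rows (accepted, see above).

## A small worked run

```{r smoke, eval = FALSE}
run <- run_gdm_pipeline(gdm_config(n_patients = 1000, seed = 42),
                        cv_folds = 5)
run$manifest$leaderboard
head(run$consensus[, c("feature", "average", "rank_sd")])
global_importance(run$attributions)
```
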
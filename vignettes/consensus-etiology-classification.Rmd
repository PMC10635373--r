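---
title: "Ensemble consensus classification of ischemic stroke etiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble consensus classification of ischemic stroke etiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Determining why an ischemic stroke happened — large-artery atherosclerosis
(TOAST class 1), cardioembolism (2), small-vessel disease (3), another
determined etiology (4), or no identified cause (5, "cryptogenic") — drives
secondary prevention, yet 20–30% of strokes are discharged cryptogenic.
`etioclass` implements an automated etiology classifier over features
extracted from semi-structured discharge-summary text, and a certainty
heuristic that either assigns a cryptogenic stroke a concrete etiology or
abstains ("persistently cryptogenic").

The model is a *consensus meta-classifier of nine members*. Five
probabilistic base learners are trained on the four non-cryptogenic classes:
multinomial logistic regression (LR), an RBF support-vector classifier with
Platt-calibrated probabilities (SVC), a random forest (RF), gradient-boosted
trees (XGB), and SVC2 — the support-vector model re-read through an
alternative probability rule, a softmax over its four one-vs-rest decision
margins. From the five base probability rows $p^{(m)} \in \Delta^3$, four
summary-statistic ensembles are formed per class $c$ and renormalized:

$$q^{(s)}_c = \frac{s\big(p^{(1)}_c,\dots,p^{(5)}_c\big)}
  {\sum_{k=1}^{4} s\big(p^{(1)}_k,\dots,p^{(5)}_k\big)},
  \qquad s \in \{\mathrm{mean}, \mathrm{median}, \max, \min\}.$$

Each of the nine members votes its argmax class; the meta-prediction is the
plurality label and its **consensus support** is the number of members
voting for it (3–9 by pigeonhole). Vote ties are broken by the higher
MEAN-ensemble probability, then by the lower class code — a deterministic
rule we fixed because plurality ties are otherwise unresolvable.

## Cryptogenic reclassification

Cryptogenic strokes never enter training: they are plausibly a mixture of
the four mechanisms, so their labels are not trustworthy class evidence.
Instead, the fitted meta-model predicts each cryptogenic record, and a
per-class support threshold $t_c$ decides whether to commit: the record is
assigned its plurality class $c$ iff its support $s \ge t_c$, otherwise it
stays persistently cryptogenic. Thresholds are the per-class first quartiles
(linear interpolation between order statistics, hence fractional values) of
the support counts observed on a validation cohort; the package also ships
the published reference set $t = (7, 9, 7.2, 7)$ via
`reference_thresholds()`. Raising any $t_c$ weakly increases abstention — a
property the tests assert.

Reclassified cohorts are profiled by `signature_features()`: binary features
present in more than half of any predicted class, chi-squared tested (no
continuity correction — the correction is a small-sample 2×2 device and the
uncorrected statistic matches the textbook closed form the tests pin down)
for class specificity at p < 0.01.

## Feature schema and discretization

Features come in six families: DEMO (age, sex), CUI (binary concept
indicators named by UMLS-style identifiers), RAD (radiology), HRT
(cardiac), HEX (clinical history/exam) and LAB (laboratory). Sixteen cutoff
rules discretize noisy continuous measurements into `high`/`normal`(/`low`)
levels — e.g. NIHSS at 6, sodium at 136, hematocrit at 46/35, hemoglobin
sex-specifically at 15.5/11.7 (female) and 17.1/13.2 (male). The boundary
convention is strict (`value > hi` is high, `value < lo` is low, ties are
normal); the printed rules do not state inclusivity, so we chose strictness
once, for determinism. The labels are positional, not clinical: ejection
fraction's cutoff of 40 marks its *high* side even though low EF is the
abnormal finding.

`feature_group_registry()` enumerates 24 named training-dataset
configurations: three age+sex encoding variants, seven single-family sets,
eight multi-family combinations (including the flagship full discretized set
`combn1d.age.sex.v1`), two MaxInfo-filtered variants, and four PCA variants.
The `v1`/`v2`/`v3` suffixes are not defined anywhere we could consult, so
the package defines them as age-encoding variants (continuous, dichotomized
at 65, standardized) — a design choice stated here rather than hidden.
`maxinfo_filter()` keeps samples with at least four of the five
non-demographic families observed (a family counts as present with one
observed value). Four families × 24 datasets makes the canonical 96-task
hyperparameter sweep that `hpo_tasks()` enumerates.

## Text extraction

`render_note()`/`extract_note()` are a matched pair: the generator writes
semi-structured notes (site-specific headers, identical content encoding)
and the extraction layer recovers age from the first "`<n> year old`"
pattern, sex by counting the pronouns *her* versus *his* (word-bounded;
equal counts give a missing sex rather than a guess), registered numerics
(NIHSS, blood pressure, respiratory rate, ejection fraction, 13 labs) by
first-match-wins regular expressions, and concept indicators by dictionary
phrase matching with a 3-token negation window that never crosses a
sentence boundary. On these templates the round trip is exact by
construction — which is the point: it isolates every downstream failure
from extraction noise. Real clinical text is far messier; the dictionary
tagger is a deliberate toy stand-in for full concept normalization, and
nothing here models negated findings prose, abbreviation ambiguity, or
word-sense disambiguation.

## Imputation and PCA

`impute()` offers single-completion predictive mean matching (each
incomplete column regressed on the rest, missing cells borrowing the
observed value of one of the k = 5 nearest-predicted-mean donors, so imputed
values stay in the observed support) and a per-column random-forest method
that tolerates larger missing fractions. Both are deterministic under their
seed and are the identity on complete data. Multiple-imputation pooling is
out of scope: the pipeline consumes one completed dataset.

`pca_fit()` standardizes the training matrix (configurable), fits principal
components on training data only, and selects, for each threshold in
{0.10, …, 0.90, 0.95, 0.99} (eleven values), the smallest component count
reaching that cumulative fraction of total variance; `pca_apply()` projects
new data with the training means, scales and loadings only, so no
information leaks from validation to training.

## Evaluation harness

`rmfcv_plan()` encodes the repeated multi-fold CV design: 2/3/4/5/10-fold
CV with 30/20/15/12/6 repetitions — 60 repetitions, 300 train/validation
splits. Repetition *r* (counted across the whole plan) derives its seed as
`base_seed + r`. Splits are stratified: within a repetition the folds
partition the cohort exactly and per-fold class counts differ by at most
one. `compute_metrics()` reports the seven-metric weighted one-vs-rest
panel (AUCROC, AUPRC as average precision, accuracy = weighted recall,
balanced accuracy, precision, F1, Cohen's kappa) plus per-class breakdowns;
balanced accuracy is macro recall by default with the
mean-of-sensitivity-and-specificity reading available by flag, since the
two common definitions disagree for multiclass data. Kappa values map to
the Landis–Koch bands via `kappa_band()`.

Feature importance comes in two flavors: classifier-agnostic univariate
one-vs-rest t and Kolmogorov–Smirnov tests, and `shap_adapter()`, a
permutation-sampling Shapley-value estimator (background distribution
summarized by k-means with k = 100 centers). The estimator credits each
feature the change in class probability as features are switched
one-at-a-time from a background row to the instance's values along sampled
permutations; it is exact in expectation, assigns exactly zero to a
constant model, and is deterministic under its seed.

## The synthetic cohort: what it does and does not emulate

Real discharge summaries cannot ship with a package, so
`generate_cohort()` produces cohorts with the statistical structure the
pipeline assumes: five-class labels at the merged derivation priors
(0.21, 0.31, 0.13, 0.09, 0.26); class-conditional effects planting the
etiology-typical associations (carotid stenosis/occlusion and
atherosclerosis in class 1; atrial fibrillation, left-atrial enlargement
and intracardiac thrombus in class 2; basal-ganglia/thalamus locations in
class 3; hypercoagulability and markedly younger age in class 4); two sites
with distinct note templates, per-family missingness near the reported
completeness (4–10%, labs least complete) and a mild additive covariate
shift at the second site. Cryptogenic records carry a hidden latent class
(or none, with probability 0.2) whose effects are attenuated toward the
null by a factor of 0.7 — strong enough to be recoverable above chance,
weak enough that abstention has something to do.

Choices a reader should know: binary features are independent Bernoulli
given class (no correlation model), missingness is MCAR within family, age
is a class-shifted normal clipped to [18, 100], and effect sizes were fixed
once at values giving a clearly separable but imperfect problem. Passing
tests on this cohort demonstrate that the machinery is correct — proper
probabilities, exact partitions, monotone abstention, above-chance latent
recovery — not that any particular real-data accuracy would be achieved;
real-data performance claims are explicitly out of scope.

## Worked example

```{r, eval = FALSE}
library(etioclass)

coh  <- generate_cohort(generator_config(n = 2000, seed = 11))
prep <- prepare_matrix(coh, impute_seed = 1)     # full discretized dataset
tr   <- prep$y %in% 1:4                          # cryptogenic never trains

res <- rmfcv_evaluate(prep$x[tr, ], prep$y[tr], fast_params(),
                      rmfcv_plan(folds = c(2, 5), reps = c(1, 1)))
mean(res$split_metrics$accuracy)                 # consensus CV accuracy

fit <- etio_ensemble(prep$x[tr, ], prep$y[tr], params = fast_params())
th  <- quartile_thresholds(res$predictions$pred, res$predictions$support)
cry <- predict(fit, prep$x[prep$y == 5, ])
table(reclassify_cryptogenic(cry$pred, cry$support, th))
```

The problem sizes used throughout the tests and the acceptance script —
n = 2,000 cohorts, a reduced RMFCV plan of one 2-fold plus one 5-fold
repetition, and single fixed hyperparameters per family via
`fast_params()` — are the package's chosen desk-scale study conditions: big
enough for stable estimates (binomial SE on an accuracy at n ≈ 1,500
validation predictions is under 1%), small enough to rerun anywhere. The
full 300-split plan and full grids remain available and are exercised
structurally (split counts, partition and stratification invariants) rather
than by brute force.

## Known limitations

* SVC2's probability rule is this package's declared construction (softmax
  of one-vs-rest margins, temperature 1), isolated in one function; other
  calibrations could be swapped in.
* The extraction layer is validated only against the package's own note
  templates; its regexes are reconstructions, not a clinical NLP system.
* The synthetic generator's independence and MCAR assumptions understate
  real EHR correlation and informative missingness.
* Class weighting is not applied during training; imbalance is handled at
  evaluation through class-support-weighted metrics.
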
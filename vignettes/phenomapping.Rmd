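---
title: "Phenomapping subclinical diastolic dysfunction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenomapping subclinical diastolic dysfunction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfpefmap)
```

## The analysis in one paragraph

`hfpefmap` takes a patient-by-variable table of mixed categorical and
numeric clinical/echocardiographic measurements, with missing entries and
right-censored event times, and asks two questions. First, *do the patients
fall into phenotypically coherent subgroups (phenogroups) that differ in
their risk of progressing from subclinical diastolic dysfunction (DD) to
HFpEF?* — answered by unsupervised hierarchical clustering on squared
Euclidean distances over the encoded variables, with the number of clusters
chosen by how strongly HFpEF frequency separates across them. Second,
*which variables predict progression?* — answered by logistic risk models
with a prevalence classification cutoff, validated by alternating two-fold
cross-validation, and complemented by Kaplan–Meier disease-trajectory
comparisons. Outcome and survival columns are withheld from the clustering
inputs by construction (the pipeline refuses to encode them), so the
phenogroups are formed blind to what they are later evaluated against.

## Preprocessing model

**Outlier screen.** A patient is removed when any numeric variable lies at
least `z_threshold` (default 8) standard deviations from the column mean,
with moments computed over observed values including the candidate. The
screen removes whole patients, not values, reflecting the view that a
multi-measurement excursion of that size indicates an unreliable record.
It is a single pass, hence idempotent at a fixed threshold; zero-variance
columns are skipped with a warning.

**Encoding.** Full one-hot encoding is used: an L-level variable becomes L
indicator columns, not L−1. For distance computation the redundancy is
harmless (it scales each categorical variable's contribution equally) and
it matches the "each category as its own yes/no dichotomy" reading of the
underlying design. Missingness propagates to all of a variable's
indicators, and the invariant "indicators of an observed variable sum to
exactly 1" is enforced by tests.

**SVD imputation.** Missing cells are initialised at their column means and
the loop *truncated SVD reconstruction → overwrite missing cells* is
iterated until the relative Frobenius change of the imputed entries falls
below `tol`. Defaults: `rank = 5`, `tol = 1e-6`, `max_iter = 500`. Columns
are centred and scaled inside the iteration — recomputed from the current
completed matrix each sweep — and restored afterwards. Recomputing the
moments matters for correctness: it makes any exactly low-rank matrix a
fixed point of the iteration (a rank-1 matrix with one masked cell is
completed to machine precision, which the tests assert). The price is
linear convergence; on the default 161 × 107 cohort the iteration needs a
few hundred sweeps of a ~5 ms SVD to reach `tol`, which is why the
iteration cap is 500 rather than a double-digit number. Non-convergence is
reported as a flag and warning, never an error, and observed entries are
returned bit-identical. A column with no observed values is rejected.

**Standardisation.** Before distances, numeric-provenance columns are
scaled to mean 0, SD 1 (population convention, divisor n) by default
(`numeric_only`); indicator columns are left at 0/1. Without this,
variables on large raw scales (NT-proBNP in the thousands of pg/mL) would
dominate the squared Euclidean distance. A `none` policy reproduces the
literal unscaled computation, and `all` also scales indicators. The
transformation records its parameters and inverts exactly.

**Clinical grading.** DD severity is graded solely from the E/A ratio and
average e′ (cm/s): mild (E/A < 1), moderate (1 ≤ E/A < 2), severe
(E/A ≥ 2), all within the e′ ≤ 9 cm/s domain; for e′ > 9 the scheme does
not apply and `indeterminate` is returned rather than a guess. CKD stages
are half-open GFR intervals ([60, ∞) stage 1–2, [45, 60) 3a, [30, 45) 3b,
[15, 30) 4, below 15 stage 5); the half-open convention resolves the
boundary ambiguity of the usual printed ranges ("45–59", "30–45") in favour
of the stage with the higher GFR at 45 and continuity at 60.

## Clustering and cluster-count selection

The distance is the squared Euclidean metric on the encoded, imputed,
scaled matrix. Agglomeration is implemented in-package with the
Lance–Williams updates (Ward on the squared distances by default; complete,
average, single also available) and a deterministic tie-break: among
minimum-dissimilarity pairs, the lexicographically smallest pair of cluster
indices merges first, a cluster inheriting the index of its oldest member.
This makes the merge sequence — and therefore the whole analysis —
bit-reproducible. The tests verify the merge heights and all cut partitions
against base R's `hclust` on random (tie-free) inputs, and a
density-reachability clustering (`eps`, `min_pts` on the squared-distance
scale, noise reported as unassigned) is provided as the non-hierarchical
alternative.

Cuts at k = 2…5 are scored by (i) the Pearson chi-square test (no
continuity correction, df = k−1) of whether HFpEF frequency is homogeneous
across clusters, and (ii) purity, the fraction of patients sharing their
cluster's majority outcome. `select_k` picks the k with the smallest
homogeneity p, breaking ties toward the smaller k; because published
cluster-count choices typically also weigh qualitative considerations, the
full evaluation table is returned so a user can override the selection.
Clusters are lettered A, B, C… by decreasing HFpEF frequency.

A caution established while validating this operationalisation: minimum-p
selection over nested cuts has a structural appetite for extra clusters.
Splitting a homogeneous cluster adds a noise degree of freedom that lowers
the minimum p in a nontrivial fraction of datasets, so even under a cleanly
planted three-group outcome structure (frequencies 0.7/0.6/0.4 at n = 160)
the three-cluster cut is chosen in only roughly seven out of ten runs, with
most of the remainder going to k = 2 or a k = 4 refinement. The acceptance
suite measures exactly this recovery rate; treat `select_k` as a screening
device whose evaluation table deserves inspection, not an oracle.

## Comparative statistics

`chi_square_test` computes the Pearson statistic from first principles with
the Yates continuity correction (deviations clamped at zero) applied to
2 × 2 tables only — the convention pinned by the bundled fixtures, where
the 2 × 2 mortality table reproduces its reference p-value only *with* the
correction and every larger table only *without* it. No minimum expected
count is enforced (one bundled 3 × 5 fixture has expected counts below 1 by
design); a warning is attached instead. ANOVA is the classic fixed-effects
F test on complete cases. Newman–Keuls and Duncan are implemented with the
shared stepwise studentized-range machinery: means ordered, ranges tested
widest first against `qtukey` quantiles at df = N−k, the harmonic mean of
group sizes standing in for a common n, and non-rejected ranges blocking
all inner pairs (stepwise consistency, asserted as an invariant). Duncan
differs only in its protection level 1−(1−α)^(span−1), which makes its
rejections a superset of Newman–Keuls's — also property-tested. The group
comparison report applies no multiple-testing adjustment across variables;
every p-value is marginal, and the report says so rather than hiding it.

## Risk modelling

Fits are binomial GLMs (IRLS, coefficient tolerance 1e-8, 50 iterations)
on complete cases. Models are displayed in the clinical
exponent-subtraction form `P = 1/(1 + exp(a − Σ (0 or b)·factor ± c·x))`,
which is algebraically the standard `plogis` parameterisation with
`a = −b0`; the two evaluation routes agree to 1e-12 by property test.
`select_predictors` operationalises progressive model building: univariate
Wald screening at `alpha` (default 0.05), addition in order of univariate
significance, collinearity pruning (drop the less significant of a pair
when an included variable loses significance and its correlation with the
newcomer exceeds `collinearity_r`, default 0.5 — the threshold is a design
choice, exposed as configuration), and final pruning until every retained
variable is significant adjusting for the others. The classification
cutoff equals the complete-case outcome prevalence, with strictly-greater
comparison; `classify` reports the confusion matrix, sensitivity and
specificity. Odds ratios are `exp(|b|)` for binary history variables and
`exp(b)` per unit for continuous terms. Alternating two-fold
cross-validation orders patients by identifier within each outcome stratum,
assigns them alternately to two folds (per-stratum sizes differing by at
most one), refits on each fold and scores both folds in both directions; a
covariate that degenerates inside one fold is dropped there with a warning
rather than aborting the validation. Wald tests were chosen for
per-coefficient significance; diastolic wall strain, where absent from an
input table, can be derived as (LVPWs − LVPWd)/LVPWs.

The three shipped risk equations are fixtures, not fits: evaluable models
whose coefficients, cutoffs (53.0%, 61.8%, 41.3%) and qualitative
behaviour (any single factor multiplies the odds 3–4-fold; two or more of
the four whole-cohort factors push P above the cutoff across all 16
covariate patterns, verified by enumeration) are pinned by tests. The
"all four factors" joint odds ratio implied by the rounded printed
coefficients is exp(1.14+1.37+1.08+1.39) ≈ 146, and the package makes no
claim beyond what those rounded coefficients imply.

## Survival summaries

Kaplan–Meier estimation and log-rank tests go through the `survival`
package, with the package's tests independently re-deriving the
product-limit arithmetic and the per-event-time hypergeometric sums. The
median convention is the first time at which S(t) ≤ 0.5 (undefined if never
reached). Four endpoints are reported per phenogroup and stratum: time
DD→HFpEF (non-progressors censored at their last known time alive), age at
HFpEF, time HFpEF→death (progressors only), and age at death. The log-rank
test is used for between-group comparisons; this is a design choice where
a Wilcoxon-weighted alternative would also have been defensible. Median
times from any particular cohort are data-dependent, so tests check
orderings (faster-progressing clusters have smaller medians) rather than
values.

## What the synthetic generator emulates — and what it does not

`default_cohort_spec()` encodes the study conditions the pipeline is
designed for: 161 patients in three latent phenogroups (7/59/95); 46
numeric and 19 categorical variables whose per-cluster means follow the
published phenogroup summaries (a small severe-hypertrophy/aortic-stenosis
group, an intermediate group, a larger low-LV-mass predominantly female
group); log-normal (moment-matched) biomarkers such as NT-proBNP; MCAR
missingness at per-variable rates chosen from the published per-variable
n's (NT-proBNP observed for ~44% of patients); a logistic outcome model on
diabetes, CKD, atrial fibrillation and diuretic use with intercept −1.94
and coefficients 1.14/1.37/1.08/1.39, giving ~50% HFpEF prevalence; and
exponential progression hazards with medians 1.7/5.3/9.4 years by cluster,
death hazards of 0.075/0.060/0.045 per year, and administrative censoring
at 12 years. One planted patient with LVOT measurements 12 SD above the
mean (far enough that the value remains ≥ 8 SD out even after inflating
the column SD it is part of) exercises the 162 → 161 screening step.

Because the outcome indicator must coincide with an observed HFpEF event,
progressor event times are drawn from the horizon-truncated exponential
(inverse-CDF), i.e. conditioned on occurring inside the censoring window;
non-progressors are censored at death or at the horizon. This is a
generator design choice, made so that prevalence and event observation
stay mutually consistent.

The generator emulates *shape and scale*, not the real cohort's joint
distribution: variables are drawn independently within clusters (no
realistic correlation structure beyond cluster membership), missingness is
MCAR only (no MAR/MNAR mechanisms), hazards are exponential (a Weibull
shape could be added via the spec but is not default), and categorical
co-morbidity probabilities are cluster-wise marginals. Passing tests on
synthetic data therefore demonstrate that the *machinery* is correct and
that planted structure of realistic magnitude is recoverable — not that
any particular clinical finding would replicate.

## Numerical choices and degenerate inputs

* Tie-breaks: lexicographic smallest cluster-index pair in agglomeration;
  smaller k on equal selection p-values; events before censorings at tied
  survival times.
* Tolerances: imputation `tol = 1e-6` (relative Frobenius change of imputed
  entries); IRLS 1e-8; distance symmetry enforced exactly by averaging.
* Degenerate inputs: zero-SD columns are skipped (screen) or left untouched
  (standardisation) with warnings; empty clusters, zero marginals,
  single-class outcomes and rank-deficient designs are rejected with the
  offending column named; fewer than three groups falls back from
  range tests to a pairwise t test with a warning; an all-censored sample
  yields S ≡ 1 with an undefined median.
* Determinism: every stochastic step consumes an explicit seed; two
  pipeline runs from one configuration produce byte-identical artifacts
  (asserted on checksums).

## Test problem sizes

The suite validates against brute-force oracles at small n (agglomeration
n ≤ 8 plus one n = 40 instance; density clustering n = 40; log-rank n = 30)
and uses moderate simulations elsewhere: logistic recovery at n = 5000
averaged over replicates (a single fit's sampling SE, ~0.075, is of the
same order as the 0.15 recovery tolerance), cluster-recovery and selection
studies at n ≈ 160–400 with 200 replicates, and null Monte-Carlo studies of
the post-hoc procedures at 1500 replicates. These sizes were chosen to keep
the full suite in the tens of seconds while leaving each check's Monte
Carlo error well inside its asserted margin.

## Known limitations

* `select_k`'s minimum-p rule has the over-splitting appetite described
  above; use the evaluation table.
* The collinearity rule in `select_predictors` uses pairwise association
  only; it will not detect three-way aliasing short of the final
  rank-deficiency check.
* Risk-model coefficients — including the shipped fixtures — are
  prevalence-specific and do not transport to populations with different
  HFpEF base rates; the prevalence cutoff makes this explicit.
* No Cox regression, competing risks, consensus clustering or gap/silhouette
  selection: deliberately outside this pipeline's scope.
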
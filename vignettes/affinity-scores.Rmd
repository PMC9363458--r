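---
title: "Affinity-score fingerprints: model, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Affinity-score fingerprints: model, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affinityscores)
```

## The problem

Group-average biomarker analyses assume diagnostic categories are
mutually exclusive and internally homogeneous. Neuropsychiatric cohorts
violate both assumptions: symptoms overlap across diagnoses and people
sharing a diagnosis differ widely across clinical, cognitive,
psychosocial and brain-structural measures. This package implements an
individual-centric alternative: every participant is scored, variable by
variable, by the diagnostic composition of their local neighbourhood in
the cohort, producing a multi-domain *fingerprint* of graded group
affinities rather than a single hard label.

## The model

All variables are z-scored against the pooled sample (all groups
together, sample SD with denominator $n-1$). For each variable $v$ a
**hop size**

$$h_v = \frac{\sum \text{consecutive gaps of sorted group means}}{\alpha G}$$

sets the half-width of the neighbourhood window in SD units, where $G$
is the number of groups and $\alpha > 0$ a scaling constant. The
numerator is often written as a sum of differences of successive group
means $|\mu_{g-1}-\mu_g|$, which leaves the first term undefined; we
resolve it by sorting the group mean z-scores ascending and summing the
$G-1$ consecutive gaps (equal to the range of the group means), keeping
the $\alpha G$ denominator. The window is
closed on both ends: a participant exactly at distance $h_v$ is a
neighbour.

The neighbourhood $\Psi_p^v$ of participant $p$ is every participant
with $|z_j - z_p| \le h_v$. With $f_g$ the number of group-$g$ members
of $\Psi_p^v$, $s_g$ the group size and $N_s$ the total sample size,

$$F_{p,g}^v = \frac{f_g}{s_g}\cdot\frac{\sum_g f_g}{N_s}.$$

The first factor measures how much of group $g$ the window captures,
the second scales by the local density; a window covering the whole
sample scores 1 for every group, an empty window scores 0. Including
$p$ in $\Psi_p^v$ gives **verification mode** (checking assigned
diagnoses); excluding it gives **classification mode** (the
self-excluded scores, and scores of held-out participants, behave like
a classifier).

Five multivariate metrics aggregate the $V$ variable-wise vectors:

* **composite** — the mean of $F_{p,g}^v$ over variables: a $1/V$
  normalisation of the $V$-term sum (the constant is sometimes written
  $1/G$; the choice cannot change any argmax label, because a shared
  positive rescaling is order-preserving, and $1/V$ matches the
  "average across variables" reading).
* **rank-based** — within each variable, groups are ranked $1..G$
  ascending by affinity (ties averaged); scores are mean ranks, so row
  means are always $(G+1)/2$.
* **vote-based** — each variable casts one vote for its argmax group;
  $m$-way ties split the vote $1/m$ so votes always total $V$.
* **common neighbourhood** — from the summed variable adjacency
  matrices $A^C = \sum_v A^v$ (with $A^v_{ij} = 1$ iff $j \in \Psi_i^v$,
  $j \ne i$), the group-averaged count
  $F^C_{p,g} = \frac{1}{s_g}\sum_{k \in g} A^C_{p,k}$.
* **common community** — Louvain modularity maximisation partitions
  each variable's adjacency graph; $A^{CC}$ counts, per pair, the
  variables on which they share a community, averaged by group as
  above. A participant belongs to exactly one community per variable;
  isolated participants are singletons.

Labels are argmax over groups. Ties are resolved deterministically: in
verification the participant's assigned label wins if it is among the
tied groups; otherwise (and in classification) the tie is broken by the
composite score restricted to the tied groups, then by the lowest group
index. An all-zero vector (possible only with self excluded) falls back
to the composite, and is `"indeterminate"` only if that is also zero.

## Parameters that matter

* `alpha` (default 6) — the only real tuning knob. $h_v \propto
  1/\alpha$, so larger values shrink every neighbourhood; accuracy is
  non-monotone in `alpha` and depends on sample size, so the classifier
  must be re-tuned whenever the reference sample changes
  (`nested_cv()`, then `tune_alpha()` on the full training set — the
  final model uses the full-training tuning, not the best inner-loop
  value). On tied tuning accuracy the smallest `alpha` (widest, most
  stable neighbourhoods) is selected.
* decision metric — `common_neighbourhood` by default, following the
  observation that neighbourhood- and community-based metrics carry the
  most classification signal while the vote metric is the most lenient
  verifier.
* KNN baseline — inverse-distance-weighted KNN on standardized
  Euclidean distance, $K$ tuned over 5..15 in the same nested harness.
  Zero-distance neighbours dominate the vote (infinite-weight
  convention, matching the reference implementation's documented
  behaviour).

## Preprocessing

Covariate adjustment fits an identity-link Gaussian linear model of
every variable on the covariates over the pooled sample — not per
group, since the affinity reference space is itself pooled — and
replaces the variable by its residual. Categorical covariates are
one-hot encoded with the first level dropped; rank-deficient designs
error out naming the collinear columns. Participants with any missing
variable or covariate are excluded (`drop_incomplete()`), since a
fingerprint needs a complete row; partial fingerprints are out of
scope. Held-out participants are always projected with the training
pooled mean/SD and scored against training participants only; at test
time a participant inherits, per variable, the community label most
frequent among its training neighbours (no neighbours, no community —
the variable then contributes nothing to its $A^{CC}$ row).

## Cross-validation and evaluation

`nested_cv()` uses stratified outer and inner 5-fold splits (5-fold
nesting with inner-loop tuning is the framework's protocol; the inner
fold count is this package's choice and is configurable). Folds are
seeded and keyed to participant IDs, so
results are invariant to row order. Accuracy is the fraction of
correctly labelled validation participants, reported per group and in
total.

`performance()` reports confusion counts, sensitivity, specificity and
prevalence-adjusted predictive values via Bayes' rule at the test-set
prevalence; these reduce to the raw ratios at the sample prevalence,
an identity the tests verify to $10^{-12}$.

`learning_curve()` subsamples the cohort at a geometric grid of
per-group sizes, measures held-out error of the chosen classifier, and
fits $error(n) = a + bn^c$ by weighted nonlinear least squares (weights
= inverse empirical variance per grid point, multi-start over
$c \in \{-0.1, -0.3, -0.5, -1\}$; the port algorithm with box
constraints, falling back to Levenberg–Marquardt). This weighted-NLS
procedure is this package's own re-specification of the classic
inverse-power-law learning-curve fit, keeping the standard
parameterisation ($a$ = minimum achievable error, $1-a$ = maximum
achievable accuracy, $b$ = learning rate, $c$ = decay rate).
Confidence intervals are a seeded nonparametric bootstrap over
replicate points (B = 500 by default); error points come from repeated
stratified subsampling with held-out evaluation.
`sample_size_for_accuracy()` inverts the curve in closed form and
returns a double, because flat curves (small $|c|$) can demand
astronomically large samples.

## Clustering

`kmeans_separability()` concatenates the composite,
common-neighbourhood and common-community G-vectors (both group axes of
each metric; the metric set is configurable), column-standardizes them (the metrics live on
incommensurate scales), and runs Euclidean k-means with 50 seeded
restarts, keeping the lowest within-cluster sum of squares. Cluster
labels are canonicalized by descending size then centroid norm so
reports are seed-stable. The composition table divides each cluster's
per-group count by the group size, so each group's shares sum to 1.

## Fingerprint uncertainty

The per-participant fingerprint export needs uncertainty; no canonical
method exists for interval estimates of neighbourhood-count scores, so
the conventions here are this package's own and are labelled as such.
CIs: B bootstrap resamples of the *other*
participants (index participant held fixed), full recomputation of
z-scores, hop sizes and scores per resample, percentile 2.5/97.5.
Reliability: L group-label permutations with the z-space held fixed and
hop sizes recomputed from the permuted labels; the p-value counts
permutations in which the maximal group's score reaches the observed
one, observed configuration included, so $p \ge 1/(L+1)$.

## The synthetic generator

`generate_cohort()` draws Gaussian variables with specified per-group
mean shifts (in within-group SD units), optional equicorrelation via a
shared latent factor, uniform age on [18, 65], Bernoulli sex with
group-specific rates, linear covariate effects and MCAR missingness —
exactly the structure the affinity machinery assumes. The `asrb_like()`
preset emulates a three-group schizophrenia-spectrum study after
exclusions: 136 controls, 182 chronic-schizophrenia and 34
treatment-resistant participants over 195 variables in four domains.
No distributional description of the original restricted dataset is
available, so effect sizes were fixed once at values a clinical
researcher would call realistic for that literature — clinical ~1.1 SD,
cognitive ~0.9, psychosocial ~0.7, structural ~0.45 on a subset of
regions, an extra ~0.6 SD on a cognitive/clinical subset for the
treatment-resistant group, sex rates 48/70/81% male and small negative
age slopes on most variables — and not revisited.

What the generator does *not* emulate: non-Gaussian and bounded scales
(questionnaire totals), realistic region-to-region covariance,
site/scanner effects, informative missingness, and label noise.
Passing tests on synthetic cohorts therefore demonstrate correctness of
the machinery and qualitative behaviour (verification leniency ordering
of metrics, neighbourhood methods beating weighted KNN on overlapping
groups, subgroup separability), not expected accuracy on real clinical
data — with 195 informative-on-average variables the synthetic cohort
is more separable than a real one.

## Numerical choices and degenerate inputs

* Ties in scores are compared with exact floating-point equality: all
  tied quantities arise from identical integer-ratio arithmetic.
* $h_v = 0$ (identical group means) is kept, not clipped, and flagged;
  the window then holds only exact ties (plus self in verification),
  and the score formula remains well defined down to the empty set.
* Zero-variance variables error out by name at z-scoring; bootstrap
  resamples that lose a group or a variable's variance are handled by
  excluding the empty group's mean from the hop computation and scoring
  it 0.
* Problem sizes in the tests and acceptance script (full 352 x 195
  preset for the end-to-end run; 100 cohorts of up to 30 participants
  for oracle equivalence; 8-point grids with 20 replicates for
  learning-curve recovery) were chosen as the smallest sizes at which
  the properties under test are stable.

## Worked example

```{r example}
ch <- adjust_covariates(asrb_like(seed = 7))
verify(ch, alpha = 6)
```

```{r classify}
merged <- relabel_groups(ch, c(TRS = "Scz"))
set.seed(11)
tr_idx <- sort(c(sample(which(merged$group == "HC"), 110),
                 sample(which(merged$group == "Scz"), 170)))
tr <- merged[tr_idx]
te <- merged[setdiff(seq_along(merged$id), tr_idx)]
fit <- affinity(tr, alpha = 6)
performance(te$group, predict(fit, te), positive_class = "HC")
```

## Known limitations

* Verification/classification percentages of the original restricted
  clinical dataset are not reproducible here; only the arithmetic
  identities among its printed prediction-table numbers are checked.
* Louvain community detection is order- and seed-dependent in general;
  we fix node order to participant order and seed the RNG, which makes
  runs reproducible but does not guarantee a global modularity optimum.
* The affinity classifier re-tunes `alpha` per sample size by design;
  fitted models should not be reused after the reference cohort
  changes (the object stores its training data for this reason).
* G > 2 classification benchmarking and alternative baselines (SVM),
  weighted adjacency, per-participant adaptive hop sizes and
  multi-site harmonization are out of scope.
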
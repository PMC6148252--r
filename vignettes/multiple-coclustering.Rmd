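---
title: "Multiple co-clustering of mixed-type study data: model, inference and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple co-clustering of mixed-type study data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvcoclust)
```

## The model

`mvcoclust` fits a three-level nonparametric Bayesian partition of a
subjects × features table of mixed type. Writing $x_{ij}$ for the value of
feature $j$ on subject $i$ (possibly missing):

* every feature belongs to exactly one **view** $v$, with truncated
  stick-breaking prior weights built from $\mathrm{Beta}(1, \alpha_1)$
  fragments;
* within a view, features of each declared type are grouped into **feature
  clusters** $g$ (sticks $\mathrm{Beta}(1, \alpha_2)$, one stick-breaking
  process per view and type);
* within each view, subjects are independently grouped into **subject
  clusters** $k$ (sticks $\mathrm{Beta}(1, \beta)$), so every view carries
  its own subject partition.

A *block* $(v, g, k)$ holds all values of its feature cluster on its subject
cluster and is modelled by one parametric family chosen by the declared
feature type:

* numerical — Gaussian with Normal–Gamma prior: precision
  $s_{v,g,k} \sim \mathrm{Ga}(\gamma_0/2,\ \gamma_0\sigma_0^2/2)$ and mean
  $\mu \mid s \sim \mathrm{N}(\mu_0, (\lambda_0 s_{v,g,k})^{-1})$;
* categorical — multinomial with symmetric $\mathrm{Dirichlet}(\rho_0)$
  prior;
* integer — Poisson with $\mathrm{Ga}(a_0, b_0)$ rate prior.

The defaults ($\alpha_1 = \alpha_2 = \beta = 1$,
$\gamma_0 = \sigma_0^2 = \lambda_0 = 1/100$, $\mu_0 = 0$, $\rho_0 = 1$,
$a_0 = b_0 = 1$) are the non-informative setting of the depression study this
package operationalizes. Ordinal questionnaire items are declared
categorical, not numerical: a Gaussian fits item-level score distributions
poorly, and the study made the same choice.

The mapping of concentrations to levels (α₁ → views, α₂ → feature clusters,
β → subject clusters) is a package convention — the three Beta distributions
are named in the source material without an explicit level assignment — and
is recorded in every run manifest.

## Variational inference

Inference is coordinate-ascent variational Bayes (CAVI) under the mean-field
factorization

$$q = \prod_j q(v_j, g_j)\ \prod_{i,v} q(k_{i}^{(v)})\ \prod q(\text{sticks})\ \prod q(\theta_{v,g,k}),$$

where the feature-level factor is a joint responsibility over
(view, feature-cluster) pairs, and each subject holds one assignment factor
per view. All four update families are exact conjugate coordinate updates,
so the evidence lower bound (ELBO) is non-decreasing across iterations; the
engine verifies this at relative tolerance $10^{-8}$ and raises a diagnostic
error on any violation, which the test suite exercises across hundreds of
restarts. Each iteration updates sticks, then block posteriors, then feature
responsibilities, then subject responsibilities, then evaluates the ELBO;
the per-iteration cost is dominated by a handful of
(subjects × features) × (clusters) cross-products, so fits with a few
hundred features take seconds.

Missing entries are handled by marginalization: a missing cell contributes
to no block sufficient statistic and no responsibility term. A
fully-missing feature is therefore assigned purely by the stick prior and
cannot perturb other features' assignments (a tested contract).

Convergence is declared when the relative ELBO change falls below $10^{-6}$
(500 iterations maximum); both are configurable. Hard assignments are read
off by maximum responsibility with ties to the lowest index, empty
views/clusters are pruned with contiguous, order-preserving relabeling, and
block posteriors are then recomputed at the hard assignments for reporting.

### Truncation

The default truncation (15 views, 12 feature clusters, 10 subject clusters)
covers the ranges observed in the motivating study (15 views, ≤ 11 feature
clusters, ≤ 9 subject clusters). Benchmarks in the tests and acceptance
script use (6, 4, 6), comfortably above their planted (3, 3, 3) structure;
truncation is an upper bound, not a model-order choice, since the
stick-breaking prior empties unneeded components.

### Restart selection

Cluster solutions depend on the random initial configuration, so `mcc_fit()`
runs many restarts (uniformly random hard initializations from per-restart
seeds) and keeps the best. The selection score is the **ELBO**. The
alternative — the plug-in log-likelihood of the hard assignments at the
posterior-mean parameters, available as `select = "loglik"` — was evaluated
and rejected as a default: hard singleton clusters receive inflated
posterior-mean precisions, so plug-in likelihood systematically prefers
overfragmented restarts (on the planted 134 × 200 benchmark it selects
4-view solutions with view-partition ARI ≈ 0.6 where ELBO selection recovers
the planted 3-view structure exactly). Both scores are logged per restart in
`$restart_scores`. The desk-scale default is 10 restarts; the original
analysis used 1000, and the benchmark suites here use 20–50.

### Categorical level space

Categorical blocks share a Dirichlet over a common level space sized by the
largest level set among the categorical features; levels a feature never
takes simply keep their prior mass. This lets features with different level
counts share a feature cluster without special-casing, at the cost of a mild
prior dilution for features with few levels ($\rho_0 = 1$ per level).

## Pre-processing conventions

`standardize_features()` implements the study's two-track rule: FC
(functional-connectivity) features are standardized by the mean and standard
deviation of the *control* subjects, anchoring the baseline at the control
average; all other numerical features are standardized over all subjects.
Statistics ignore missing entries, which remain missing. The standard
deviation uses the unbiased $n-1$ denominator — the convention had to be
fixed for reproducibility and the unbiased estimator is the R default.
Categorical and integer features pass through untouched.

`compute_fc_features()` defines functional connectivity as the Pearson
correlation of ROI-averaged BOLD time series, one feature per unordered ROI
pair over the strict upper triangle, named `<roiA>__<roiB>` in ROI-list
order. An inventory of $n$ ROIs yields $n(n-1)/2$ features; for the study's
78 retained ROIs that is 3003, although the source text quotes 2701 with the
same formula — the formula is implemented literally and the discrepancy
(possibly a different effective ROI count) cannot be resolved from the text.

## What the synthetic generators emulate

The clinical dataset behind the method is ethically restricted, so the
package treats synthetic data as a first-class module with exported ground
truth at all three levels.

`simulate_depression_study()` plants, by default, the study's headline
conditions chosen once and fixed: 67 + 67 subjects; 2701 FC-style features
already on the control-standardized scale; 60 questionnaire features; 20
categorical (sex/SNP-like, 3 levels) and 2 integer count features; 5%
missing completely at random; three planted views. The diagnosis view
carries five subject clusters — C1/C2 for controls and D1/D2/D3 for
depressed subjects — whose numerical profiles follow the studied subtype
pattern (D1: high CATS, high AG-FC, low baseline severity, poor outcome;
D2: low CATS, moderate AG-FC, good outcome; D3: high CATS, low AG-FC, high
baseline severity, good outcome), with between-cluster separations of
`effect_size` standard deviations (default 3, a separation strong enough to
make downstream contracts testable; the real between-cluster separations are
unpublished, so this default is chosen for testability, not realism). The
post-treatment outcome score is the planted subtype mean plus
$\mathrm{N}(0, 0.5^2)$ noise — outcome dominated by subtype with moderate
individual variation — and its resistant/responsive dichotomy thresholds it
at the midpoint between the planted means.

What the generator deliberately does *not* emulate: correlated noise across
FC features (real FC matrices have network structure beyond the planted
blocks), non-Gaussian questionnaire marginals, missingness that depends on
severity (ours is MCAR, matching the "left as they were" treatment of
missing entries), and any within-block dependence. Passing tests therefore
demonstrate correctness of the machinery under the model's own assumptions,
not robustness to their violation.

`recovery_fixture()` is the fixed recovery benchmark: 134 subjects, 200
features in three structured views (a three-cluster Gaussian view with two
feature clusters, a mixed Gaussian/categorical/Poisson view, a second
two-cluster Gaussian view), 3-sd mean gaps, Poisson rates 2 vs 10, 10%
missing. All three views carry real subject structure; a pure-noise view
was deliberately not planted in this benchmark because a structureless
feature set can legitimately be absorbed as a flat feature cluster of any
view, making the view-partition ground truth ill-posed.

## View characterization

* **Adjusted Rand index** (Hubert–Arabie) compares each view's subject
  partition with the control/depression labels; 0 at chance, 1 for
  identity. The implementation is the contingency-table closed form,
  cross-checked in the tests against brute-force pair counting over all
  partitions of small subject sets and against `mclust`.
* **First-PC scores**: the leading principal component of a view's FC
  features, sign-oriented so the majority of loadings are nonnegative (the
  rule resolves the PCA sign indeterminacy deterministically). Missing
  entries are imputed with the fitted block posterior mean before the
  decomposition so every subject receives a score; views with fewer than
  two FC features return an explicit not-applicable result.
* **Average Cohen's d**: per FC feature cluster the fitted Gaussian block
  means are sorted and $d = (\mu_2 - \mu_1)/\sqrt{(\sigma_1^2 +
  \sigma_2^2)/2}$ is computed between neighboring means, then averaged
  within the view. Block standard deviations come from the posterior-mean
  precision, consistent with the fitted model rather than empirical cell
  standard deviations. Eligibility follows the study's conditioning rules
  read strictly: feature clusters with *more than three* (≥ 4) FC features
  and subject clusters with more than three (≥ 4) depressed subjects.
* **Depression-related proportion**: the fraction of a view's features
  flagged depression-related. FC features are excluded from numerator and
  primary denominator; because the denominator convention is genuinely
  ambiguous, the all-feature denominator is reported alongside.
* **Significance screens**: one-way ANOVA (numerical) and χ² crosstable
  tests (categorical/integer) of each feature against the view's subject
  clusters, at 0.05 with Bonferroni correction *within each feature type*;
  constant features get $p = 1$.
* **Hamming consensus**: subject-by-subject distance defined as the
  fraction of views in which cluster memberships differ, fed to
  average-linkage hierarchical clustering and exported as Newick text.
  These distances are reported as-is; they are ratios, not metrics with
  guaranteed triangle inequality.
* **Sensitivity sweep**: refits under perturbed hyperparameters and reports
  feature-partition and subject-partition agreement with the baseline.

## The subtype classifier

`loocv_gmm_accuracy()` evaluates how well reduced predictor sets explain
the depressed subjects' cluster memberships: each subject in turn is held
out, per-cluster Gaussian components (means, full covariances, mixing
weights from the known memberships — supervised, no EM) are re-estimated
from the rest, and the held-out subject is assigned by maximum posterior.
Missing predictor entries are imputed with training-fold means inside the
loop, so the held-out subject never leaks into estimation. Singular
covariances are ridge-jittered and counted. The companion
`loocv_predictor_curve()` reports one accuracy per incremental predictor
set (CATS, then + FC, then + severity scores, then the rest).

`fit_threshold_classifier()` learns the two-step rule: an AG-related FC
score threshold separating D3 (low FC) from the rest, then a CATS threshold
separating D2 (low CATS) from D1 among non-D3 subjects. Thresholds maximize
the respective binary accuracies over midpoints between sorted unique
scores, with ties broken toward the lower threshold — the study displays
the thresholds only graphically, so they are learned from data rather than
hard-coded. The outcome map (D1 resistant; D2, D3 responsive) mirrors the
post-treatment severity pattern of the subtypes. `classify_subjects()` is a
deterministic total function of the two scores; missing scores yield an
explicit unclassifiable result.

## Numerical choices and degenerate inputs

* ELBO convergence $10^{-6}$ relative, monotonicity guard $10^{-8}$
  relative, 500 iterations maximum.
* Gaussian block posterior rates are computed via the cancellation-stable
  form $b_0 + \tfrac12(\sum x^2 + \lambda_0\mu_0^2 - \lambda_n\mu_n^2)$
  and floored at machine-tiny to guard against floating cancellation.
* Ties in maximum responsibility break to the lowest index; pruning
  relabels contiguously preserving index order, so co-membership relations
  are invariant.
* Constant data collapses to one view, one feature cluster and one subject
  cluster: with identical block posteriors everywhere, the stick prior's
  preference for early components drives winner-take-all onto the first
  component (tested).
* Zero-spread features are rejected at standardization with the feature
  named; zero-variance ROI series are rejected at FC computation with the
  ROI named.

## Problem sizes used in the shipped checks

The test suite and acceptance script run at desk scale, chosen so the whole
suite completes in minutes on one CPU: the recovery benchmark is 10 seeds ×
20 restarts at 134 × 200 with truncation (6, 4, 6); the exhaustive
likelihood oracle enumerates all $4^4 \times 2 \times 2^6$ hard assignments
of a fixed 6 × 4 matrix at truncation (2, 2, 2); the downstream classifier
chain uses the study fixture with 120 FC and 40 questionnaire features. The
full-scale defaults (2701 FC features, 1000 restarts) remain available
through the same interfaces.

## Known limitations

* The variational posterior is a point of the mean-field family: posterior
  uncertainty over partitions is not quantified, and restart selection
  returns a single solution.
* Blocks assume within-block independence; correlated residuals (ubiquitous
  in FC data) can induce extra feature clusters.
* The categorical level-space sharing mildly inflates the prior for
  few-level features (see above).
* The two-step classifier is a descriptive rule on two scores; no claim of
  clinical validity is made, and no survival or remission modelling beyond
  the rule is attempted.
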
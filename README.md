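# mvcoclust

Nonparametric Bayesian **multiple co-clustering** of mixed-type
subjects-by-features tables, with the downstream view-characterization
statistics and the two-step depression-subtype classifier built on top of it.

## The problem

High-dimensional clinical datasets — resting-state functional connectivity
(FC) between brain regions, questionnaire scores, genotypes, count variables —
rarely carry a single cluster structure. Different subsets of features support
different, equally real partitions of the subjects (one driven by diagnosis,
another by demographics, others by noise). Classical PCA/CCA-then-cluster
pipelines recover only the dominant structure. `mvcoclust` instead fits a
model in which:

1. features are **exclusively partitioned into views** (truncated
   stick-breaking prior, concentration α₁),
2. within each view, features of each type are clustered (concentration α₂),
3. within each view, subjects are independently clustered (concentration β),

and every block — the cell of one feature cluster × one subject cluster — is
modelled by a single parametric family chosen by the declared feature type:

| type        | block model | prior |
|-------------|-------------|-------|
| numerical   | Gaussian    | s ~ Ga(γ₀/2, γ₀σ₀²/2), μ \| s ~ N(μ₀, (λ₀s)⁻¹) |
| categorical | multinomial | Dirichlet(ρ₀) |
| integer     | Poisson     | Ga(a₀, b₀) |

Defaults are the non-informative setting α₁ = α₂ = β = 1, γ₀ = σ₀² = λ₀ =
1/100, μ₀ = 0, ρ₀ = 1, a₀ = b₀ = 1. Inference is coordinate-ascent
variational Bayes over the three assignment posteriors, the stick weights and
the conjugate block posteriors; missing entries contribute to no likelihood
term and need no imputation. Multiple random restarts guard against local
optima; the evidence lower bound (ELBO) selects the returned solution.

For a fitted solution the package computes the field's standard
characterization statistics — adjusted Rand index against diagnosis labels,
between-view correlations of first-principal-component FC scores, per-view
depression-related feature proportions, average Cohen's
d = (μ₂ − μ₁)/√((σ₁² + σ₂²)/2) between neighboring block means,
ANOVA/χ² significance screens with per-type Bonferroni correction, and a
Hamming-distance consensus dendrogram — plus a clinically motivated two-step
classifier: subjects with a low angular-gyrus-related FC score are assigned
to subtype D3, the rest split into D2 (low childhood-adversity CATS score,
treatment-responsive) and D1 (high CATS, treatment-resistant).

Because the motivating clinical dataset is ethically restricted, the package
ships first-class synthetic-data generators with planted multi-view block
structure and exported ground truth, including a full depression-study-like
fixture (134 subjects, 67/67 control/depressed, FC + questionnaire +
categorical + count features, planted C1/C2/D1/D2/D3 subject clusters and a
post-treatment outcome score).

## Worked example

```r
library(mvcoclust)

sim <- simulate_depression_study(study_fixture_config(
  n_fc_features = 120, n_questionnaire_features = 40, seed = 11))
dep   <- sim$data$labels$label == "depressed"
truth <- sim$truth$subtype$subtype[dep]

# AG-related FC score (first PC of the planted AG feature cluster) and CATS
vals     <- sim$data$values
fc_score <- first_pc_scores(as.matrix(vals[, grep("^FC_AG", names(vals))]))
cats     <- rowMeans(as.matrix(vals[, grep("^CATS", names(vals))]), na.rm = TRUE)

clf <- fit_threshold_classifier(fc_score[dep], cats[dep], truth)
clf
#> <mcc_subtype_classifier>
#>   FC score  < -2.333319 -> D3 (responsive)
#>   else CATS < 0.004947599 -> D2 (responsive)
#>   else                -> D1 (resistant)

pred <- classify_subjects(clf, fc_score[dep], cats[dep])
mean(pred$subtype == truth)
#> [1] 1
```

The two learned thresholds sit in the planted gaps (FC cluster means ±1.5 for
D1/D3 around 0 for D2; CATS means 1.5 vs −1.5), and on this fixture the
classifier reproduces every planted membership. Fitting the full model and
summarizing it follows the same grammar:

```r
fx  <- recovery_fixture(101)
fit <- mcc_fit(fx$data, truncation = c(6, 4, 6), n_restarts = 20, seed = 5)
glance(fit)
#> # A tibble: 1 × 8
#>   n_subjects n_features n_views    elbo  logLik n_iter converged n_restarts
#>        <int>      <int>   <int>   <dbl>   <dbl>  <int> <lgl>          <int>
#> 1        134        200       3 -34608. -33706.    121 TRUE              20
tidy(fit) |> dplyr::count(view, dtype)    # feature partition across views
view_report(fit, data = fx$data)          # per-view characterization
```

The three planted views (a three-cluster numerical view, a mixed
numerical/categorical/Poisson view, and a second two-cluster view) are
recovered exactly (adjusted Rand index 1 at both the view-partition and
subject-cluster level on this seed).

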
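# divprop

Propensity-score quantification of cohort diversity and its effect on
out-of-distribution predictive accuracy and pattern stability in multi-site
case-control studies.

## The problem

Multi-site clinical cohorts (neuroimaging consortia are the motivating
case) mix participants who differ in age, sex composition, and acquisition
site. A diagnosis classifier trained on one demographic slice of such a
cohort may not transport to another, and the brain pattern it extracts may
drift with the makeup of its training sample. `divprop` gives investigators
a single, principled handle on this: the propensity score

&nbsp;&nbsp;&nbsp;&nbsp;π = P(Y = 1 | C),&nbsp;&nbsp; logit(π) = β₀ + β₁C₁ + … + β_kC_k,

the probability of carrying the diagnosis given only the covariates C
(age, sex, site) — estimated by a covariate-only logistic model with Platt
calibration, never from brain features. Because π is a balancing score,
distances on the score spectrum index distances in the whole covariate
configuration. **Diversity** is then the mean absolute pairwise score
difference — within a training set (WD), or between a training set and a
holdout stratum (OOD):

&nbsp;&nbsp;&nbsp;&nbsp;WD = 2/(Nₜ(Nₜ−1)) Σ_{i<j} |π_i − π_j|,&nbsp;&nbsp;
OOD = 1/(NₜN_s) Σ_i Σ_j |π_i − π_j|.

The pipeline: caliper-constrained optimal pair matching of cases to
controls on |Δπ| (Hungarian assignment, caliper 0.2 × SD of pairwise score
differences) → 10 score-ordered equally sized strata of matched pairs →
train/holdout draws under contiguous / diverse / random schemes (or all 252
combinations of 5-of-10 strata) → nested cross-validated L2-penalized
logistic classification of the brain features (λ tuned on a 7-point
log-grid in [1e-3, 1e+3]) → per-holdout-stratum evaluation (AUC, F1,
confusion) against OOD diversity → stability of the extracted weight
vectors (consistency matrices, per-region ANOVA over diversity groups with
permutation TFCE, network-level correlations). Linear-residualization and
ComBat-style empirical-Bayes deconfounding are built in, as is a seeded
synthetic multi-site cohort generator that reproduces the framework's
assumed statistical structure.

## Worked example

A single-feature toy cohort whose case-control separation Δx shrinks toward
both ends of the propensity spectrum (the regime in which accuracy *falls*
as train-test diversity grows):

```r
library(divprop)
ch  <- generate_toy_single_feature("abide-like", n = 1000, seed = 7)
cfg <- experiment_config(pheno = ch$pheno, features = ch$features,
                         scheme = "all", r = 5, compute_wd = FALSE, seed = 7)
ex  <- run_experiment(cfg)
print(ex$pairs)
#> Matched pairs: 222 (caliper threshold 0.0535, d_sd 0.2675)
#>   |delta pi|: median 0.0010, max 0.0535
print(ex)
#> Diversity experiment
#>   matched pairs: 222; strata: 10; draws: 252 (all)
#>   OOD evaluations: 1260; cor(diversity, AUC) = -0.725
head(ex$ood_table[, c("draw", "stratum", "ood_diversity", "auc", "f1")], 5)
#>   draw stratum ood_diversity       auc        f1
#> 1    1       6     0.2331036 0.8595041 0.8000000
#> 2    1       7     0.3004834 0.8388430 0.7441860
#> 3    1       8     0.3797128 0.6942149 0.6222222
#> 4    1       9     0.4451305 0.6136364 0.5957447
#> 5    1      10     0.5617434 0.6384298 0.6250000
```

Reading the output: matching retained 222 of 1,000 participants per group
as case-control pairs with nearly identical scores (median |Δπ| = 0.001).
Draw 1 trains on the five lowest strata; its nearest holdout stratum
(stratum 6, OOD diversity 0.23) is classified well (AUC 0.86), while the
most distant stratum (10, OOD diversity 0.56) drops toward chance — across
all 252 × 5 evaluations the diversity-accuracy correlation is r = −0.725.
The `"hbn-like"` scenario (separation growing toward the extremes) flips
the sign. Swap in your own phenotype table and feature matrix (from
`build_features`) to run the same experiment on real data, and use
`deconfound_method = "linreg"` or `"combat"` to compare deconfounding
regimes.

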
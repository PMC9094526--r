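---
title: "Quantifying cohort diversity with propensity scores: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cohort diversity with propensity scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divprop)
```

## The problem

Multi-site case-control cohorts in clinical neuroimaging mix participants
who differ systematically in age, sex composition, and acquisition site.
When a classifier of diagnosis is trained on one slice of that population
and deployed on another, its accuracy and the brain pattern it extracts can
change with the demographic distance between the two slices - a form of
dataset shift that no single-covariate hold-out design can expose.

`divprop` operationalizes that distance with the propensity score
$\pi = P(Y = 1 \mid C)$: the probability that a participant carries the
diagnosis given only their covariates $C$ (age, sex, site), estimated by a
covariate-only logistic model and never from brain features. Because the
propensity score is a balancing score, participants at the same score value
have exchangeable covariate profiles across the diagnostic groups, so one
number indexes the whole covariate configuration. *Diversity* is then the
mean absolute pairwise score difference - within a training set
(within-distribution, WD) or between a training set and a holdout stratum
(out-of-distribution, OOD).

## The pipeline

1. **Features** (`build_features`): participant fingerprints are either the
   strict upper triangle (row-major over $i < j$; the order is arbitrary but
   fixed, since the classifier is permutation-equivariant over features) of
   the parcel-level Pearson correlation matrix ($F = P(P-1)/2$; 4,950 for a
   100-parcel atlas), or per-parcel mean thickness values ($F = P$). No
   Fisher z-transform is applied.
2. **Propensity** (`estimate_propensity`): logistic model of diagnosis on
   standardized age, binary sex, and a one-hot site block, with a very weak
   ridge penalty ($\lambda = 10^{-4}$, intercept unpenalized) purely for
   numerical stability under separation. Platt recalibration is fitted on
   out-of-fold linear predictors from 5-fold stratified cross-fitting - an
   in-sample calibration map would inherit the base model's optimism.
   Coefficients are never interpreted, so covariate scaling is free. Scores
   are clipped to $[10^{-6}, 1 - 10^{-6}]$.
3. **Matching** (`match_pairs`): one case to one control, globally minimal
   total $|\Delta\pi|$ via an $O(n^3)$ shortest-augmenting-path assignment
   solver. Costs above the caliper $0.2 \cdot d_{sd}$ are set to a
   forbidden value of $10 \times (\text{max admissible cost} + 1)$, and any
   assigned pair still above the threshold is discarded. $d_{sd}$ is by
   default the SD of the case-by-control absolute score differences (the
   costs the assignment actually uses); an all-pairs variant is available
   via `d_sd_mode = "all"` since the phrasing "all pairwise differences" is
   ambiguous between the two. Matching is what keeps every later
   train/holdout split exactly class-balanced.
4. **Stratification** (`stratify`): pairs ranked by pair-mean score and cut
   into $q = 10$ equally sized strata; remainder pairs go to the
   lowest-score strata (a documented, configurable convention - the
   alternative of equal-width score bins trades stratum-size control for
   diversity-range control and is out of scope). Ties break on case id for
   determinism.
5. **Sampling** (`enumerate_draws`): training sets of $r$ strata under
   `contiguous` (adjacent windows), `diverse` (subsets whose indices do not
   form one unbroken run, ranked by training WD diversity, top `n_draws`),
   `random` (pair-level, score-agnostic), and `all` (exhaustive; 252 draws
   at $q = 10$, $r = 5$). A set counts as contiguous *iff* its sorted
   stratum indices form an unbroken run; any gap makes it diverse (so 8 of
   the 10 nine-strata subsets are diverse). When a contiguous request
   exceeds the available windows, extra draws use runs of consecutive
   matched pairs at the same training fraction, window starts evenly spaced
   and deduplicated.
6. **Classifier** (`train_classifier`): L2-penalized logistic regression
   minimizing $J(w) = -\sum_i [y_i\log\varphi(z_i) +
   (1-y_i)\log(1-\varphi(z_i))] + \lambda\lVert w\rVert^2$, intercept
   unpenalized. $\lambda$ is tuned by inner 5-fold stratified CV over the 7
   log-equidistant grid values in $[10^{-3}, 10^{3}]$ *in this exact
   parameterization* (no solver-convention rescaling leaks into the grid).
   The tuning metric is AUC, with ties resolved toward the strongest
   penalty - the least-variance choice among equals. Features are z-scored
   with training-row statistics only; evaluation applies the stored
   parameters, so holdout rows can never influence the fit.
7. **Evaluation** (`evaluate`): AUC on probabilities; F1 at the 0.5
   probability threshold with the diagnosis as the positive class;
   confusion proportions normalized to sum to 1, with optional per-site /
   per-sex / per-age-bin breakdowns. OOD performance is always reported per
   holdout stratum, never pooled, so that diversity *between* training and
   test - not diversity *within* the test set - drives the comparison.
8. **Deconfounding** (`deconfound`): `linreg` residualizes every feature on
   age, sex, and site indicators (for categorical confounds this equals
   within-group centering); `combat` first removes per-site location and
   scale effects with parametric empirical-Bayes shrinkage while protecting
   age and sex in the standardization design, then residualizes age and
   sex. By default deconfounding runs cohort-wide before
   matching by default; `deconfound_scope = "train"` refits inside every
   draw for leakage-safe comparisons. All transforms store their parameters
   and can be replayed on new rows - the reason the harmonizer is
   implemented in-package rather than delegated.
9. **Stability** (`consistency_matrix`, `diversity_anova`,
   `permutation_cluster_correct`, `network_correlation`): pairwise Pearson
   correlations of the per-draw weight vectors (rows sorted by diversity);
   per-region one-way ANOVA of node coefficients over 5 near-equal
   diversity groups; TFCE over the parcel adjacency graph with permutation
   family-wise correction; per-network correlation of aggregated node
   coefficients with diversity.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `caliper` | 0.2 | multiplier on $d_{sd}$ bounding an admissible pair's score distance |
| `q` | 10 | number of score-ordered strata |
| `r` | 5 (2-8 typical) | training strata per draw |
| `n_draws` | 20 | draws per scheme (contiguous/diverse/random) |
| `lambda_grid` | $10^{-3} \dots 10^{3}$, 7 values | penalty grid of $J(w)$ |
| `inner_folds` / `wd_folds` | 5 / 10 | nested CV structure |
| TFCE `E`, `H`, `n_steps` | 0.5, 2, 100 | extent/height exponents and integration steps (the standard defaults for the enhancement method) |
| `n_perm` | 1000 | permutations for family-wise correction |

The TFCE node statistic is the per-node ANOVA F. The permutation unit is
the draw's diversity-group label; draws share training pairs, so they are
not independent - the permutation p-values are descriptive of this design
rather than of an i.i.d. population, an inferential caveat inherited from
the experiment's structure.

## The synthetic cohort generator

`generate_cohort` emulates the statistical structure the framework assumes,
not brain data: $K$ sites with graded age means (10-18 years), sex ratios
(0.70-0.35 male), and a logistic diagnosis link on the covariates (so the
true propensity model lies inside the fitted family); features are baseline
+ group effect + optional per-site additive/scale batch effects + Gaussian
noise. The default 3-site, $n = 400$ cohort uses link coefficients
(age 0.8, sex 0.3, site $\mp$0.2) calibrated by a systematic scan so that
the generator satisfies the two properties it is designed around:
covariates clearly informative before matching (covariate-only AUC
$\approx$ 0.71, reliably above 0.65) *and* post-matching balance (all
covariate SMDs below 0.1 in roughly nine out of ten seeded replicates — the
regime well-conducted propensity matching achieves on real multi-site
cohorts). The two pull in opposite directions -
stronger confounding raises the pre-matching AUC but degrades achievable
balance at $n = 400$ - and age-dominant confounding resolves the tension
best, because a continuous covariate can be matched more finely than
binary site indicators. Site batch
effects default to zero because site is linked to diagnosis through the
covariates: a nonzero default would inject genuine label signal into the
`"null"` scenario through the features, which must stay at chance.

The group effect $\Delta x$ is a function of the true propensity score:

* `abide-like`: $\Delta x(\pi) = a\,(1 - |2\pi - 1|)^{\gamma}$ - largest
  mid-spectrum, vanishing at the extremes, producing a *negative*
  OOD-diversity / accuracy correlation;
* `hbn-like`: $\Delta x(\pi) = a\,|2\pi - 1|^{\gamma}$ - the reverse
  profile, producing a *positive* correlation;
* `constant`, `null`: fixed and zero effects.

The single-feature toy (`generate_toy_single_feature`, $n = 1000$, two
sites, $a = 1.5$ noise SDs, $\gamma = 1$) exercises the full
match-stratify-draw-fit-evaluate chain and recovers the sign of the
diversity-accuracy link; only the sign is a designed property - the
magnitudes depend on $a$ and the covariate mix.

What the generator does **not** emulate: spatial autocorrelation between
parcels, realistic fMRI autocorrelation or motion artifacts, non-Gaussian
feature noise, comorbidity structure, and site-by-effect interactions.
Passing tests therefore certify the statistical machinery - balance,
optimality, calibration, sign recovery - not performance claims on real
imaging cohorts.

## Numerical choices and degenerate inputs

* One penalized-logistic solver (BFGS on the exact cost with analytic
  gradient, relative tolerance $10^{-12}$) backs both the propensity model
  and the classifier.
* Zero-variance features get $\sigma = 1$ in z-scoring (they contribute a
  constant); zero-variance parcels are an error naming the parcel, since a
  correlation is undefined there.
* SMD with zero pooled variance is 0 for equal means, `Inf` otherwise.
* Platt-calibrated scores are clipped to $[10^{-6}, 1-10^{-6}]$ before any
  logit.
* ComBat: parametric empirical-Bayes variant (the common default; the
  nonparametric variant is out of scope); convergence at $10^{-4}$ relative
  change; constant features pass through with a warning; a site with one
  participant is an error naming the site; with a single feature the
  hyperpriors are undefined and per-site estimates are used unshrunk.
  Empirical-Bayes shrinkage leaves a residual between-site mean difference
  on the order of the site-mean standard error, so harmonization quality is
  judged on standardized (SMD-scale) moments.
* Residualization idempotence holds to $10^{-8}$ relative tolerance.
* Assignment-problem ties resolve by the solver's deterministic scan order;
  results are order-stable because inputs are sorted by participant id.
* Within-score-bin covariate balance is asymptotic: per-bin SMD sits below
  0.2 once bins hold several hundred participants (the property test uses
  $n = 10{,}000$ with decile bins so that binning noise does not mask the
  property).
* For matched cohorts, covariate-audit CV assigns folds at the pair level:
  splitting a matched pair across folds lets the model fit within-pair
  noise contrasts and biases the out-of-fold AUC systematically below 0.5.

## Problem sizes used in the test-bed

The shipped checks run the exhaustive 252-draw experiment on the
single-feature toy at $n = 1000$ (10 seeds per scenario), the balance suite
at $n = 400$ over 20 seeds, matching optimality against exhaustive search
on instances up to $7 \times 7$, null calibration on 50 replicates of a
60-draw, 40-region coefficient collection, and permutation TFCE with 199
permutations on a 12-node chain graph. These sizes were chosen so each
property is measured with comfortable statistical margin while the whole
suite stays desk-scale; the framework itself has no such limits.

## Known limitations

* 1:1 matching without replacement only; no 1:k or full matching.
* Binary diagnosis only; continuous targets would need generalized
  propensity scores.
* Diversity is only as complete as the covariates fed to the score: unknown
  or unmeasured sources of population variation remain untracked by
  construction.
* Equal-sized (not equal-width) strata mean the diversity range covered can
  differ between strata.
* The permutation TFCE inherits the dependence between overlapping draws
  (see above).
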
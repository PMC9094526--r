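# Seeded synthetic multi-site cohorts with the statistical structure the
# framework assumes: site-specific age/sex composition (hence covariate
# confounding of diagnosis), a logistic diagnosis link on the covariates
# (so the true propensity model lies in the fitted model's family), and
# features carrying a group effect whose size Delta-x varies along the
# propensity spectrum, plus optional additive/scale site batch effects and
# Gaussian noise. Two single-feature toy scenarios reproduce the divergent
# diversity-performance regimes: "abide-like" (effect largest mid-spectrum)
# and "hbn-like" (effect largest at the extremes).

delta_profile <- function(pi_true, scenario, a, gamma) {
  switch(scenario,
         "abide-like" = a * (1 - abs(2 * pi_true - 1))^gamma,
         "hbn-like"   = a * abs(2 * pi_true - 1)^gamma,
         "constant"   = rep(a, length(pi_true)),
         "null"       = rep(0, length(pi_true)),
         stop("unknown scenario: ", scenario))
}

#' Specification of a synthetic multi-site cohort
#'
#' Defaults describe a 3-site cohort of 400 participants with site-graded
#' age and sex composition, covariate-confounded diagnosis at 50%
#' prevalence, and a constant group effect of 1 noise SD on 10 features with
#' no site batch effects (batch effects are injectable via `site_offset` /
#' `site_scale`).
#'
#' @param n_per_site participants per site.
#' @param sites site labels.
#' @param sex_prob per-site probability of `sex = 1`; default a gradient
#'   from 0.70 to 0.35 across sites.
#' @param age_mean,age_sd per-site age distribution (years); defaults grade
#'   the mean from 10 to 18 and the SD from 2.5 to 3.5 across sites.
#' @param age_range truncation range for ages (years).
#' @param prevalence target marginal diagnosis prevalence.
#' @param beta_age,beta_sex,beta_site logistic diagnosis-link coefficients
#'   (age on the z-scale; `beta_site` one offset per site, default a
#'   gradient from -0.2 to 0.2).
#' @param n_features number of features F.
#' @param scenario group-effect profile along the propensity spectrum:
#'   `"constant"`, `"abide-like"`, `"hbn-like"`, `"null"`.
#' @param effect_size amplitude a of the group effect (units of feature
#'   scale; the group means are separated by Delta-x).
#' @param effect_gamma shape exponent of the abide/hbn-like profiles.
#' @param site_offset per-site additive batch effect on all features.
#' @param site_scale per-site multiplicative batch effect on the noise.
#' @param noise_sd residual feature noise SD (> 0).
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_site = c(140, 130, 130),
                        sites = paste0("site", seq_along(n_per_site)),
                        sex_prob = NULL,
                        age_mean = NULL,
                        age_sd = NULL,
                        age_range = c(5, 30),
                        prevalence = 0.5,
                        beta_age = 0.8, beta_sex = 0.3,
                        beta_site = NULL,
                        n_features = 10,
                        scenario = c("constant", "abide-like", "hbn-like",
                                     "null"),
                        effect_size = 1, effect_gamma = 1,
                        site_offset = rep(0, length(n_per_site)),
                        site_scale = rep(1, length(n_per_site)),
                        noise_sd = 1) {
  scenario <- match.arg(scenario)
  K <- length(n_per_site)
  # site-graded composition defaults scale with the number of sites
  # (K = 3 gives sex 0.70/0.525/0.35, age 10/14/18, link offsets -0.2/0/0.2)
  if (is.null(sex_prob)) sex_prob <- seq(0.70, 0.35, length.out = K)
  if (is.null(age_mean)) age_mean <- seq(10, 18, length.out = K)
  if (is.null(age_sd)) age_sd <- seq(2.5, 3.5, length.out = K)
  if (is.null(beta_site)) {
    beta_site <- if (K == 1) 0 else seq(-0.2, 0.2, length.out = K)
  }
  stopifnot(K >= 1, all(n_per_site >= 1),
            length(sites) == K, length(sex_prob) == K,
            length(age_mean) == K, length(age_sd) == K,
            length(beta_site) == K, length(site_offset) == K,
            length(site_scale) == K,
            prevalence > 0, prevalence < 1,
            all(sex_prob >= 0 & sex_prob <= 1),
            n_features >= 1, noise_sd > 0)
  structure(list(n_per_site = n_per_site, sites = sites, sex_prob = sex_prob,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 prevalence = prevalence, beta_age = beta_age,
                 beta_sex = beta_sex, beta_site = beta_site,
                 n_features = n_features, scenario = scenario,
                 effect_size = effect_size, effect_gamma = effect_gamma,
                 site_offset = site_offset, site_scale = site_scale,
                 noise_sd = noise_sd),
            class = "cohort_spec")
}

#' Generate a seeded synthetic cohort
#'
#' Samples covariates per site, assigns diagnosis through a logistic link on
#' the covariates (recentered so the marginal prevalence matches the spec),
#' and draws features as group effect + site batch effect + Gaussian noise,
#' where the group effect Delta-x is a function of the true propensity
#' score. Randomness flows from the single seed through named substreams
#' (covariates, labels, noise), so repeated calls are bit-identical.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return list with `pheno` (data.frame `id`, `age`, `sex`, `site`,
#'   `diagnosis`), `features` (N x F matrix), `truth` (data.frame `id`,
#'   `pi_true`, `delta`).
#' @export
generate_cohort <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  seeds <- derive_seeds(seed, c("covariates", "labels", "noise"))
  K <- length(spec$n_per_site)
  N <- sum(spec$n_per_site)
  site_idx <- rep.int(seq_len(K), spec$n_per_site)

  set.seed(seeds[["covariates"]])
  age <- rnorm(N, spec$age_mean[site_idx], spec$age_sd[site_idx])
  age <- pmin(pmax(age, spec$age_range[1]), spec$age_range[2])
  sex <- rbinom(N, 1, spec$sex_prob[site_idx])

  age_z <- (age - mean(age)) / sd(age)
  lin <- spec$beta_age * age_z + spec$beta_sex * sex +
    spec$beta_site[site_idx]
  lin <- lin - mean(lin) + qlogis(spec$prevalence)
  pi_true <- plogis(lin)

  set.seed(seeds[["labels"]])
  y <- rbinom(N, 1, pi_true)
  if (length(unique(y)) < 2) {
    stop("infeasible composition: generated cohort contains a single class")
  }

  delta <- delta_profile(pi_true, spec$scenario, spec$effect_size,
                         spec$effect_gamma)
  set.seed(seeds[["noise"]])
  noise <- matrix(rnorm(N * spec$n_features, sd = spec$noise_sd),
                  N, spec$n_features)
  features <- (y - 0.5) * delta + spec$site_offset[site_idx] +
    spec$site_scale[site_idx] * noise
  ids <- sprintf("sub%04d", seq_len(N))
  rownames(features) <- ids
  colnames(features) <- paste0("f", seq_len(spec$n_features))

  list(
    pheno = data.frame(id = ids, age = age, sex = sex,
                       site = spec$sites[site_idx], diagnosis = y,
                       stringsAsFactors = FALSE),
    features = features,
    truth = data.frame(id = ids, pi_true = pi_true, delta = delta,
                       stringsAsFactors = FALSE)
  )
}

#' Single-feature toy cohort for the diversity-performance sign experiments
#'
#' A two-site cohort with one feature whose group difference follows the
#' requested profile of the propensity score: `"abide-like"` shrinks toward
#' both ends of the spectrum, `"hbn-like"` grows toward the extremes. The
#' covariate mix (site-graded age and sex) spreads the estimated propensity
#' scores over a wide range, so the full match / stratify / draw / fit /
#' evaluate chain is exercised end to end.
#'
#' @param scenario `"abide-like"` or `"hbn-like"`.
#' @param n total participants (default 1000; at least 80 so 10 strata can
#'   be filled after matching).
#' @param seed integer seed.
#' @param effect_size amplitude of the group effect in noise-SD units
#'   (default 1.5).
#' @return as [generate_cohort()].
#' @export
generate_toy_single_feature <- function(scenario = c("abide-like",
                                                     "hbn-like"),
                                        n = 1000, seed = 1,
                                        effect_size = 1.5) {
  scenario <- match.arg(scenario)
  if (n < 80) {
    stop("n too small: need at least 80 participants to fill 10 strata ",
         "after matching")
  }
  n1 <- n %/% 2
  spec <- cohort_spec(
    n_per_site = c(n1, n - n1), sites = c("siteA", "siteB"),
    sex_prob = c(0.65, 0.35), age_mean = c(11, 16), age_sd = c(3, 3),
    age_range = c(5, 30), prevalence = 0.5,
    beta_age = 1.2, beta_sex = 1.0, beta_site = c(-0.9, 0.9),
    n_features = 1, scenario = scenario,
    effect_size = effect_size, effect_gamma = 1, noise_sd = 1)
  generate_cohort(spec, seed = seed)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort spec: %d participants, %d sites, %d features, scenario '%s'\n",
    sum(x$n_per_site), length(x$sites), x$n_features, x$scenario))
  invisible(x)
}
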
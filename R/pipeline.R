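# End-to-end orchestration: features -> deconfound -> propensity -> match ->
# stratify -> draws -> fit -> per-stratum OOD evaluation (-> stability
# inputs). Every stage is a pure function of its inputs plus the seeds
# derived from the single experiment seed, so reruns reproduce results
# exactly.

#' Configuration of a full diversity experiment
#'
#' Provide either a phenotype table plus feature matrix, or a
#' [cohort_spec()] from which a cohort is generated at run time.
#'
#' @param pheno phenotype data.frame (`id`, `age`, `sex`, `site`,
#'   `diagnosis`) or NULL.
#' @param features N x F feature matrix with ids as row names, or NULL.
#' @param spec optional [cohort_spec()] used when `pheno` is NULL.
#' @param deconfound_method `"raw"`, `"linreg"` or `"combat"`; applied
#'   cohort-wide before matching (the default), or train-only when
#'   `deconfound_scope = "train"`.
#' @param deconfound_scope `"cohort"` (default) or `"train"` (leakage-safe
#'   refit of the deconfounding model inside every draw).
#' @param q number of strata (default 10).
#' @param scheme sampling scheme passed to [enumerate_draws()]
#'   (default `"all"`, the exhaustive 252-draw setting at q = 10, r = 5).
#' @param r number of training strata (default 5).
#' @param n_draws draws per scheme for contiguous/diverse/random.
#' @param caliper caliper multiplier for matching (default 0.2).
#' @param training a [training_config()].
#' @param compute_wd also evaluate within-distribution performance by outer
#'   k-fold CV inside every draw (default TRUE; the expensive part).
#' @param seed master seed; all stage seeds are derived from it.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(pheno = NULL, features = NULL, spec = NULL,
                              deconfound_method = c("raw", "linreg", "combat"),
                              deconfound_scope = c("cohort", "train"),
                              q = 10, scheme = "all", r = 5, n_draws = 20,
                              caliper = 0.2, training = training_config(),
                              compute_wd = TRUE, seed = 1) {
  deconfound_method <- match.arg(deconfound_method)
  deconfound_scope <- match.arg(deconfound_scope)
  if (is.null(pheno) && is.null(spec)) {
    stop("provide either pheno + features or a cohort spec")
  }
  if (!is.null(pheno) && is.null(features)) {
    stop("features must accompany pheno")
  }
  if (r < 2 || r > q - 1) stop(sprintf("r must lie in [2, %d]", q - 1))
  structure(list(pheno = pheno, features = features, spec = spec,
                 deconfound_method = deconfound_method,
                 deconfound_scope = deconfound_scope,
                 q = q, scheme = scheme, r = r, n_draws = n_draws,
                 caliper = caliper, training = training,
                 compute_wd = compute_wd, seed = seed),
            class = "experiment_config")
}

# Within-distribution performance of one training set by outer k-fold CV
# (each fold re-runs the full inner tuning).
wd_performance <- function(X, y, training, folds, seed) {
  fold_id <- stratified_folds(y, folds, seed)
  aucs <- f1s <- rep(NA_real_, folds)
  for (k in seq_len(folds)) {
    hold <- fold_id == k
    if (!any(hold) || length(unique(y[!hold])) < 2) next
    fit_k <- train_classifier(X[!hold, , drop = FALSE], y[!hold], training)
    probs <- predict(fit_k, X[hold, , drop = FALSE])
    if (length(unique(y[hold])) == 2) aucs[k] <- auc_score(y[hold], probs)
    f1s[k] <- f1_score(y[hold], probs)
  }
  c(auc = mean(aucs, na.rm = TRUE), f1 = mean(f1s, na.rm = TRUE))
}

#' Run a full diversity experiment
#'
#' Executes every stage in order: (optional) synthetic cohort generation,
#' cohort-wide deconfounding, covariate-only propensity estimation,
#' caliper-constrained optimal matching, score-ordered stratification, draw
#' enumeration under the configured scheme, and per-draw model fitting with
#' out-of-distribution evaluation in every holdout stratum (plus optional
#' within-distribution outer CV). Collects the per-draw weight vectors for
#' downstream stability analysis and the Pearson correlations between
#' performance and diversity (WD points: one per draw; OOD points: one per
#' draw x holdout stratum).
#'
#' @param config an [experiment_config()].
#' @return object of class `divprop_experiment`: list with `propensity`,
#'   `pairs`, `strata`, `draws`, `draw_table`, `ood_table`, `weights`,
#'   `correlations`, `balance` (before/after matching), `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  seeds <- derive_seeds(config$seed,
                        c("cohort", "propensity", "draws", "fits"))
  if (is.null(config$pheno)) {
    cohort <- generate_cohort(config$spec, seed = seeds[["cohort"]])
    pheno <- cohort$pheno
    features <- cohort$features
  } else {
    pheno <- config$pheno
    features <- as.matrix(config$features)
  }
  if (is.null(rownames(features))) rownames(features) <- pheno$id
  stopifnot(identical(rownames(features), as.character(pheno$id)))

  cohort_wide <- config$deconfound_scope == "cohort"
  meta_full <- encode_covariates(pheno)$meta
  if (cohort_wide) {
    dec <- deconfound(features, pheno, method = config$deconfound_method)
    X_all <- dec$adjusted
  } else {
    dec <- NULL
    X_all <- features
  }

  prop <- estimate_propensity(pheno, seed = seeds[["propensity"]])
  scores <- stats::setNames(prop$scores$score, prop$scores$id)
  y_all <- stats::setNames(as.numeric(pheno$diagnosis), pheno$id)

  case_ids <- names(y_all)[y_all == 1]
  ctrl_ids <- names(y_all)[y_all == 0]
  pairs <- match_pairs(scores[case_ids], scores[ctrl_ids],
                       caliper = config$caliper,
                       ids_case = case_ids, ids_control = ctrl_ids)
  balance <- list(before = balance_report(pheno),
                  after = if (nrow(pairs) > 0)
                    balance_report(pheno, ids = c(pairs$case_id,
                                                  pairs$control_id))
                  else NULL)
  strat <- stratify(pairs, q = config$q)
  draws <- enumerate_draws(strat, scheme = config$scheme, r = config$r,
                           n_draws = config$n_draws, seed = seeds[["draws"]])
  if (!length(draws)) {
    message("no draws under scheme '", config$scheme, "' with r = ",
            config$r, "; nothing to fit")
    return(structure(list(propensity = prop, pairs = pairs, strata = strat,
                          draws = draws, draw_table = NULL, ood_table = NULL,
                          weights = NULL, correlations = NULL,
                          balance = balance, deconfound = dec,
                          config = config),
                     class = "divprop_experiment"))
  }

  fit_seeds <- derive_seeds(seeds[["fits"]], paste0("draw", seq_along(draws)))
  draw_rows <- ood_rows <- list()
  weights <- NULL
  for (d in seq_along(draws)) {
    dr <- draws[[d]]
    tr_pairs <- strat[dr$train_pairs, , drop = FALSE]
    tr_ids <- c(tr_pairs$case_id, tr_pairs$control_id)
    tr_scores <- c(tr_pairs$score_case, tr_pairs$score_control)

    training <- config$training
    training$seed <- fit_seeds[d]
    if (cohort_wide) {
      X_train <- X_all[tr_ids, , drop = FALSE]
    } else {
      # cohort-level encoding metadata: a training subset need not span
      # every site; a site column that is constant in the subset is dropped
      # from the confound fit
      dec_d <- suppressWarnings(
        deconfound(features[tr_ids, , drop = FALSE],
                   pheno[match(tr_ids, pheno$id), , drop = FALSE],
                   method = config$deconfound_method, meta = meta_full))
      X_train <- dec_d$adjusted
    }
    fit <- train_classifier(X_train, y_all[tr_ids], training)
    if (is.null(weights)) {
      weights <- matrix(NA_real_, length(draws), length(fit$w),
                        dimnames = list(NULL, colnames(features)))
    }
    weights[d, ] <- fit$w

    wd_perf <- c(auc = NA_real_, f1 = NA_real_)
    if (isTRUE(config$compute_wd)) {
      wd_perf <- wd_performance(X_train, y_all[tr_ids], training,
                                config$training$wd_folds, fit_seeds[d])
    }
    draw_rows[[d]] <- data.frame(
      draw = d, scheme = dr$scheme,
      train_strata = paste(dr$train_strata, collapse = "+"),
      n_train = length(tr_ids), wd = dr$wd, lambda = fit$lambda,
      wd_auc = wd_perf[["auc"]], wd_f1 = wd_perf[["f1"]],
      stringsAsFactors = FALSE)

    for (s in dr$holdout_strata) {
      ho_idx <- setdiff(which(strat$stratum == s), dr$train_pairs)
      if (!length(ho_idx)) next
      ho_pairs <- strat[ho_idx, , drop = FALSE]
      ho_ids <- c(ho_pairs$case_id, ho_pairs$control_id)
      if (cohort_wide) {
        X_hold <- X_all[ho_ids, , drop = FALSE]
      } else {
        X_hold <- apply_deconfound(dec_d$model,
                                   features[ho_ids, , drop = FALSE],
                                   pheno[match(ho_ids, pheno$id), ,
                                         drop = FALSE])
      }
      rep_s <- evaluate(fit, X_hold, y_all[ho_ids])
      ood_rows[[length(ood_rows) + 1L]] <- data.frame(
        draw = d, stratum = s,
        ood_diversity = ood_diversity(tr_scores,
                                      c(ho_pairs$score_case,
                                        ho_pairs$score_control)),
        auc = rep_s$auc, f1 = rep_s$f1,
        tp = rep_s$confusion[["tp"]], tn = rep_s$confusion[["tn"]],
        fp = rep_s$confusion[["fp"]], fn = rep_s$confusion[["fn"]],
        n = rep_s$n, stringsAsFactors = FALSE)
    }
  }
  draw_table <- do.call(rbind, draw_rows)
  ood_table <- do.call(rbind, ood_rows)

  cor_or_na <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
    cor(x[ok], y[ok])
  }
  correlations <- list(
    ood_auc = cor_or_na(ood_table$ood_diversity, ood_table$auc),
    ood_f1 = cor_or_na(ood_table$ood_diversity, ood_table$f1),
    wd_auc = cor_or_na(draw_table$wd, draw_table$wd_auc),
    wd_f1 = cor_or_na(draw_table$wd, draw_table$wd_f1))

  structure(list(propensity = prop, pairs = pairs, strata = strat,
                 draws = draws, draw_table = draw_table,
                 ood_table = ood_table, weights = weights,
                 correlations = correlations, balance = balance,
                 deconfound = dec, config = config),
            class = "divprop_experiment")
}

#' Correlation between prediction performance and diversity
#'
#' @param experiment a `divprop_experiment`.
#' @param metric `"auc"` or `"f1"`.
#' @param setting `"ood"` (one point per draw x holdout stratum) or `"wd"`
#'   (one point per draw).
#' @return Pearson correlation coefficient.
#' @export
diversity_performance_cor <- function(experiment, metric = c("auc", "f1"),
                                      setting = c("ood", "wd")) {
  metric <- match.arg(metric)
  setting <- match.arg(setting)
  experiment$correlations[[paste(setting, metric, sep = "_")]]
}

#' @export
print.divprop_experiment <- function(x, ...) {
  cat("Diversity experiment\n")
  cat(sprintf("  matched pairs: %d; strata: %d; draws: %d (%s)\n",
              nrow(x$pairs), attr(x$strata, "q"), length(x$draws),
              x$config$scheme))
  if (!is.null(x$ood_table)) {
    cat(sprintf("  OOD evaluations: %d; cor(diversity, AUC) = %s\n",
                nrow(x$ood_table),
                ifelse(is.na(x$correlations$ood_auc), "NA",
                       sprintf("%.3f", x$correlations$ood_auc))))
  }
  invisible(x)
}
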
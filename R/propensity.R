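# Propensity scores pi = P(Y = 1 | C) from participant covariates only
# (age, sex, site) -- never from brain features. A weakly ridge-regularized
# logistic model provides the raw scores; a Platt (sigmoid) recalibration,
# fitted on out-of-fold linear predictors from 5-fold cross-fitting, maps
# them to the final calibrated scores. The propensity score is a balancing
# score: participants with the same score have exchangeable covariate
# profiles across the diagnostic groups, which is what makes it a one-number
# index of cohort diversity.

#' Encode phenotype covariates as a numeric design
#'
#' Builds the covariate design used by the propensity model and the balance
#' diagnostics: standardized age, binary sex, and a one-hot block over sites.
#' The encoding metadata (site level order, age centering constants) is
#' stored so new rows can be encoded identically.
#'
#' @param pheno data.frame with columns `id`, `age` (years), `sex` (0/1 or a
#'   2-level factor), `site`, and optionally `diagnosis` (0/1).
#' @param meta encoding metadata from a previous call; when supplied the same
#'   transform is applied (unseen site levels are an error).
#' @return object of class `covariate_design`: list with `X` (numeric matrix
#'   with columns `age_z`, `sex`, `site_<level>...`), `ids`, `meta`.
#' @export
encode_covariates <- function(pheno, meta = NULL) {
  required <- c("id", "age", "sex", "site")
  missing_cols <- setdiff(required, names(pheno))
  if (length(missing_cols)) {
    stop("phenotype table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in required) {
    bad <- which(is.na(pheno[[col]]))
    if (length(bad)) {
      stop(sprintf("missing covariate value in row %d, column '%s'", bad[1], col))
    }
  }
  age <- as.numeric(pheno$age)
  if (!all(is.finite(age))) stop("non-finite age values")
  sex <- pheno$sex
  if (is.factor(sex) || is.character(sex)) {
    lev <- if (!is.null(meta)) meta$sex_levels else sort(unique(as.character(sex)))
    if (length(lev) > 2) stop("sex must be binary")
    sex <- as.numeric(match(as.character(sex), lev) - 1)
    if (any(is.na(sex))) stop("unseen sex level at transform time")
  } else {
    lev <- NULL
    sex <- as.numeric(sex)
    if (!all(sex %in% c(0, 1))) stop("numeric sex must be 0/1")
  }
  site <- as.character(pheno$site)
  if (is.null(meta)) {
    site_levels <- sort(unique(site))
    age_mean <- mean(age)
    age_sd <- sd(age)
    if (!is.finite(age_sd) || age_sd == 0) age_sd <- 1
    meta <- list(site_levels = site_levels, age_mean = age_mean,
                 age_sd = age_sd, sex_levels = lev)
  } else {
    unseen <- setdiff(site, meta$site_levels)
    if (length(unseen)) {
      stop("unseen site level at transform time: ", paste(unseen, collapse = ", "))
    }
  }
  site_block <- vapply(meta$site_levels, function(s) as.numeric(site == s),
                       numeric(length(site)))
  site_block <- matrix(site_block, nrow = length(site),
                       dimnames = list(NULL, paste0("site_", meta$site_levels)))
  X <- cbind(age_z = (age - meta$age_mean) / meta$age_sd, sex = sex, site_block)
  structure(list(X = X, ids = as.character(pheno$id), meta = meta),
            class = "covariate_design")
}

#' Estimate calibrated propensity scores from covariates
#'
#' Fits a logistic model of diagnosis on the encoded covariates (a very weak
#' ridge penalty keeps the fit defined under separation; the intercept is
#' unpenalized), then recalibrates with Platt scaling fitted on out-of-fold
#' linear predictors from stratified cross-fitting. Scores are clipped to
#' `[1e-6, 1 - 1e-6]`.
#'
#' @param pheno phenotype data.frame with `id`, `age`, `sex`, `site`,
#'   `diagnosis` (binary 0/1; both classes required).
#' @param lambda ridge penalty of the base logistic fit (default `1e-4`).
#' @param folds number of cross-fitting folds for the calibration map.
#' @param seed integer seed driving fold assignment.
#' @return object of class `propensity_model`: list with `coefficients`
#'   (named, intercept first), `platt` (`c(intercept, slope)` of the
#'   recalibration), `meta` (covariate encoding), `scores` (data.frame with
#'   `id`, `score`), `lambda`, `folds`, `seed`.
#' @export
estimate_propensity <- function(pheno, lambda = 1e-4, folds = 5, seed = 1) {
  if (!"diagnosis" %in% names(pheno)) stop("phenotype table lacks 'diagnosis'")
  y <- as.numeric(pheno$diagnosis)
  if (!all(y %in% c(0, 1))) stop("diagnosis must be 0/1")
  if (length(unique(y)) < 2) stop("both diagnostic classes must be present")
  design <- encode_covariates(pheno)
  X <- design$X
  if (nrow(X) <= ncol(X) + 1) {
    warning("fewer participants than recommended for ", ncol(X),
            " design columns")
  }
  base <- logistic_ridge_fit(X, y, lambda = lambda)

  fold_id <- stratified_folds(y, folds, seed)
  f_oof <- numeric(length(y))
  for (k in seq_len(folds)) {
    hold <- fold_id == k
    fit_k <- logistic_ridge_fit(X[!hold, , drop = FALSE], y[!hold],
                                lambda = lambda)
    f_oof[hold] <- drop(X[hold, , drop = FALSE] %*% fit_k$w) + fit_k$b
  }
  platt <- logistic_ridge_fit(matrix(f_oof, ncol = 1), y, lambda = 1e-8)

  f_full <- drop(X %*% base$w) + base$b
  scores <- clip01(plogis(platt$b + platt$w * f_full))
  structure(list(
    coefficients = stats::setNames(c(base$b, base$w),
                                   c("(Intercept)", colnames(X))),
    platt = c(intercept = platt$b, slope = platt$w),
    meta = design$meta,
    scores = data.frame(id = design$ids, score = scores,
                        stringsAsFactors = FALSE),
    lambda = lambda, folds = folds, seed = seed
  ), class = "propensity_model")
}

#' Predict calibrated propensity scores for new participants
#'
#' @param object a `propensity_model`.
#' @param newdata phenotype data.frame with `id`, `age`, `sex`, `site`.
#' @param ... unused.
#' @return numeric vector of calibrated scores in (0, 1), named by id.
#' @export
predict.propensity_model <- function(object, newdata, ...) {
  design <- encode_covariates(newdata, meta = object$meta)
  beta <- object$coefficients
  f <- drop(design$X %*% beta[-1L]) + beta[1L]
  stats::setNames(
    clip01(plogis(object$platt["intercept"] + object$platt["slope"] * f)),
    design$ids)
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("Propensity model (covariates-only logistic + Platt calibration)\n")
  cat(sprintf("  %d participants, %d covariate columns, ridge lambda = %g\n",
              nrow(x$scores), length(x$coefficients) - 1L, x$lambda))
  cat(sprintf("  score range: [%.3f, %.3f]\n",
              min(x$scores$score), max(x$scores$score)))
  invisible(x)
}
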
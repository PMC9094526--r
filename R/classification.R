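# Nested cross-validated L2-penalized logistic classification of diagnosis
# from brain features. Features are z-scored on the training rows only; the
# regularization strength lambda is tuned by inner 5-fold CV (selection
# metric: AUC, ties resolved toward stronger regularization) over a grid of
# 7 log-equidistant values in [1e-3, 1e+3] in the J(w) parameterization.

#' Training configuration for the pattern classifier
#'
#' @param lambda_grid ascending positive penalty grid; default the 7
#'   log-equidistant values spanning `[1e-3, 1e+3]`.
#' @param inner_folds folds of the inner tuning CV (default 5).
#' @param wd_folds outer folds for within-distribution evaluation
#'   (default 10).
#' @param seed seed for all fold assignments.
#' @return list of class `training_config`.
#' @export
training_config <- function(lambda_grid = 10^seq(-3, 3, length.out = 7),
                            inner_folds = 5, wd_folds = 10, seed = 1) {
  stopifnot(all(lambda_grid > 0), !is.unsorted(lambda_grid),
            inner_folds >= 2, wd_folds >= 2)
  structure(list(lambda_grid = lambda_grid, inner_folds = inner_folds,
                 wd_folds = wd_folds, seed = seed),
            class = "training_config")
}

#' Train the penalized logistic classifier with inner-CV tuning
#'
#' Z-scores features using training rows only, selects lambda by stratified
#' inner k-fold CV maximizing out-of-fold AUC (ties go to the largest
#' lambda), and refits on all training rows at the chosen lambda by
#' minimizing \eqn{J(w)} (see [logistic_ridge_fit()]).
#'
#' @param X numeric n x F feature matrix (training rows).
#' @param y binary 0/1 labels, both classes present.
#' @param config a [training_config()].
#' @return object of class `classifier_fit`: `w`, `b`, `lambda`, `mu`/`sigma`
#'   (z-scoring parameters), `cv_auc` (mean inner-CV AUC per grid value),
#'   `config`.
#' @export
train_classifier <- function(X, y, config = training_config()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(is.finite(X))) stop("non-finite feature values")
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  mu <- colMeans(X)
  sigma <- apply(X, 2, sd)
  sigma[!is.finite(sigma) | sigma == 0] <- 1
  Xz <- sweep(sweep(X, 2, mu), 2, sigma, "/")

  grid <- config$lambda_grid
  if (length(grid) > 1) {
    fold_id <- stratified_folds(y, config$inner_folds, config$seed)
    cv_auc <- numeric(length(grid))
    oof <- matrix(NA_real_, nrow(X), length(grid))
    for (k in seq_len(config$inner_folds)) {
      hold <- fold_id == k
      if (length(unique(y[!hold])) < 2 || !any(hold)) next
      Xtr <- Xz[!hold, , drop = FALSE]
      for (g in seq_along(grid)) {
        fit_g <- logistic_ridge_fit(Xtr, y[!hold], lambda = grid[g])
        oof[hold, g] <- plogis(drop(Xz[hold, , drop = FALSE] %*% fit_g$w) +
                                 fit_g$b)
      }
    }
    for (g in seq_along(grid)) {
      ok <- !is.na(oof[, g])
      cv_auc[g] <- suppressWarnings(auc_score(y[ok], oof[ok, g]))
    }
    best <- max(which(cv_auc >= max(cv_auc, na.rm = TRUE) - 1e-12))
    lambda <- grid[best]
  } else {
    cv_auc <- NA_real_
    lambda <- grid
  }
  final <- logistic_ridge_fit(Xz, y, lambda = lambda)
  structure(list(w = final$w, b = final$b, lambda = lambda,
                 mu = mu, sigma = sigma,
                 cv_auc = stats::setNames(cv_auc, signif(grid, 3)),
                 config = config),
            class = "classifier_fit")
}

#' Predicted class probabilities from a fitted classifier
#'
#' Applies the z-scoring parameters learned on the training set, then the
#' sigmoid of the linear predictor.
#'
#' @param object a `classifier_fit`.
#' @param newdata numeric matrix with the same F columns.
#' @param ... unused.
#' @return probabilities of the positive class.
#' @export
predict.classifier_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  Xz <- sweep(sweep(X, 2, object$mu), 2, object$sigma, "/")
  plogis(drop(Xz %*% object$w) + object$b)
}

#' Evaluate a fitted classifier on held-out participants
#'
#' Computes AUC (on probabilities), F1 (probability threshold 0.5, positive
#' class = diagnosis), and confusion proportions normalized to sum to 1;
#' optionally broken down by grouping labels (e.g. site, sex, age bin). With
#' single-class labels the AUC is reported as `NA` with a warning and F1 is
#' still computed.
#'
#' @param fit a `classifier_fit`.
#' @param X held-out feature rows.
#' @param y held-out binary labels.
#' @param groups optional data.frame/list of grouping label vectors aligned
#'   with the rows of `X`.
#' @return object of class `metric_report`: list with `auc`, `f1`,
#'   `confusion` (tp/tn/fp/fn proportions), `n`, and `by_group` (per grouping
#'   variable, per level: n + confusion proportions) when `groups` given.
#' @export
evaluate <- function(fit, X, y, groups = NULL) {
  y <- as.numeric(y)
  probs <- predict(fit, X)
  auc <- auc_score(y, probs)
  rep <- list(auc = auc, f1 = f1_score(y, probs),
              confusion = confusion_props(y, probs), n = length(y),
              probs = probs)
  if (!is.null(groups)) {
    groups <- as.data.frame(groups, stringsAsFactors = FALSE)
    rep$by_group <- lapply(groups, function(gv) {
      lv <- sort(unique(as.character(gv)))
      out <- lapply(lv, function(l) {
        sel <- as.character(gv) == l
        c(n = sum(sel), confusion_props(y[sel], probs[sel]))
      })
      stats::setNames(out, lv)
    })
  }
  structure(rep, class = "metric_report")
}

#' Average confusion matrices in chunks of increasing diversity
#'
#' Sorts per-stratum evaluation reports by their OOD diversity, splits them
#' into `n_chunks` near-equal groups (remainder to the lowest-diversity
#' chunks), and averages the confusion proportions within each chunk.
#'
#' @param reports data.frame with columns `ood_diversity`, `tp`, `tn`, `fp`,
#'   `fn` (one row per (draw, holdout stratum) evaluation).
#' @param n_chunks number of diversity chunks (default 6).
#' @return data.frame with one row per chunk: `chunk`, `n`,
#'   `diversity_lo`/`diversity_hi`, mean `tp`/`tn`/`fp`/`fn`.
#' @export
confusion_by_diversity <- function(reports, n_chunks = 6) {
  stopifnot(all(c("ood_diversity", "tp", "tn", "fp", "fn") %in% names(reports)))
  if (nrow(reports) < n_chunks) {
    stop(sprintf("need at least %d reports, got %d", n_chunks, nrow(reports)))
  }
  ord <- order(reports$ood_diversity)
  reports <- reports[ord, , drop = FALSE]
  chunk <- chunk_assign(nrow(reports), n_chunks)
  out <- lapply(seq_len(n_chunks), function(cc) {
    rows <- reports[chunk == cc, , drop = FALSE]
    data.frame(chunk = cc, n = nrow(rows),
               diversity_lo = min(rows$ood_diversity),
               diversity_hi = max(rows$ood_diversity),
               tp = mean(rows$tp), tn = mean(rows$tn),
               fp = mean(rows$fp), fn = mean(rows$fn))
  })
  do.call(rbind, out)
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Evaluation on %d participants: AUC %s, F1 %.3f\n", x$n,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc)), x$f1))
  cm <- x$confusion
  cat(sprintf("  confusion (proportions): TP %.2f TN %.2f FP %.2f FN %.2f\n",
              cm["tp"], cm["tn"], cm["fp"], cm["fn"]))
  invisible(x)
}
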
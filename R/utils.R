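# Shared numerical helpers. These are deliberately small and dependency-free;
# everything stochastic takes an explicit seed so reruns are bit-identical.

#' Clip probabilities away from 0 and 1
#'
#' Scores exactly at 0 or 1 break downstream logit operations; all propensity
#' and classifier probabilities are clipped to `[eps, 1 - eps]`.
#'
#' @param p numeric vector of probabilities.
#' @param eps clipping margin (default `1e-6`).
#' @return clipped numeric vector.
#' @export
clip01 <- function(p, eps = 1e-6) {
  pmin(pmax(p, eps), 1 - eps)
}

# Sizes of k near-equal chunks of n items; the remainder goes to the
# lowest-index chunks (e.g. 23 into 10 -> 3,3,3,2,...,2).
chunk_sizes <- function(n, k) {
  stopifnot(k >= 1, n >= k)
  sizes <- rep(n %/% k, k)
  rem <- n %% k
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  as.integer(sizes)
}

# Chunk membership (1..k) for n already-sorted items.
chunk_assign <- function(n, k) {
  rep.int(seq_len(k), chunk_sizes(n, k))
}

# Derive named sub-seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, labels) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, length(labels))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  stats::setNames(s, labels)
}

# Stratified fold assignment: classes are spread evenly over k folds.
stratified_folds <- function(y, k, seed) {
  stopifnot(k >= 2)
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Fit an L2-penalized logistic regression by direct minimization
#'
#' Minimizes the cost \deqn{J(w, b) = -\sum_i [y_i \log\varphi(z_i) +
#' (1-y_i)\log(1-\varphi(z_i))] + \lambda \lVert w \rVert^2} with
#' \eqn{z_i = w^T x_i + b} and \eqn{\varphi} the sigmoid; the intercept is
#' never penalized. This is the exact parameterization used throughout the
#' package (propensity base model and pattern classifier), so the
#' regularization grid has literal meaning in \eqn{J(w)}.
#'
#' @param X numeric matrix (n x p) of predictors, no intercept column.
#' @param y binary 0/1 response vector of length n.
#' @param lambda non-negative ridge penalty on the slope coefficients.
#' @param maxit maximum BFGS iterations.
#' @return list with `w` (slopes), `b` (intercept), `value` (final cost),
#'   `converged` (logical).
#' @export
logistic_ridge_fit <- function(X, y, lambda = 0, maxit = 500) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("non-finite values in predictor matrix")
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(y)) < 2) stop("both classes must be present to fit")
  p <- ncol(X)
  obj <- function(theta) {
    b <- theta[1L]
    w <- theta[-1L]
    z <- drop(X %*% w) + b
    # log(phi(z)) and log(1 - phi(z)) computed stably
    ll <- sum(y * plogis(z, log.p = TRUE) + (1 - y) * plogis(-z, log.p = TRUE))
    -ll + lambda * sum(w^2)
  }
  grad <- function(theta) {
    b <- theta[1L]
    w <- theta[-1L]
    r <- plogis(drop(X %*% w) + b) - y
    c(sum(r), drop(crossprod(X, r)) + 2 * lambda * w)
  }
  fit <- stats::optim(rep(0, p + 1L), obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  list(w = fit$par[-1L], b = fit$par[1L], value = fit$value,
       converged = fit$convergence == 0L)
}

# Cost J(w) at given parameters (used for optimizer sanity checks).
logistic_ridge_cost <- function(w, b, X, y, lambda) {
  z <- drop(as.matrix(X) %*% w) + b
  ll <- sum(y * plogis(z, log.p = TRUE) + (1 - y) * plogis(-z, log.p = TRUE))
  -ll + lambda * sum(w^2)
}

#' Area under the ROC curve
#'
#' Thin wrapper around [pROC::auc()] with a fixed orientation (positive class
#' is `1`, larger scores indicate the positive class) so results are
#' deterministic. Returns `NA` with a warning when only one class is present.
#'
#' @param labels binary 0/1 vector.
#' @param scores numeric scores (e.g. predicted probabilities).
#' @return AUC in `[0, 1]`, or `NA_real_`.
#' @export
auc_score <- function(labels, scores) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  as.numeric(pROC::auc(labels, scores, levels = c(0, 1),
                       direction = "<", quiet = TRUE))
}

#' F1 score at a fixed probability threshold
#'
#' Positive class is `1`; predictions are `scores >= threshold`. When there
#' are no true positives and no predicted positives the score is defined as 0.
#'
#' @param labels binary 0/1 vector.
#' @param scores predicted probabilities.
#' @param threshold decision threshold (default 0.5).
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(labels, scores, threshold = 0.5) {
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

# Confusion proportions (sum to 1) at a fixed threshold.
confusion_props <- function(labels, scores, threshold = 0.5) {
  pred <- as.numeric(scores >= threshold)
  n <- length(labels)
  c(tp = sum(pred == 1 & labels == 1) / n,
    tn = sum(pred == 0 & labels == 0) / n,
    fp = sum(pred == 1 & labels == 0) / n,
    fn = sum(pred == 0 & labels == 1) / n)
}

# Vectorized one-way ANOVA over the columns of a matrix: X is n x m,
# g a grouping vector of length n. Returns F and p per column.
# Zero within-group variance with between-group signal yields F = Inf, p = 0.
oneway_f <- function(X, g) {
  X <- as.matrix(X)
  g <- as.factor(g)
  k <- nlevels(g)
  n <- nrow(X)
  if (k < 2) stop("need at least 2 groups")
  cnt <- as.vector(table(g))
  if (any(cnt < 2)) stop("each group needs at least 2 observations")
  gm <- colMeans(X)
  sums <- rowsum(X, g)                      # k x m group sums
  means <- sums / cnt
  ssb <- colSums(cnt * sweep(means, 2, gm)^2)
  sst <- colSums(sweep(X, 2, gm)^2)
  ssw <- pmax(sst - ssb, 0)
  fstat <- (ssb / (k - 1)) / (ssw / (n - k))
  fstat[ssw == 0 & ssb > 0] <- Inf
  fstat[ssw == 0 & ssb == 0] <- 0
  p <- pf(fstat, k - 1, n - k, lower.tail = FALSE)
  p[is.infinite(fstat)] <- 0
  list(f = fstat, p = p, df1 = k - 1, df2 = n - k)
}
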
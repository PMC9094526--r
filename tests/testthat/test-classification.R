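test_that("the solver minimizes J(w) and respects the lambda grid", {
  set.seed(61)
  X <- matrix(rnorm(80 * 3), 80, 3)
  y <- rbinom(80, 1, plogis(X[, 1] - X[, 2]))
  for (lam in c(1e-3, 1, 100)) {
    fit <- logistic_ridge_fit(X, y, lambda = lam)
    expect_true(fit$converged)
    j0 <- divprop:::logistic_ridge_cost(rep(0, 3), 0, X, y, lam)
    expect_lte(fit$value, j0)
    # local optimality: small perturbations only increase the cost
    for (k in 1:3) {
      d <- rnorm(4, sd = 1e-3)
      expect_gte(divprop:::logistic_ridge_cost(fit$w + d[-1], fit$b + d[1],
                                               X, y, lam) + 1e-10, fit$value)
    }
  }
})

test_that("ridge path agrees with glmnet under the lambda conversion", {
  set.seed(62)
  n <- 150
  X <- matrix(rnorm(n * 4), n, 4)
  y <- rbinom(n, 1, plogis(0.8 * X[, 1] - 0.5 * X[, 3]))
  for (lam in c(0.1, 1, 10)) {
    ours <- logistic_ridge_fit(X, y, lambda = lam)
    # glmnet ridge objective: (1/n) loglik + lam_g * ||w||^2 / 2
    gfit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                           lambda = 2 * lam / n, standardize = FALSE,
                           thresh = 1e-12)
    expect_equal(unname(ours$w), as.numeric(gfit$beta), tolerance = 5e-3)
    expect_equal(ours$b, as.numeric(gfit$a0), tolerance = 5e-3)
  }
})

test_that("predicted probabilities follow the sigmoid arithmetic", {
  fit <- structure(list(w = 2, b = -1, lambda = 1, mu = 0, sigma = 1),
                   class = "classifier_fit")
  x <- matrix(c(-1, 0, 0.5, 3), ncol = 1)
  expect_equal(predict(fit, x), 1 / (1 + exp(-(2 * x[, 1] - 1))),
               tolerance = 1e-12)
})

test_that("separable data reach training AUC 1 at any grid lambda", {
  set.seed(63)
  X <- rbind(matrix(rnorm(40, -3), 20, 2), matrix(rnorm(40, 3), 20, 2))
  y <- rep(c(0, 1), each = 20)
  for (lam in c(1e-3, 1e3)) {
    fit <- train_classifier(X, y, training_config(lambda_grid = lam))
    expect_equal(evaluate(fit, X, y)$auc, 1)
  }
})

test_that("weight norm is non-increasing in lambda", {
  set.seed(64)
  X <- matrix(rnorm(100 * 6), 100, 6)
  y <- rbinom(100, 1, plogis(X[, 1]))
  norms <- sapply(10^seq(-3, 3), function(lam) {
    sqrt(sum(logistic_ridge_fit(X, y, lambda = lam)$w^2))
  })
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("z-scoring parameters come from the training rows only", {
  set.seed(65)
  X <- matrix(rnorm(60 * 4), 60, 4)
  y <- rbinom(60, 1, 0.5)
  fit <- train_classifier(X, y, training_config(seed = 2))
  expect_equal(fit$mu, colMeans(X))
  Xtest <- matrix(rnorm(20 * 4, mean = 50), 20, 4)  # wildly shifted test rows
  p1 <- predict(fit, Xtest)
  fit2 <- train_classifier(X, y, training_config(seed = 2))
  # test rows never touched the fit: refitting gives bit-identical weights
  expect_identical(fit$w, fit2$w)
  expect_identical(fit$lambda, fit2$lambda)
  expect_length(p1, 20)
})

test_that("AUC equals the exhaustive pair-counting estimate", {
  set.seed(66)
  for (rep in 1:15) {
    n <- sample(6:30, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 2)                 # rounding forces ties
    expect_equal(auc_score(y, s), auc_pair_counting(y, s), tolerance = 1e-12)
  }
  # 6-participant toy: AUC equals the normalized Mann-Whitney U
  y6 <- c(1, 1, 1, 0, 0, 0)
  s6 <- c(0.9, 0.6, 0.4, 0.6, 0.3, 0.1)
  expect_equal(auc_score(y6, s6), auc_pair_counting(y6, s6))
})

test_that("evaluate reports the documented metrics and degenerate cases", {
  fit <- structure(list(w = 10, b = 0, lambda = 1, mu = 0, sigma = 1),
                   class = "classifier_fit")
  X <- matrix(c(rep(1, 10), rep(-1, 10)), ncol = 1)
  y <- rep(c(1, 0), each = 10)
  r <- evaluate(fit, X, y)
  expect_equal(r$auc, 1)
  expect_equal(r$f1, 1)
  expect_equal(unname(r$confusion[c("tp", "tn")]), c(0.5, 0.5))
  expect_equal(sum(r$confusion), 1)
  # constant scorer: tie convention gives AUC 0.5; threshold >= 0.5 counts
  # every prediction positive
  fit0 <- structure(list(w = 0, b = 0, lambda = 1, mu = 0, sigma = 1),
                    class = "classifier_fit")
  r0 <- evaluate(fit0, X, y)
  expect_equal(r0$auc, 0.5)
  expect_equal(unname(r0$confusion[["fn"]] + r0$confusion[["tn"]]), 0)
  expect_equal(sum(r0$confusion), 1)
  # single-class evaluation labels: AUC missing with warning, F1 computed
  expect_warning(r1 <- evaluate(fit, X, rep(1, 20)), "one class")
  expect_true(is.na(r1$auc))
  expect_equal(r1$f1, f1_score(rep(1, 20), predict(fit, X)))
})

test_that("per-group confusion breakdowns are returned when requested", {
  fit <- structure(list(w = 5, b = 0, lambda = 1, mu = 0, sigma = 1),
                   class = "classifier_fit")
  X <- matrix(c(1, 1, -1, -1), ncol = 1)
  y <- c(1, 0, 1, 0)
  r <- evaluate(fit, X, y, groups = data.frame(site = c("a", "a", "b", "b")))
  expect_named(r$by_group, "site")
  expect_equal(r$by_group$site$a[["n"]], 2)
  expect_equal(r$by_group$site$a[["tp"]], 0.5)
})

test_that("confusion chunks follow the sort-and-split rule", {
  mk <- function(div) data.frame(ood_diversity = div, tp = div, tn = 0,
                                 fp = 0, fn = 1 - div)
  same <- mk(rep(0.4, 6))
  c6 <- confusion_by_diversity(same, 6)
  expect_equal(c6$tp, rep(0.4, 6))
  r12 <- mk((1:12) / 12)
  c12 <- confusion_by_diversity(r12, 6)
  expect_equal(c12$tp, sapply(seq(1, 11, 2), function(i) mean(c(i, i + 1) / 12)))
  r13 <- mk((1:13) / 13)
  c13 <- confusion_by_diversity(r13, 6)
  expect_equal(c13$n, c(3, 2, 2, 2, 2, 2))
  expect_error(confusion_by_diversity(mk((1:4) / 4), 6), "at least 6")
})
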
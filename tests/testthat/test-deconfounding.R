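test_that("residualization removes confound contributions exactly", {
  set.seed(71)
  n <- 300
  age <- rnorm(n, 12, 3)
  # independent confound: output stays essentially the centered input
  X <- matrix(rnorm(n * 3), n, 3)
  out <- residualize(X, cbind(age = age))
  for (f in 1:3) expect_gt(cor(out$adjusted[, f], X[, f]), 0.99)
  # perfectly confounded feature collapses to its mean
  X2 <- cbind(2 * age)
  out2 <- residualize(X2, cbind(age = age))
  expect_lt(sd(out2$adjusted[, 1]), 1e-10)
  expect_equal(mean(out2$adjusted[, 1]), mean(X2), tolerance = 1e-10)
})

test_that("site residualization equals within-site centering", {
  set.seed(72)
  n <- 200
  site <- rep(c(0, 1), each = n / 2)
  X <- cbind(1.5 * site + rnorm(n))
  out <- residualize(X, cbind(site = site))
  # oracle: subtract group means, add back grand mean
  oracle <- X - ave(X[, 1], site) + mean(X)
  expect_equal(out$adjusted[, 1], oracle[, 1], tolerance = 1e-10)
  m0 <- mean(out$adjusted[site == 0, 1])
  m1 <- mean(out$adjusted[site == 1, 1])
  expect_lt(abs(m1 - m0), 1e-10)
})

test_that("residualization is idempotent and transfers to new rows", {
  set.seed(73)
  n <- 150
  C <- cbind(rnorm(n), rbinom(n, 1, 0.5))
  X <- matrix(rnorm(n * 4), n, 4) + C[, 1]
  out1 <- residualize(X, C)
  out2 <- residualize(out1$adjusted, C)
  expect_equal(out1$adjusted, out2$adjusted, tolerance = 1e-8)
  # stored parameters reproduce the transform
  redo <- apply_deconfound(out1$model, X, confounds = C)
  expect_equal(redo, out1$adjusted, tolerance = 1e-12)
})

test_that("collinear confound columns are dropped with a warning", {
  set.seed(74)
  C <- cbind(a = rnorm(50))
  C <- cbind(C, b = 2 * C[, 1])
  expect_warning(residualize(matrix(rnorm(100), 50, 2), C), "collinear")
})

test_that("harmonization agrees with the reference empirical-Bayes fit", {
  skip_if_not_installed("sva")
  set.seed(75)
  n <- 120
  site <- rep(c("a", "b"), each = n / 2)
  age <- rnorm(n, 12, 3)
  sexv <- rbinom(n, 1, 0.5)
  X <- matrix(rnorm(n * 8), n, 8)
  X[site == "b", ] <- X[site == "b", ] * 1.6 + 1.2
  mod <- cbind(age_z = scale(age)[, 1], sex = sexv)
  ours <- combat_adjust(X, site, mod, two_step = FALSE)$adjusted
  ref <- t(sva::ComBat(dat = t(X), batch = site,
                       mod = cbind(1, mod), par.prior = TRUE))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-4)
})

test_that("injected additive and scale site effects are removed", {
  set.seed(76)
  n <- 400
  site <- rep(c("a", "b"), each = n / 2)
  age <- rnorm(n, 12, 3)
  sexv <- rbinom(n, 1, 0.5)
  X <- matrix(rnorm(n * 6), n, 6)
  X[site == "b", ] <- X[site == "b", ] * 3 + 2      # offset +2, scale x3
  mod <- cbind(age_z = scale(age)[, 1], sex = sexv)
  adj <- combat_adjust(X, site, mod, two_step = FALSE)$adjusted
  # location: the between-site gap (+2 before harmonization) collapses;
  # empirical-Bayes shrinkage leaves zero-mean per-feature noise on the
  # order of the site-mean standard error, so the bias is judged on the
  # feature-averaged moments and the per-feature residual on the SMD scale
  gap <- mean(colMeans(adj[site == "b", ]) - colMeans(adj[site == "a", ]))
  expect_lt(abs(gap), 0.1)
  for (f in 1:6) {
    expect_lt(smd_continuous(adj[site == "a", f], adj[site == "b", f]), 0.2)
    ratio <- sd(adj[site == "a", f]) / sd(adj[site == "b", f])
    expect_gt(ratio, 0.85)
    expect_lt(ratio, 1.18)
  }
  # identical distributions across sites: harmonization is near-identity
  X0 <- matrix(rnorm(n * 4), n, 4)
  adj0 <- combat_adjust(X0, site, mod, two_step = FALSE)$adjusted
  expect_lt(sqrt(mean((adj0 - X0)^2)), 0.2)
})

test_that("age slope survives step 1 and is removed by step 2", {
  set.seed(77)
  n <- 400
  site <- rep(c("a", "b"), each = n / 2)
  age <- rnorm(n, 12, 3)                     # sites balanced in age
  sexv <- rbinom(n, 1, 0.5)
  X <- cbind(1.0 * age + rnorm(n, sd = 1))
  mod <- cbind(age = age, sex = sexv)
  step1 <- combat_adjust(X, site, mod, two_step = FALSE)$adjusted
  slope1 <- coef(lm(step1[, 1] ~ age))[2]
  expect_gt(slope1, 0.8)
  expect_lt(slope1, 1.2)
  both <- combat_adjust(X, site, mod, two_step = TRUE)$adjusted
  expect_lt(abs(coef(lm(both[, 1] ~ age))[2]), 0.1)
})

test_that("harmonization guards degenerate inputs", {
  set.seed(78)
  X <- matrix(rnorm(30), 10, 3)
  expect_error(combat_adjust(X, c(rep("a", 9), "b"),
                             cbind(rnorm(10))), "single participant.*b")
  Xc <- cbind(X[, 1:2], const = 1)
  site <- rep(c("a", "b"), 5)
  expect_warning(out <- combat_adjust(Xc, site, cbind(rnorm(10)),
                                      two_step = FALSE), "constant feature")
  expect_equal(out$adjusted[, 3], Xc[, 3])  # passthrough
  expect_equal(dim(out$adjusted), dim(Xc))
})

test_that("the deconfound front end preserves shape and supports new rows", {
  set.seed(79)
  ph <- make_pheno(120, n_sites = 2, seed = 79)
  X <- matrix(rnorm(120 * 5), 120, 5,
              dimnames = list(ph$id, paste0("f", 1:5)))
  for (m in c("raw", "linreg", "combat")) {
    out <- deconfound(X, ph, method = m)
    expect_equal(dim(out$adjusted), dim(X))
    expect_identical(rownames(out$adjusted), rownames(X))
    redo <- apply_deconfound(out$model, X, pheno = ph)
    expect_equal(unname(redo), unname(out$adjusted), tolerance = 1e-8)
  }
})
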
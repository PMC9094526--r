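test_that("consistency matrix has the documented structure", {
  W <- matrix(rep(c(1, -2, 3), 4), 4, 3, byrow = TRUE)
  cm <- consistency_matrix(W, diversity = c(0.3, 0.1, 0.4, 0.2))
  expect_equal(unname(cm), matrix(1, 4, 4), ignore_attr = TRUE)
  # anti-correlated weights
  W2 <- rbind(c(1, 0, -1), c(-1, 0, 1))
  cm2 <- consistency_matrix(W2, c(0.1, 0.2))
  expect_equal(cm2[1, 2], -1)
  # hand vectors against the direct correlation formula
  set.seed(81)
  W3 <- matrix(rnorm(12), 3, 4)
  div <- c(0.2, 0.05, 0.4)
  cm3 <- consistency_matrix(W3, div)
  ord <- order(div)
  expect_equal(unname(cm3), unname(cor(t(W3[ord, ]))), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(cm3), unname(t(cm3)))
  expect_equal(attr(cm3, "diversity"), sort(div))
  # invariant to a common rescaling of all weight vectors
  expect_equal(unname(consistency_matrix(5 * W3, div)), unname(cm3),
               tolerance = 1e-12, ignore_attr = TRUE)
  # zero-variance weight vector yields missing entries, unit diagonal
  W4 <- rbind(c(1, 1, 1), c(1, 2, 3))
  cm4 <- consistency_matrix(W4, c(0.1, 0.2))
  expect_true(is.na(cm4[1, 2]))
  expect_equal(diag(cm4), c(1, 1))
})

test_that("node coefficients aggregate incident edges correctly", {
  # constant edge weights: every node value equals the constant
  P <- 5
  w <- rep(0.7, P * (P - 1) / 2)
  expect_equal(node_coefficients(w, P), rep(0.7, P))
  # P = 3 hand enumeration: edges (1,2)=+1, (1,3)=-1, (2,3)=0
  w3 <- c(1, -1, 0)
  expect_equal(node_coefficients(w3, 3), c(0, 0.5, -0.5))
  sg <- node_coefficients(w3, 3, mode = "signed")
  expect_equal(sg$positive[1], 1)
  expect_equal(sg$negative[1], -1)
  expect_true(is.na(sg$negative[2]))        # node 2 has no negative edge
  # thickness weights pass through
  wt <- rnorm(4)
  expect_equal(node_coefficients(wt, 4), wt)
  w3p <- rnorm(3)   # at P = 3 the parcel reading must be requested explicitly
  expect_equal(node_coefficients(w3p, 3, provenance = "parcels"), w3p)
  expect_error(node_coefficients(rnorm(5), 4), "expected 6")
})

test_that("diversity ANOVA matches base R and the two-group t-test", {
  set.seed(82)
  D <- 40
  X <- matrix(rnorm(D * 6), D, 6)
  div <- runif(D)
  res <- diversity_anova(X, div, n_groups = 4)
  g <- res$groups
  for (j in 1:6) {
    ref <- stats::oneway.test(X[, j] ~ factor(g), var.equal = TRUE)
    expect_equal(res$f[j], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p[j], ref$p.value, tolerance = 1e-10)
  }
  # two groups: F equals t^2
  res2 <- diversity_anova(X, div, n_groups = 2)
  tt <- stats::t.test(X[, 1] ~ factor(res2$groups), var.equal = TRUE)
  expect_equal(res2$f[1], unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("ANOVA flags a planted group shift and survives degeneracy", {
  set.seed(83)
  D <- 50
  X <- matrix(rnorm(D * 5), D, 5)
  div <- sort(runif(D))
  g <- divprop:::chunk_assign(D, 5)
  X[g == 5, 2] <- X[g == 5, 2] + 5           # 5 within-group SDs
  res <- diversity_anova(X, div, n_groups = 5)
  expect_lt(res$p[2], 1e-4)
  expect_gt(min(res$p[c(1, 3:5)]), 1e-4)
  # zero within-group variance: F infinite, p -> 0, no crash
  Xd <- matrix(c(1, 1, 2, 2), 4, 1)
  resd <- diversity_anova(Xd, c(0.1, 0.2, 0.8, 0.9), n_groups = 2)
  expect_true(is.infinite(resd$f[1]))
  expect_equal(resd$p[1], 0)
})

test_that("BFS components agree with igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(84)
  for (rep in 1:10) {
    P <- sample(5:15, 1)
    A <- matrix(rbinom(P * P, 1, 0.2), P, P)
    A <- A * upper.tri(A); A <- A + t(A)
    active <- as.logical(rbinom(P, 1, 0.7))
    nb <- divprop:::adjacency_to_neighbors(A, P)
    ours <- divprop:::components_bfs(nb, active)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    sub <- igraph::induced_subgraph(g, which(active))
    ref <- igraph::components(sub)
    expect_equal(length(ours), ref$no)
    sizes <- sort(vapply(ours, length, 1L))
    expect_equal(sizes, sort(unname(ref$csize)))
  }
})

test_that("TFCE enhancement behaves on simple graphs", {
  # chain graph, all-zero statistics stay zero
  adj <- cbind(1:4, 2:5)
  expect_equal(tfce_enhance(rep(0, 5), adj), rep(0, 5))
  # a large connected plateau is enhanced above an equal-height isolated peak
  stat <- c(2, 2, 2, 0, 2)
  enh <- tfce_enhance(stat, adj)
  expect_gt(enh[2], enh[5])
  expect_equal(enh[4], 0)
})

test_that("permutation TFCE detects a planted effect and respects nulls", {
  set.seed(85)
  D <- 60; P <- 12
  adj <- cbind(seq_len(P - 1), 2:P)
  div <- sort(runif(D))
  g <- divprop:::chunk_assign(D, 5)
  # strong planted effect on two adjacent nodes
  X <- matrix(rnorm(D * P), D, P)
  X[g == 5, 5:6] <- X[g == 5, 5:6] + 4
  res <- permutation_cluster_correct(X, g, adj, n_perm = 199, seed = 3,
                                     n_steps = 30)
  expect_lte(res$p_corrected[5], 0.05)
  expect_lte(res$p_corrected[6], 0.05)
  # all-null statistics: corrected p near 1
  X0 <- matrix(rnorm(20 * P), 20, P)
  res0 <- permutation_cluster_correct(X0 * 0, divprop:::chunk_assign(20, 4),
                                      adj, n_perm = 99, seed = 4,
                                      n_steps = 20)
  expect_true(all(res0$p_corrected >= 1 - 1 / 100))
  # degenerate single group
  expect_warning(res1 <- permutation_cluster_correct(X0, rep(1, 20), adj,
                                                     n_perm = 9, seed = 5))
  expect_true(all(res1$p_corrected == 1))
  # empty adjacency falls back to max-statistic correction
  expect_warning(
    res2 <- permutation_cluster_correct(X, g, NULL, n_perm = 99, seed = 6),
    "max-statistic")
  expect_lte(res2$p_corrected[5], 0.05)
})

test_that("network correlations recover a planted trend", {
  set.seed(86)
  D <- 252; P <- 20
  nets <- rep(c("dmn", "vis", "smn", "fpn"), each = 5)
  div <- sort(runif(D, 0.05, 0.4))
  X <- matrix(rnorm(D * P, sd = 0.5), D, P)
  X[, nets == "dmn"] <- X[, nets == "dmn"] + 6 * div   # planted linear trend
  r <- network_correlation(X, div, nets)
  expect_gt(r[["dmn"]], 0.8)
  expect_lt(max(abs(r[c("vis", "smn", "fpn")])), 0.2)
  # null coefficients: every network near zero on average over seeds
  worst0 <- sapply(1:5, function(s) {
    set.seed(s)
    max(abs(network_correlation(matrix(rnorm(D * P), D, P), div, nets)))
  })
  expect_lt(mean(worst0), 0.15)
  # two draws: degenerate |r| = 1 with warning
  expect_warning(r2 <- network_correlation(X[1:2, ], div[1:2], nets))
  expect_equal(abs(unname(r2)), rep(1, 4), tolerance = 1e-8)
})
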
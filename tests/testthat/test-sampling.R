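test_that("diversity indices match hand values and enumeration oracles", {
  expect_equal(wd_diversity(c(0.2, 0.4)), 0.2)
  expect_equal(wd_diversity(rep(0.3, 6)), 0)
  expect_equal(wd_diversity(c(0.1, 0.2, 0.7)), 0.4)
  expect_equal(ood_diversity(0.5, 0.5), 0)
  expect_equal(ood_diversity(c(0, 1), 0.5), 0.5)
  expect_equal(ood_diversity(c(0.1, 0.3), c(0.6, 0.9)), 0.55)
  set.seed(51)
  for (rep in 1:20) {
    s <- runif(sample(2:20, 1))
    expect_equal(wd_diversity(s), wd_oracle(s), tolerance = 1e-12)
    a <- runif(sample(1:20, 1)); b <- runif(sample(1:20, 1))
    expect_equal(ood_diversity(a, b), ood_oracle(a, b), tolerance = 1e-12)
    expect_equal(ood_diversity(a, b), ood_diversity(b, a))
  }
  expect_error(wd_diversity(0.4), "fewer than 2")
  expect_error(ood_diversity(numeric(), 0.5), "empty")
})

test_that("draw counts match closed forms and brute-force enumeration", {
  set.seed(52)
  st <- stratify(make_pairs(runif(40, 0.05, 0.95)), q = 10)
  expect_length(enumerate_draws(st, "all", r = 5), 252)
  # contiguous windows before augmentation: q - r + 1
  expect_length(enumerate_draws(st, "contiguous", r = 2, n_draws = 9), 9)
  for (q in 4:12) {
    stq <- stratify(make_pairs(runif(3 * q, 0.05, 0.95)), q = q)
    for (r in seq(2, q - 1, by = max(1, (q - 3) %/% 2))) {
      expect_length(enumerate_draws(stq, "all", r = r), choose(q, r))
      expect_length(enumerate_draws(stq, "contiguous", r = r,
                                    n_draws = q - r + 1), q - r + 1)
      dv <- enumerate_draws(stq, "diverse", r = r, n_draws = choose(q, r))
      expect_length(dv, count_nonrun_subsets(q, r))
    }
  }
})

test_that("nine-of-ten training sets with a gap count as diverse", {
  set.seed(53)
  st <- stratify(make_pairs(runif(30, 0.05, 0.95)), q = 10)
  dv <- enumerate_draws(st, "diverse", r = 9, n_draws = 100)
  # brute force over all C(10,9) = 10 subsets: only the two windows that
  # exclude a terminal stratum are unbroken runs
  expect_length(dv, count_nonrun_subsets(10, 9))
  expect_length(dv, 8)
})

test_that("diverse draws are ranked by non-increasing WD diversity", {
  set.seed(54)
  st <- stratify(make_pairs(runif(50, 0.05, 0.95)), q = 10)
  dv <- enumerate_draws(st, "diverse", r = 5, n_draws = 20)
  expect_length(dv, 20)
  wd <- vapply(dv, `[[`, numeric(1), "wd")
  expect_true(all(diff(wd) <= 1e-12))
  for (d in dv) expect_false(all(diff(sort(d$train_strata)) == 1))
  # top-ranked diverse draw beats every contiguous draw of the same size
  ct <- enumerate_draws(st, "contiguous", r = 5, n_draws = 6)
  expect_gt(wd[1], max(vapply(ct, `[[`, numeric(1), "wd")))
})

test_that("draws keep train and holdout disjoint and class balanced", {
  set.seed(55)
  st <- stratify(make_pairs(runif(40, 0.05, 0.95)), q = 10)
  for (scheme in c("all", "contiguous", "diverse", "random")) {
    dws <- enumerate_draws(st, scheme, r = 3, n_draws = 10, seed = 5)
    for (d in dws) {
      hold_rows <- setdiff(seq_len(nrow(st)), d$train_pairs)
      expect_length(intersect(d$train_pairs, hold_rows), 0)
      # pairs move as units: one case and one control per training pair
      expect_length(unique(st$case_id[d$train_pairs]), length(d$train_pairs))
      if (!is.null(d$train_strata)) {
        expect_setequal(d$holdout_strata,
                        setdiff(1:10, d$train_strata))
      }
    }
  }
})

test_that("random draws are reproducible bit-exactly under a seed", {
  set.seed(56)
  st <- stratify(make_pairs(runif(40, 0.05, 0.95)), q = 10)
  d1 <- enumerate_draws(st, "random", r = 4, n_draws = 8, seed = 99)
  d2 <- enumerate_draws(st, "random", r = 4, n_draws = 8, seed = 99)
  expect_identical(unclass(d1), unclass(d2))
})

test_that("contiguous augmentation adds deduplicated consecutive runs", {
  set.seed(57)
  st <- stratify(make_pairs(runif(40, 0.05, 0.95)), q = 10)
  dws <- enumerate_draws(st, "contiguous", r = 2, n_draws = 20)
  expect_gt(length(dws), 9)
  schemes <- vapply(dws, `[[`, character(1), "scheme")
  expect_equal(sum(schemes == "contiguous"), 9)
  extras <- dws[schemes == "consecutive-extra"]
  keysets <- lapply(dws, `[[`, "train_pairs")
  expect_equal(anyDuplicated(keysets), 0)
  for (e in extras) {
    expect_equal(e$train_pairs, seq(min(e$train_pairs), max(e$train_pairs)))
    expect_equal(length(e$train_pairs), round(nrow(st) * 2 / 10))
  }
})

test_that("out-of-range r is rejected", {
  set.seed(58)
  st <- stratify(make_pairs(runif(30, 0.1, 0.9)), q = 10)
  expect_error(enumerate_draws(st, "all", r = 1), "must lie")
  expect_error(enumerate_draws(st, "all", r = 10), "must lie")
})
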
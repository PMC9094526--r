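# Shared test fixtures and independent oracles. Everything is generated in
# code; oracles deliberately avoid the implementation paths they check.

# Small phenotype table builder.
make_pheno <- function(n, n_sites = 2, seed = 1, confounded = TRUE) {
  set.seed(seed)
  site <- sample(paste0("s", seq_len(n_sites)), n, replace = TRUE)
  age <- rnorm(n, 12 + 2 * as.integer(factor(site)), 3)
  sex <- rbinom(n, 1, 0.5)
  lin <- if (confounded) 0.5 * scale(age)[, 1] + 0.5 * sex else rep(0, n)
  diagnosis <- rbinom(n, 1, plogis(lin))
  data.frame(id = sprintf("p%03d", seq_len(n)), age = age, sex = sex,
             site = site, diagnosis = diagnosis, stringsAsFactors = FALSE)
}

# All permutations of a vector (for exhaustive assignment search).
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# Exhaustive minimum-cost assignment with forbidden-cost entries, mirroring
# the caliper protocol: minimize total cost (forbidden entries priced at
# `forbidden`), then report the retained (admissible) pairs and their cost.
brute_force_match <- function(cost, threshold, forbidden) {
  n <- nrow(cost)
  m <- ncol(cost)
  swap <- FALSE
  if (n > m) { cost <- t(cost); tmp <- n; n <- m; m <- tmp; swap <- TRUE }
  work <- cost
  work[cost > threshold] <- forbidden
  best_total <- Inf
  best_kept_cost <- NA_real_
  best_kept_n <- NA_integer_
  for (p in all_perms(seq_len(m))) {
    cols <- p[seq_len(n)]
    total <- sum(work[cbind(seq_len(n), cols)])
    if (total < best_total - 1e-12) {
      best_total <- total
      kept <- cost[cbind(seq_len(n), cols)] <= threshold
      best_kept_cost <- sum(cost[cbind(seq_len(n), cols)][kept])
      best_kept_n <- sum(kept)
    }
  }
  list(kept_cost = best_kept_cost, kept_n = best_kept_n)
}

# Pair-counting AUC oracle (ties count 1/2).
auc_pair_counting <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Double-loop diversity oracles.
wd_oracle <- function(s) {
  n <- length(s)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) tot <- tot + abs(s[i] - s[j])
  2 * tot / (n * (n - 1))
}
ood_oracle <- function(a, b) {
  tot <- 0
  for (x in a) for (y in b) tot <- tot + abs(x - y)
  tot / (length(a) * length(b))
}

# Build a synthetic matched_pairs/stratification object from raw pair-mean
# scores (for sampling/stratification tests that do not need real matching).
make_pairs <- function(pair_means, deltas = 0.01) {
  n <- length(pair_means)
  df <- data.frame(
    case_id = sprintf("c%03d", seq_len(n)),
    control_id = sprintf("t%03d", seq_len(n)),
    score_case = pair_means + deltas / 2,
    score_control = pair_means - deltas / 2,
    delta = rep(deltas, n), pair_mean = pair_means,
    stringsAsFactors = FALSE)
  class(df) <- c("matched_pairs", "data.frame")
  df
}

# Brute-force count of r-subsets of 1..q that do NOT form an unbroken run.
count_nonrun_subsets <- function(q, r) {
  sum(vapply(combn(q, r, simplify = FALSE),
             function(s) any(diff(sort(s)) != 1), logical(1)))
}
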
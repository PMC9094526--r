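# Train/holdout draw enumeration over strata, and the two diversity indices:
# within-distribution (WD) diversity of a participant set and
# out-of-distribution (OOD) diversity between a training set and a holdout
# stratum. Matched pairs are the sampling unit in every scheme, so all
# training and holdout sets stay exactly class balanced.

#' Within-distribution diversity of a set of propensity scores
#'
#' The average of all pairwise absolute differences:
#' \deqn{\frac{2}{N_t(N_t-1)} \sum_{i<j} |\pi_i - \pi_j|.}
#'
#' @param scores propensity scores (length >= 2).
#' @return diversity value in `[0, 1)`.
#' @export
wd_diversity <- function(scores) {
  if (length(scores) < 2) stop("WD diversity undefined for fewer than 2 scores")
  mean(dist(scores))
}

#' Out-of-distribution diversity between training and holdout scores
#'
#' The mean absolute propensity-score difference over all
#' \eqn{N_t \times N_s} cross pairs; symmetric in its arguments.
#'
#' @param train_scores,holdout_scores non-empty score vectors.
#' @return diversity value in `[0, 1)`.
#' @export
ood_diversity <- function(train_scores, holdout_scores) {
  if (!length(train_scores) || !length(holdout_scores)) {
    stop("OOD diversity undefined for empty score sets")
  }
  mean(abs(outer(train_scores, holdout_scores, "-")))
}

# TRUE when the sorted stratum indices form an unbroken run.
is_contiguous_set <- function(s) {
  s <- sort(s)
  all(diff(s) == 1L)
}

make_draw <- function(scheme, train_strata, train_pairs, holdout_strata, wd) {
  list(scheme = scheme, train_strata = train_strata,
       train_pairs = train_pairs, holdout_strata = holdout_strata, wd = wd)
}

#' Enumerate train/holdout draws under a sampling scheme
#'
#' Given a stratification into `q` score-ordered strata, builds draws that
#' use `r` strata (or the equivalent fraction of matched pairs) for training:
#'
#' * `"contiguous"`: all `q - r + 1` adjacent windows of strata. When fewer
#'   than `n_draws`, the list is augmented with `"consecutive-extra"` draws
#'   that train on runs of consecutive matched pairs (in score order) of the
#'   same training fraction, starting at evenly spaced offsets and
#'   deduplicated against existing draws.
#' * `"diverse"`: all `r`-subsets whose sorted indices do not form an
#'   unbroken run, ranked by decreasing WD diversity of the pooled training
#'   scores (ties keep lexicographic subset order) and truncated to `n_draws`.
#' * `"random"`: `n_draws` seeded samples of matched pairs at the training
#'   fraction `r/q`, irrespective of scores (pairs as units, so class
#'   proportions are preserved).
#' * `"all"`: every `r`-subset of strata (e.g. 252 for q = 10, r = 5).
#'
#' @param strat a `stratification` object.
#' @param scheme one of `"contiguous"`, `"diverse"`, `"random"`, `"all"`.
#' @param r number of training strata, `2 <= r <= q - 1`.
#' @param n_draws target number of draws for contiguous/diverse/random
#'   (default 20).
#' @param seed seed for the random scheme.
#' @return object of class `draw_set`: list of draws, each with `scheme`,
#'   `train_strata` (NULL for pair-level draws), `train_pairs` (row indices
#'   into `strat`), `holdout_strata`, `wd` (WD diversity of the training
#'   participants). Attributes `q`, `r`, `scheme`.
#' @export
enumerate_draws <- function(strat, scheme = c("contiguous", "diverse",
                                              "random", "all"),
                            r, n_draws = 20, seed = 1) {
  scheme <- match.arg(scheme)
  q <- attr(strat, "q")
  if (r < 2 || r > q - 1) stop(sprintf("r must lie in [2, %d]", q - 1))
  if (scheme == "all" && r != 5) {
    message("exhaustive enumeration with non-default r = ", r)
  }
  n_pairs <- nrow(strat)
  sc_list <- strata_scores(strat)
  pair_rows_of <- function(strata_set) which(strat$stratum %in% strata_set)
  wd_of_strata <- function(strata_set) {
    wd_diversity(unlist(sc_list[strata_set], use.names = FALSE))
  }

  draws <- list()
  if (scheme %in% c("contiguous", "diverse", "all")) {
    subsets <- switch(scheme,
      contiguous = lapply(seq_len(q - r + 1L), function(s) s:(s + r - 1L)),
      {
        all_sub <- combn(q, r, simplify = FALSE)
        if (scheme == "diverse") {
          Filter(function(s) !is_contiguous_set(s), all_sub)
        } else all_sub
      })
    draws <- lapply(subsets, function(s) {
      make_draw(if (scheme == "all") {
        if (is_contiguous_set(s)) "contiguous" else "diverse"
      } else scheme,
      s, pair_rows_of(s), setdiff(seq_len(q), s), wd_of_strata(s))
    })
    if (scheme == "diverse") {
      wd_vals <- vapply(draws, `[[`, numeric(1), "wd")
      draws <- draws[order(-wd_vals)]       # stable: ties keep subset order
      draws <- head(draws, n_draws)
    }
    if (scheme == "contiguous" && length(draws) < n_draws) {
      draws <- c(draws, consecutive_extra_draws(strat, r, q,
                                                n_draws - length(draws),
                                                existing = draws))
    }
  } else {                                  # random
    len <- max(2L, round(n_pairs * r / q))
    set.seed(seed)
    for (d in seq_len(n_draws)) {
      idx <- sort(sample.int(n_pairs, len))
      hold <- setdiff(seq_len(n_pairs), idx)
      draws[[d]] <- make_draw(
        "random", NULL, idx,
        sort(unique(strat$stratum[hold])),
        wd_diversity(c(strat$score_case[idx], strat$score_control[idx])))
    }
  }
  structure(draws, q = q, r = as.integer(r), scheme = scheme,
            class = "draw_set")
}

# Augmentation draws for the contiguous scheme: runs of consecutive matched
# pairs (score order) matching the r/q training fraction, window starts
# evenly spaced, deduplicated against existing draws.
consecutive_extra_draws <- function(strat, r, q, n_extra, existing) {
  n_pairs <- nrow(strat)
  len <- max(2L, round(n_pairs * r / q))
  if (len >= n_pairs) return(list())
  max_start <- n_pairs - len + 1L
  seen <- lapply(existing, function(d) d$train_pairs)
  n_cand <- min(max_start, max(n_extra * 3L, n_extra + 2L))
  starts <- unique(round(seq(1L, max_start, length.out = n_cand)))
  out <- list()
  for (s in starts) {
    if (length(out) >= n_extra) break
    idx <- s:(s + len - 1L)
    if (any(vapply(seen, function(e) identical(e, idx), logical(1)))) next
    seen[[length(seen) + 1L]] <- idx
    hold <- setdiff(seq_len(n_pairs), idx)
    out[[length(out) + 1L]] <- make_draw(
      "consecutive-extra", NULL, idx,
      sort(unique(strat$stratum[hold])),
      wd_diversity(c(strat$score_case[idx], strat$score_control[idx])))
  }
  out
}

#' @export
print.draw_set <- function(x, ...) {
  cat(sprintf("Draw set: %d draws (scheme %s, q = %d, r = %d)\n",
              length(x), attr(x, "scheme"), attr(x, "q"), attr(x, "r")))
  if (length(x)) {
    wd <- vapply(x, `[[`, numeric(1), "wd")
    cat(sprintf("  WD diversity: [%.4f, %.4f]\n", min(wd), max(wd)))
  }
  invisible(x)
}
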
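# Score-ordered stratification of matched pairs: pairs ranked by pair-mean
# propensity score and divided into q equally sized, mutually exclusive
# strata (remainder pairs go to the lowest-score strata).

#' Stratify matched pairs by pair-mean propensity score
#'
#' Pairs are sorted ascending by `pair_mean` (ties broken by `case_id` for
#' determinism) and chunked into `q` contiguous blocks with sizes as equal as
#' possible; any remainder is allocated to the lowest-index (lowest-score)
#' strata. Stratum 1 holds the lowest scores, stratum `q` the highest.
#'
#' @param pairs a `matched_pairs` data.frame (or any data.frame with
#'   `case_id`, `control_id`, `pair_mean`).
#' @param q number of strata (default 10).
#' @return data.frame of class `stratification`: the pairs sorted by
#'   `pair_mean` with an integer `stratum` column; attribute `q`.
#' @export
stratify <- function(pairs, q = 10) {
  if (q < 2) stop("q must be at least 2")
  n <- nrow(pairs)
  if (n < q) stop(sprintf("need at least q = %d pairs, got %d", q, n))
  ord <- order(pairs$pair_mean, pairs$case_id)
  out <- pairs[ord, , drop = FALSE]
  out$stratum <- chunk_assign(n, q)
  rownames(out) <- NULL
  attr(out, "q") <- as.integer(q)
  class(out) <- c("stratification", "data.frame")
  out
}

# Participant-level propensity scores per stratum (each pair contributes its
# case and control score).
strata_scores <- function(strat) {
  q <- attr(strat, "q")
  lapply(seq_len(q), function(s) {
    rows <- strat[strat$stratum == s, , drop = FALSE]
    c(rows$score_case, rows$score_control)
  })
}

#' @export
print.stratification <- function(x, ...) {
  q <- attr(x, "q")
  sizes <- as.vector(table(factor(x$stratum, levels = seq_len(q))))
  cat(sprintf("Stratification: %d pairs in %d strata (sizes %s)\n",
              nrow(x), q, paste(sizes, collapse = ",")))
  invisible(x)
}
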
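# Caliper-constrained optimal pair matching on propensity-score distance.
# Cases are paired one-to-one with controls by minimizing the total absolute
# score difference (globally optimal assignment); pair distances above the
# caliper threshold 0.2 * d_sd are made prohibitively expensive and any such
# pair surviving the assignment is discarded afterwards.

# Rectangular minimum-cost assignment: returns for each row of `cost` the
# assigned column (NA for rows absorbed by dummy padding). Padding with
# zero-cost dummies preserves optimality for the real rows/columns.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  k <- max(n, m)
  padded <- matrix(0, k, k)
  padded[seq_len(n), seq_len(m)] <- cost
  cols <- solve_lsap_cpp(padded)
  out <- cols[seq_len(n)]
  out[out > m] <- NA_integer_
  out
}

#' Optimal caliper-constrained matching of cases to controls
#'
#' Solves the rectangular linear assignment problem on the cost
#' `|pi_case - pi_control|`, after replacing every cost above the caliper
#' threshold with a large forbidden cost (10 x (max admissible cost + 1)).
#' The threshold is `caliper * d_sd`, where `d_sd` is the standard deviation
#' of pairwise absolute score differences -- by default over the case x
#' control pairs whose costs enter the assignment, optionally over all pairs
#' of participants. Assigned pairs whose distance still exceeds the threshold
#' are discarded.
#'
#' @param scores_case,scores_control propensity scores in (0, 1).
#' @param caliper caliper multiplier (default 0.2).
#' @param ids_case,ids_control optional participant ids.
#' @param d_sd_mode `"cross"` (default) computes `d_sd` over case-control
#'   pairs; `"all"` over all pairs of pooled participants.
#' @return data.frame of class `matched_pairs` with columns `case_id`,
#'   `control_id`, `score_case`, `score_control`, `delta` (absolute score
#'   difference), `pair_mean`; rows ordered by `pair_mean`. Attributes:
#'   `threshold`, `d_sd`, `forbidden_cost`, `caliper`. Zero admissible pairs
#'   yield an empty result with a warning.
#' @export
match_pairs <- function(scores_case, scores_control, caliper = 0.2,
                        ids_case = NULL, ids_control = NULL,
                        d_sd_mode = c("cross", "all")) {
  d_sd_mode <- match.arg(d_sd_mode)
  stopifnot(length(scores_case) >= 1, length(scores_control) >= 1)
  if (any(scores_case <= 0 | scores_case >= 1) ||
      any(scores_control <= 0 | scores_control >= 1)) {
    stop("propensity scores must lie strictly in (0, 1)")
  }
  if (is.null(ids_case)) ids_case <- paste0("case", seq_along(scores_case))
  if (is.null(ids_control)) ids_control <- paste0("ctrl", seq_along(scores_control))
  # deterministic input order
  oc <- order(ids_case)
  ot <- order(ids_control)
  scores_case <- scores_case[oc]; ids_case <- ids_case[oc]
  scores_control <- scores_control[ot]; ids_control <- ids_control[ot]

  cost <- abs(outer(scores_case, scores_control, "-"))
  d_sd <- if (d_sd_mode == "cross") {
    sd(as.vector(cost))
  } else {
    sd(dist(c(scores_case, scores_control)))
  }
  if (!is.finite(d_sd)) d_sd <- 0
  threshold <- caliper * d_sd

  empty <- data.frame(case_id = character(), control_id = character(),
                      score_case = numeric(), score_control = numeric(),
                      delta = numeric(), pair_mean = numeric(),
                      stringsAsFactors = FALSE)
  admissible <- cost <= threshold
  if (!any(admissible)) {
    warning("no admissible case-control pair within the caliper threshold")
    out <- empty
  } else {
    forbidden_cost <- 10 * (max(cost[admissible]) + 1)
    workcost <- cost
    workcost[!admissible] <- forbidden_cost
    assign_col <- solve_assignment(workcost)
    keep <- which(!is.na(assign_col) &
                    cost[cbind(seq_along(assign_col), assign_col)] <= threshold)
    out <- data.frame(
      case_id = ids_case[keep],
      control_id = ids_control[assign_col[keep]],
      score_case = scores_case[keep],
      score_control = scores_control[assign_col[keep]],
      stringsAsFactors = FALSE)
    out$delta <- abs(out$score_case - out$score_control)
    out$pair_mean <- (out$score_case + out$score_control) / 2
    out <- out[order(out$pair_mean, out$case_id), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "forbidden_cost") <- forbidden_cost
  }
  attr(out, "threshold") <- threshold
  attr(out, "d_sd") <- d_sd
  attr(out, "caliper") <- caliper
  class(out) <- c("matched_pairs", "data.frame")
  out
}

#' Standardized mean difference for a continuous covariate
#'
#' \eqn{d = |\bar x_1 - \bar x_0| / \sqrt{(s_1^2 + s_0^2)/2}}. Zero pooled
#' variance yields 0 when the means agree and `Inf` otherwise.
#'
#' @param x1,x0 covariate values in the two groups.
#' @return non-negative SMD.
#' @export
smd_continuous <- function(x1, x0) {
  num <- abs(mean(x1) - mean(x0))
  den <- sqrt((var(x1) + var(x0)) / 2)
  if (!is.finite(den) || den == 0) {
    return(if (num == 0) 0 else Inf)
  }
  num / den
}

#' Standardized mean difference for a binary covariate
#'
#' \eqn{d = |p_1 - p_0| / \sqrt{(p_1(1-p_1) + p_0(1-p_0))/2}} with group
#' prevalences \eqn{p_i}.
#'
#' @param p1,p0 prevalences in the two groups.
#' @return non-negative SMD.
#' @export
smd_binary <- function(p1, p0) {
  num <- abs(p1 - p0)
  den <- sqrt((p1 * (1 - p1) + p0 * (1 - p0)) / 2)
  if (den == 0) {
    return(if (num == 0) 0 else Inf)
  }
  num / den
}

#' Covariate balance diagnostics between diagnostic groups
#'
#' Computes the absolute SMD per covariate (age as continuous; sex and each
#' site indicator as binary) between cases and controls, optionally
#' restricted to a matched subset, and flags covariates at or above the
#' conventional 0.1 balance threshold.
#'
#' @param pheno phenotype data.frame (`id`, `age`, `sex`, `site`,
#'   `diagnosis`).
#' @param ids optional character vector of participant ids to restrict to
#'   (e.g. the matched participants); default uses everyone.
#' @param flag_threshold SMD above which a covariate is flagged (default 0.1).
#' @return data.frame of class `balance_report`: `covariate`, `type`,
#'   `mean_case`, `mean_control`, `smd`, `balanced`.
#' @export
balance_report <- function(pheno, ids = NULL, flag_threshold = 0.1) {
  if (!is.null(ids)) pheno <- pheno[pheno$id %in% ids, , drop = FALSE]
  y <- as.numeric(pheno$diagnosis)
  if (length(unique(y)) < 2) stop("both groups must be non-empty")
  design <- encode_covariates(pheno)
  X <- design$X
  age <- as.numeric(pheno$age)
  rows <- list(data.frame(
    covariate = "age", type = "continuous",
    mean_case = mean(age[y == 1]), mean_control = mean(age[y == 0]),
    smd = smd_continuous(age[y == 1], age[y == 0]),
    stringsAsFactors = FALSE))
  for (col in setdiff(colnames(X), "age_z")) {
    v <- X[, col]
    rows[[length(rows) + 1L]] <- data.frame(
      covariate = col, type = "binary",
      mean_case = mean(v[y == 1]), mean_control = mean(v[y == 0]),
      smd = smd_binary(mean(v[y == 1]), mean(v[y == 0])),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$balanced <- out$smd < flag_threshold
  rownames(out) <- NULL
  class(out) <- c("balance_report", "data.frame")
  out
}

#' Cross-validated predictive power of the covariates alone
#'
#' Audits whether age, sex and site still carry diagnostic information:
#' fits the covariate-only logistic model under k-fold cross-validation and
#' returns the pooled out-of-fold AUC. After adequate propensity matching
#' this should hover around chance. For matched data, supply `pair_ids` so
#' folds are drawn at the pair level: splitting the two members of a matched
#' pair across train and test folds lets the model fit the within-pair noise
#' contrasts and biases the CV estimate below chance.
#'
#' @param pheno phenotype data.frame with covariates and `diagnosis`.
#' @param folds number of CV folds (default 10).
#' @param seed fold assignment seed.
#' @param pair_ids optional pair identifier per row; members of a pair are
#'   always assigned to the same fold.
#' @return out-of-fold AUC.
#' @export
covariate_auc <- function(pheno, folds = 10, seed = 1, pair_ids = NULL) {
  y <- as.numeric(pheno$diagnosis)
  design <- encode_covariates(pheno)
  X <- design$X
  if (is.null(pair_ids)) {
    fold_id <- stratified_folds(y, folds, seed)
  } else {
    stopifnot(length(pair_ids) == nrow(X))
    set.seed(seed)
    up <- unique(pair_ids)
    pf <- sample(rep_len(seq_len(folds), length(up)))
    fold_id <- pf[match(pair_ids, up)]
  }
  probs <- numeric(length(y))
  for (k in seq_len(folds)) {
    hold <- fold_id == k
    if (length(unique(y[!hold])) < 2) next
    fit <- logistic_ridge_fit(X[!hold, , drop = FALSE], y[!hold], lambda = 1e-4)
    probs[hold] <- plogis(drop(X[hold, , drop = FALSE] %*% fit$w) + fit$b)
  }
  auc_score(y, probs)
}

#' @export
print.matched_pairs <- function(x, ...) {
  cat(sprintf("Matched pairs: %d (caliper threshold %.4f, d_sd %.4f)\n",
              nrow(x), attr(x, "threshold"), attr(x, "d_sd")))
  if (nrow(x)) {
    cat(sprintf("  |delta pi|: median %.4f, max %.4f\n",
                stats::median(x$delta), max(x$delta)))
  }
  invisible(x)
}
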
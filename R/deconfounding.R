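# Removal of covariate effects from the feature matrix, either by per-feature
# linear residualization or by two-step harmonization: (1) empirical-Bayes
# location-scale removal of site effects while protecting age/sex variation
# (the parametric ComBat model), then (2) linear residualization of age and
# sex. All transforms store their parameters so the identical adjustment can
# be applied to new rows (enabling a leakage-safe train-only mode).

#' Residualize features on a confound design
#'
#' Per feature, ordinary least squares of the feature on the confounds (with
#' intercept); returns residuals re-centered at the grand mean. Collinear
#' confound columns are dropped with a warning. The stored coefficients and
#' confound means reproduce the identical transform on new rows.
#'
#' @param X numeric N x F feature matrix.
#' @param confounds numeric N x c confound design (no intercept column).
#' @return list with `adjusted` (N x F matrix) and `model` (class
#'   `deconfound_model`, method `"linreg"`).
#' @export
residualize <- function(X, confounds) {
  X <- as.matrix(X)
  C <- as.matrix(confounds)
  if (is.null(colnames(C))) colnames(C) <- paste0("c", seq_len(ncol(C)))
  if (nrow(X) <= ncol(C)) {
    stop("need more participants than confound columns")
  }
  qrC <- qr(cbind(1, C))
  if (qrC$rank < ncol(C) + 1) {
    keep_full <- qrC$pivot[seq_len(qrC$rank)]
    keep <- sort(setdiff(keep_full, 1L)) - 1L
    warning("dropping ", ncol(C) - length(keep),
            " collinear confound column(s)")
    C <- C[, keep, drop = FALSE]
  }
  cmeans <- colMeans(C)
  Cc <- sweep(C, 2, cmeans)
  B <- qr.coef(qr(Cc), X)                   # c x F slopes, no intercept needed
  B[is.na(B)] <- 0
  adjusted <- X - Cc %*% B
  dimnames(adjusted) <- dimnames(X)
  model <- structure(list(method = "linreg", coefficients = B,
                          confound_means = cmeans,
                          confound_names = colnames(C)),
                     class = "deconfound_model")
  list(adjusted = adjusted, model = model)
}

# Parametric empirical-Bayes location-scale harmonization of site effects.
# dat: F x N (features x participants); mod: N x p covariates to protect.
combat_fit <- function(dat, batch, mod = NULL, conv = 1e-4, maxit = 200) {
  batch <- as.factor(batch)
  K <- nlevels(batch)
  N <- ncol(dat)
  n_b <- as.vector(table(batch))
  if (any(n_b < 2)) {
    stop("site(s) with a single participant: ",
         paste(levels(batch)[n_b < 2], collapse = ", "))
  }
  batchmod <- model.matrix(~ -1 + batch)
  design <- if (is.null(mod)) batchmod else cbind(batchmod, mod)

  const <- apply(dat, 1, var) == 0
  if (any(const)) {
    warning(sum(const), " constant feature(s) skipped by harmonization")
  }
  work <- dat[!const, , drop = FALSE]
  Fh <- nrow(work)

  B_hat <- solve(crossprod(design), crossprod(design, t(work)))  # (K+p) x Fh
  grand_mean <- drop(crossprod(n_b / N, B_hat[seq_len(K), , drop = FALSE]))
  resid <- work - t(design %*% B_hat)
  var_pooled <- rowMeans(resid^2)
  var_pooled[var_pooled <= 0] <- .Machine$double.eps

  stand_mean <- matrix(grand_mean, Fh, N)
  if (!is.null(mod)) {
    tmp <- design
    tmp[, seq_len(K)] <- 0
    stand_mean <- stand_mean + t(tmp %*% B_hat)
  }
  s_data <- (work - stand_mean) / sqrt(var_pooled)

  gamma_star <- delta_star <- matrix(NA_real_, K, Fh)
  for (i in seq_len(K)) {
    sel <- batch == levels(batch)[i]
    sb <- s_data[, sel, drop = FALSE]
    g_hat <- rowMeans(sb)
    d_hat <- apply(sb, 1, var)
    g_bar <- mean(g_hat)
    t2 <- var(g_hat)
    m <- mean(d_hat); s2 <- var(d_hat)
    n <- sum(sel)
    g_old <- g_hat
    d_old <- d_hat
    if (!is.finite(t2) || t2 <= 0 || !is.finite(s2) || s2 <= 0) {
      # hyperpriors undefined (e.g. a single feature): no shrinkage
      gamma_star[i, ] <- g_hat
      delta_star[i, ] <- d_hat
      next
    }
    a_prior <- (2 * s2 + m^2) / s2
    b_prior <- (m * s2 + m^3) / s2
    for (it in seq_len(maxit)) {
      g_new <- (t2 * n * g_hat + d_old * g_bar) / (t2 * n + d_old)
      sum2 <- rowSums((sb - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior) / (n / 2 + a_prior - 1)
      change <- max(abs(g_new - g_old) / abs(g_old),
                    abs(d_new - d_old) / d_old)
      g_old <- g_new
      d_old <- d_new
      if (is.finite(change) && change < conv) break
    }
    gamma_star[i, ] <- g_old
    delta_star[i, ] <- d_old
  }
  p <- ncol(design) - K
  list(site_levels = levels(batch), const = const,
       grand_mean = grand_mean, var_pooled = var_pooled,
       cov_coef = if (p > 0) B_hat[K + seq_len(p), , drop = FALSE] else NULL,
       gamma_star = gamma_star, delta_star = delta_star)
}

combat_apply <- function(par, dat, batch, mod = NULL) {
  batch <- as.character(batch)
  unseen <- setdiff(batch, par$site_levels)
  if (length(unseen)) stop("unseen site at harmonization time: ",
                           paste(unseen, collapse = ", "))
  out <- dat
  work <- dat[!par$const, , drop = FALSE]
  N <- ncol(work)
  Fh <- nrow(work)
  stand_mean <- matrix(par$grand_mean, Fh, N)
  if (!is.null(par$cov_coef)) {
    stand_mean <- stand_mean + t(as.matrix(mod) %*% par$cov_coef)
  }
  s_data <- (work - stand_mean) / sqrt(par$var_pooled)
  for (i in seq_along(par$site_levels)) {
    sel <- batch == par$site_levels[i]
    if (!any(sel)) next
    s_data[, sel] <- (s_data[, sel, drop = FALSE] - par$gamma_star[i, ]) /
      sqrt(par$delta_star[i, ])
  }
  out[!par$const, ] <- s_data * sqrt(par$var_pooled) + stand_mean
  out
}

#' Two-step ComBat-style harmonization of site effects
#'
#' Step 1 fits the per-feature location-scale site-effect model with
#' parametric empirical-Bayes shrinkage of the per-site parameters, while
#' protecting the preserved covariates (age, sex) by including them in the
#' standardization design. Step 2 residualizes the harmonized features on
#' the preserved covariates. Constant features pass through unchanged with a
#' warning; a site with a single participant is an error naming the site.
#'
#' @param X numeric N x F feature matrix.
#' @param site site labels (length N).
#' @param preserve numeric N x p design of covariates whose variation must
#'   survive step 1 and be removed in step 2 (typically standardized age and
#'   binary sex).
#' @param two_step apply the step-2 residualization (default TRUE).
#' @return list with `adjusted` (N x F) and `model` (class
#'   `deconfound_model`, method `"combat"`) holding all per-site location and
#'   scale parameters and the step-2 regression, sufficient to transform new
#'   rows from known sites.
#' @export
combat_adjust <- function(X, site, preserve, two_step = TRUE) {
  X <- as.matrix(X)
  preserve <- as.matrix(preserve)
  par <- combat_fit(t(X), site, mod = preserve)
  harmonized <- t(combat_apply(par, t(X), site, mod = preserve))
  dimnames(harmonized) <- dimnames(X)
  step2 <- NULL
  adjusted <- harmonized
  if (two_step) {
    res <- residualize(harmonized, preserve)
    adjusted <- res$adjusted
    step2 <- res$model
  }
  model <- structure(list(method = "combat", combat = par, step2 = step2),
                     class = "deconfound_model")
  list(adjusted = adjusted, model = model)
}

# Confound design used by the deconfounding front end. Site enters with K-1
# indicator columns (first level as reference) so the centered design stays
# full rank; age is standardized, sex binary.
confound_design <- function(pheno, include_site = TRUE, meta = NULL) {
  design <- encode_covariates(pheno, meta = meta)
  X <- design$X
  cols <- c("age_z", "sex")
  if (include_site) {
    site_cols <- grep("^site_", colnames(X), value = TRUE)
    if (length(site_cols) > 1) cols <- c(cols, site_cols[-1])
  }
  list(X = X[, cols, drop = FALSE], meta = design$meta)
}

#' Deconfound a feature matrix against age, sex and site
#'
#' Front end dispatching to the supported methods: `"raw"` (identity),
#' `"linreg"` (per-feature linear residualization on age, sex and site
#' indicators), or `"combat"` (two-step harmonization: empirical-Bayes
#' site-effect removal preserving age/sex, then residualization of age/sex).
#'
#' @param X numeric N x F feature matrix, rows aligned with `pheno`.
#' @param pheno phenotype data.frame (`id`, `age`, `sex`, `site`).
#' @param method `"raw"`, `"linreg"` or `"combat"`.
#' @param meta optional covariate-encoding metadata (from
#'   [encode_covariates()]); supply the cohort-level encoding when fitting on
#'   a subset whose rows may not span every site level.
#' @return list with `adjusted` and `model` (a `deconfound_model`; for
#'   `"raw"` an identity model).
#' @export
deconfound <- function(X, pheno, method = c("raw", "linreg", "combat"),
                       meta = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (method == "raw") {
    return(list(adjusted = X,
                model = structure(list(method = "raw"),
                                  class = "deconfound_model")))
  }
  if (method == "linreg") {
    cd <- confound_design(pheno, include_site = TRUE, meta = meta)
    out <- residualize(X, cd$X)
    out$model$meta <- cd$meta
    out$model$include_site <- TRUE
    return(out)
  }
  cd <- confound_design(pheno, include_site = FALSE, meta = meta)
  out <- combat_adjust(X, as.character(pheno$site), cd$X)
  out$model$meta <- cd$meta
  out
}

#' Apply a stored deconfounding transform to new rows
#'
#' @param model a `deconfound_model` from [deconfound()], [residualize()] or
#'   [combat_adjust()].
#' @param X new feature rows (N' x F).
#' @param pheno phenotype rows aligned with `X` (required except for raw and
#'   bare residualization models built from an explicit design).
#' @param confounds explicit confound design for bare `"linreg"` models that
#'   were fitted via [residualize()] directly.
#' @return adjusted feature matrix.
#' @export
apply_deconfound <- function(model, X, pheno = NULL, confounds = NULL) {
  X <- as.matrix(X)
  if (model$method == "raw") return(X)
  if (model$method == "linreg") {
    C <- if (!is.null(confounds)) {
      Cn <- as.matrix(confounds)
      if (is.null(colnames(Cn))) colnames(Cn) <- paste0("c", seq_len(ncol(Cn)))
      Cn[, model$confound_names, drop = FALSE]
    } else {
      confound_design(pheno, include_site = isTRUE(model$include_site),
                      meta = model$meta)$X[, model$confound_names, drop = FALSE]
    }
    Cc <- sweep(C, 2, model$confound_means)
    return(X - Cc %*% model$coefficients)
  }
  # combat
  cd <- confound_design(pheno, include_site = FALSE, meta = model$meta)
  harmonized <- t(combat_apply(model$combat, t(X), as.character(pheno$site),
                               mod = cd$X))
  dimnames(harmonized) <- dimnames(X)
  if (is.null(model$step2)) return(harmonized)
  apply_deconfound(model$step2, harmonized, confounds = cd$X)
}

#' @export
print.deconfound_model <- function(x, ...) {
  cat("Deconfounding model, method:", x$method, "\n")
  invisible(x)
}
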
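# Stability of extracted predictive patterns under training-set diversity:
# pairwise consistency of the weight vectors across draws, per-region one-way
# ANOVA over diversity groups with permutation-based threshold-free cluster
# enhancement (TFCE) on the parcel adjacency graph, and network-level
# correlations between aggregated coefficients and diversity.

#' Pairwise consistency matrix of model coefficients
#'
#' Entry (a, b) is the Pearson correlation of the weight vectors of draws a
#' and b; rows/columns are ordered by ascending WD diversity of the training
#' sets. Zero-variance weight vectors yield `NA` entries (diagonal stays 1).
#'
#' @param weights D x F matrix of fitted weights, one row per draw.
#' @param diversity WD diversity per draw (length D).
#' @return D x D symmetric matrix with unit diagonal, ordered by diversity;
#'   attribute `diversity` carries the sorted values.
#' @export
consistency_matrix <- function(weights, diversity) {
  weights <- as.matrix(weights)
  if (nrow(weights) < 2) stop("need at least 2 draws")
  stopifnot(length(diversity) == nrow(weights), all(is.finite(diversity)))
  ord <- order(diversity)
  W <- weights[ord, , drop = FALSE]
  cm <- suppressWarnings(cor(t(W)))
  diag(cm) <- 1
  attr(cm, "diversity") <- diversity[ord]
  cm
}

#' Node-level coefficients from edge-level weights
#'
#' Maps connectivity weights back to parcels. `mode = "all"` averages the
#' P - 1 incident edges per node; `mode = "signed"` averages separately over
#' incident edges with positive and with negative coefficients (a node with
#' no edge of a sign reports `NA` for that sign). Thickness-modality weights
#' (already per parcel) pass through unchanged.
#'
#' @param weights edge weight vector of length P(P-1)/2, or a D x P(P-1)/2
#'   matrix (one row per draw). Length-P inputs are returned as-is.
#' @param n_parcels number of parcels P.
#' @param mode `"all"` or `"signed"`.
#' @param provenance `"auto"` resolves edge vs parcel weights from the input
#'   length; at P = 3 (where P = P(P-1)/2) auto prefers edges, so thickness
#'   users should say `"parcels"` explicitly.
#' @return for `"all"`: vector of length P (or D x P matrix); for
#'   `"signed"`: list with `positive` and `negative` of the same shape.
#' @export
node_coefficients <- function(weights, n_parcels,
                              mode = c("all", "signed"),
                              provenance = c("auto", "edges", "parcels")) {
  mode <- match.arg(mode)
  provenance <- match.arg(provenance)
  one_row <- is.null(dim(weights))
  W <- if (one_row) matrix(weights, nrow = 1) else as.matrix(weights)
  n_edges <- n_parcels * (n_parcels - 1) / 2
  if (provenance == "auto") {
    provenance <- if (ncol(W) == n_edges) "edges" else "parcels"
  }
  if (provenance == "parcels" && ncol(W) == n_parcels) {
    if (mode == "signed") {
      pos <- W; pos[W <= 0] <- NA_real_
      neg <- W; neg[W >= 0] <- NA_real_
      return(if (one_row) list(positive = drop(pos), negative = drop(neg))
             else list(positive = pos, negative = neg))
    }
    return(if (one_row) drop(W) else W)
  }
  if (ncol(W) != n_edges) {
    stop(sprintf("expected %d edge weights for %d parcels, got %d",
                 n_edges, n_parcels, ncol(W)))
  }
  ep <- edge_pairs(n_parcels)
  incident <- lapply(seq_len(n_parcels), function(k) which(ep$i == k | ep$j == k))
  agg <- function(keep_sign = NULL) {
    out <- matrix(NA_real_, nrow(W), n_parcels)
    for (k in seq_len(n_parcels)) {
      sub <- W[, incident[[k]], drop = FALSE]
      if (!is.null(keep_sign)) {
        sub[sign(sub) != keep_sign] <- NA_real_
      }
      out[, k] <- rowMeans(sub, na.rm = !is.null(keep_sign))
    }
    out[is.nan(out)] <- NA_real_
    out
  }
  if (mode == "all") {
    out <- agg()
    return(if (one_row) drop(out) else out)
  }
  pos <- agg(1)
  neg <- agg(-1)
  if (one_row) list(positive = drop(pos), negative = drop(neg))
  else list(positive = pos, negative = neg)
}

# Normalize an adjacency specification (P x P 0/1 matrix or 2-column edge
# data.frame/matrix of node indices) into a neighbor list.
adjacency_to_neighbors <- function(adjacency, n_nodes) {
  if (is.null(adjacency)) return(NULL)
  nb <- vector("list", n_nodes)
  if (is.data.frame(adjacency)) adjacency <- as.matrix(adjacency)
  if (is.matrix(adjacency) && nrow(adjacency) == n_nodes &&
      ncol(adjacency) == n_nodes) {
    for (k in seq_len(n_nodes)) nb[[k]] <- which(adjacency[k, ] != 0 &
                                                   seq_len(n_nodes) != k)
  } else if (is.matrix(adjacency) && ncol(adjacency) == 2) {
    if (nrow(adjacency) == 0) return(lapply(seq_len(n_nodes), function(k) integer()))
    if (max(adjacency) > n_nodes || min(adjacency) < 1) {
      stop("adjacency refers to nodes outside 1..", n_nodes)
    }
    for (k in seq_len(n_nodes)) nb[[k]] <- integer()
    for (e in seq_len(nrow(adjacency))) {
      a <- adjacency[e, 1]; b <- adjacency[e, 2]
      if (a == b) next
      nb[[a]] <- c(nb[[a]], b)
      nb[[b]] <- c(nb[[b]], a)
    }
    nb <- lapply(nb, function(v) sort(unique(v)))
  } else {
    stop("adjacency must be a P x P matrix or a 2-column edge list")
  }
  nb
}

# Connected components restricted to `active` nodes, by breadth-first search
# over the neighbor list. Returns a list of integer vectors.
components_bfs <- function(neighbors, active) {
  seen <- logical(length(neighbors))
  seen[!active] <- TRUE
  comps <- list()
  for (s in which(active)) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    members <- integer()
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      members <- c(members, v)
      for (u in neighbors[[v]]) {
        if (!seen[u]) { seen[u] <- TRUE; queue <- c(queue, u) }
      }
    }
    comps[[length(comps) + 1L]] <- members
  }
  comps
}

#' Threshold-free cluster enhancement of node statistics
#'
#' Integrates cluster extent and height over thresholds on the adjacency
#' graph: for thresholds h = dh, 2dh, ..., max(stat) (dh = max(stat) /
#' `n_steps`), every node in a suprathreshold connected component of size e
#' accumulates `e^E * h^H * dh`.
#'
#' @param stat non-negative node statistics (length P).
#' @param adjacency P x P matrix or 2-column edge list.
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param n_steps number of integration steps (default 100).
#' @return enhanced statistic per node.
#' @export
tfce_enhance <- function(stat, adjacency, E = 0.5, H = 2, n_steps = 100) {
  P <- length(stat)
  stopifnot(all(is.finite(stat)))
  neighbors <- adjacency_to_neighbors(adjacency, P)
  enh <- numeric(P)
  mx <- max(stat)
  if (mx <= 0) return(enh)
  dh <- mx / n_steps
  for (h in seq(dh, mx, by = dh)) {
    active <- stat >= h
    if (!any(active)) break
    for (comp in components_bfs(neighbors, active)) {
      enh[comp] <- enh[comp] + length(comp)^E * h^H * dh
    }
  }
  enh
}

#' Per-region one-way ANOVA of coefficients over diversity groups
#'
#' Draws are sorted by WD diversity and chunked into `n_groups` near-equal
#' blocks (very low to very high diversity); each region's coefficients are
#' then submitted to a classical one-way ANOVA across the groups.
#'
#' @param node_values D x P matrix of per-draw node coefficients.
#' @param diversity WD diversity per draw.
#' @param n_groups number of diversity groups (default 5).
#' @return list with `f`, `p` (per region), `groups` (group index per draw,
#'   in the input draw order), `df1`, `df2`.
#' @export
diversity_anova <- function(node_values, diversity, n_groups = 5) {
  node_values <- as.matrix(node_values)
  D <- nrow(node_values)
  if (D < n_groups) stop("need at least as many draws as groups")
  ord <- order(diversity)
  groups <- integer(D)
  groups[ord] <- chunk_assign(D, n_groups)
  res <- oneway_f(node_values, groups)
  list(f = res$f, p = res$p, groups = groups, df1 = res$df1, df2 = res$df2)
}

#' Permutation TFCE correction for diversity effects on node coefficients
#'
#' Enhances each node's one-way ANOVA F statistic with TFCE on the parcel
#' adjacency graph and corrects family-wise across nodes with the maximum
#' null enhanced statistic over seeded permutations of the draws' diversity
#' group labels. With an empty adjacency the correction falls back to the
#' maximum-statistic method on the raw F values (with a warning).
#'
#' @param node_values D x P matrix of per-draw node coefficients.
#' @param groups diversity group label per draw (e.g. from
#'   [diversity_anova()]).
#' @param adjacency P x P matrix or 2-column edge list (may have no edges).
#' @param n_perm number of permutations (default 1000).
#' @param seed permutation seed.
#' @param E,H,n_steps TFCE parameters (defaults 0.5, 2, 100).
#' @return list with `stat` (observed F), `enhanced`, `p_corrected` (in
#'   `[1/(n_perm+1), 1]`), `n_perm`.
#' @export
permutation_cluster_correct <- function(node_values, groups, adjacency,
                                        n_perm = 1000, seed = 1,
                                        E = 0.5, H = 2, n_steps = 100) {
  node_values <- as.matrix(node_values)
  P <- ncol(node_values)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) {
    warning("single diversity group: corrected p-values are all 1")
    return(list(stat = rep(0, P), enhanced = rep(0, P),
                p_corrected = rep(1, P), n_perm = n_perm))
  }
  no_edges <- is.null(adjacency) ||
    (is.matrix(adjacency) || is.data.frame(adjacency)) &&
    (NROW(adjacency) == 0 || all(as.matrix(adjacency) == 0))
  if (no_edges) {
    warning("empty adjacency: falling back to max-statistic correction")
    enhance <- function(f) f
  } else {
    enhance <- function(f) tfce_enhance(f, adjacency, E = E, H = H,
                                        n_steps = n_steps)
  }
  obs_f <- oneway_f(node_values, groups)$f
  obs_f[!is.finite(obs_f)] <- max(obs_f[is.finite(obs_f)], 1) * 1e6
  obs_e <- enhance(obs_f)
  set.seed(seed)
  null_max <- numeric(n_perm)
  g <- as.integer(groups)
  for (b in seq_len(n_perm)) {
    f_b <- oneway_f(node_values, g[sample.int(length(g))])$f
    f_b[!is.finite(f_b)] <- max(f_b[is.finite(f_b)], 1) * 1e6
    null_max[b] <- max(enhance(f_b))
  }
  p_corr <- vapply(obs_e, function(e) (1 + sum(null_max >= e)) / (n_perm + 1),
                   numeric(1))
  list(stat = obs_f, enhanced = obs_e, p_corrected = p_corr, n_perm = n_perm)
}

#' Network-level correlation of aggregated coefficients with diversity
#'
#' Per draw, node coefficients are averaged within each network; the D
#' network values are then correlated (Pearson) with the D WD diversity
#' values.
#'
#' @param node_values D x P matrix of per-draw node coefficients.
#' @param diversity WD diversity per draw.
#' @param network_map character/factor of length P assigning every parcel to
#'   one named network.
#' @return named numeric vector of correlations, one per network (`NA` for a
#'   network with no parcels).
#' @export
network_correlation <- function(node_values, diversity, network_map) {
  node_values <- as.matrix(node_values)
  stopifnot(length(network_map) == ncol(node_values),
            length(diversity) == nrow(node_values))
  if (nrow(node_values) == 2) {
    warning("only 2 draws: two-point correlations are degenerate (|r| = 1)")
  }
  networks <- sort(unique(as.character(network_map)))
  out <- vapply(networks, function(nw) {
    cols <- which(as.character(network_map) == nw)
    if (!length(cols)) return(NA_real_)
    agg <- rowMeans(node_values[, cols, drop = FALSE], na.rm = TRUE)
    suppressWarnings(cor(agg, diversity))
  }, numeric(1))
  stats::setNames(out, networks)
}
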
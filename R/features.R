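# Feature construction from parcel-level inputs. Connectivity fingerprints
# are the strict upper triangle of the per-participant Pearson correlation
# matrix between parcel time series; thickness fingerprints are per-parcel
# mean values. The flattening order is fixed (row-major over i < j) and
# round-trips through edge_pairs()/edge_index().

#' Edge provenance for a P-parcel connectivity feature vector
#'
#' Enumerates the strict upper triangle of a P x P matrix in row-major order:
#' (1,2), (1,3), ..., (1,P), (2,3), ... This fixed order defines the feature
#' layout used everywhere in the package.
#'
#' @param n_parcels number of parcels P (>= 2).
#' @return data.frame with integer columns `i`, `j` (i < j), one row per edge.
#' @export
edge_pairs <- function(n_parcels) {
  stopifnot(n_parcels >= 2)
  i <- rep.int(seq_len(n_parcels - 1L), times = (n_parcels - 1L):1L)
  j <- unlist(lapply(seq_len(n_parcels - 1L), function(a) (a + 1L):n_parcels),
              use.names = FALSE)
  data.frame(i = i, j = as.integer(j))
}

#' Flat feature index of edge (i, j)
#'
#' Inverse of [edge_pairs()]: maps a parcel pair (i < j) to its position in
#' the row-major upper-triangle feature vector.
#'
#' @param i,j parcel indices with `i < j`.
#' @param n_parcels number of parcels P.
#' @return integer flat index in `1..P(P-1)/2`.
#' @export
edge_index <- function(i, j, n_parcels) {
  stopifnot(all(i >= 1), all(j <= n_parcels), all(i < j))
  as.integer((i - 1) * n_parcels - i * (i - 1) / 2 + (j - i))
}

# Row-major upper triangle of a square matrix as a vector.
upper_tri_rowmajor <- function(m) {
  t(m)[lower.tri(m)]
}

#' Build the participant x feature matrix from parcel-level data
#'
#' For `modality = "connectivity"`, each participant contributes the strict
#' upper triangle (row-major, i < j) of the P x P Pearson correlation matrix
#' of their parcel time series, giving F = P(P-1)/2 features. For
#' `modality = "thickness"`, each participant contributes the P per-parcel
#' mean values (inputs may already be per-parcel means).
#'
#' @param x for connectivity, a list of T x P time-series matrices (one per
#'   participant, T >= 3); for thickness, a list of length-P vectors, a list
#'   of vertex-value matrices with columns as parcels, or an N x P matrix of
#'   per-parcel means.
#' @param modality `"connectivity"` or `"thickness"`.
#' @param participant_ids optional character ids; defaults to names of `x` or
#'   `sub1..subN`.
#' @return numeric N x F matrix with participant ids as row names, feature
#'   labels (`"e<i>_<j>"` or `"p<k>"`) as column names, and attributes
#'   `modality`, `n_parcels`.
#' @export
build_features <- function(x, modality = c("connectivity", "thickness"),
                           participant_ids = NULL) {
  modality <- match.arg(modality)
  if (is.matrix(x) && modality == "thickness") {
    x <- lapply(seq_len(nrow(x)), function(r) x[r, ])
  }
  stopifnot(is.list(x), length(x) >= 1)
  if (is.null(participant_ids)) {
    participant_ids <- names(x)
    if (is.null(participant_ids)) {
      participant_ids <- paste0("sub", seq_along(x))
    }
  }
  stopifnot(length(participant_ids) == length(x))

  if (modality == "connectivity") {
    P <- ncol(as.matrix(x[[1]]))
    if (P < 2) stop("need at least 2 parcels")
    ep <- edge_pairs(P)
    rows <- lapply(seq_along(x), function(s) {
      ts <- as.matrix(x[[s]])
      if (ncol(ts) != P) {
        stop(sprintf("participant '%s' has %d parcels, expected %d",
                     participant_ids[s], ncol(ts), P))
      }
      if (nrow(ts) < 3) stop("connectivity mode requires time series with T >= 3")
      if (!all(is.finite(ts))) {
        stop(sprintf("non-finite time-series values for participant '%s'",
                     participant_ids[s]))
      }
      sds <- apply(ts, 2, sd)
      if (any(sds == 0)) {
        stop(sprintf(
          "correlation undefined: zero-variance time series in parcel(s) %s for participant '%s'",
          paste(which(sds == 0), collapse = ", "), participant_ids[s]))
      }
      upper_tri_rowmajor(cor(ts))
    })
    out <- do.call(rbind, rows)
    colnames(out) <- paste0("e", ep$i, "_", ep$j)
  } else {
    vals <- lapply(seq_along(x), function(s) {
      v <- x[[s]]
      if (is.matrix(v)) v <- colMeans(v)   # per-vertex values by parcel column
      as.numeric(v)
    })
    P <- length(vals[[1]])
    if (P < 2) stop("need at least 2 parcels")
    bad <- which(vapply(vals, length, 1L) != P)
    if (length(bad)) {
      stop(sprintf("participant '%s' has %d parcels, expected %d",
                   participant_ids[bad[1]], length(vals[[bad[1]]]), P))
    }
    out <- do.call(rbind, vals)
    if (!all(is.finite(out))) stop("non-finite thickness values")
    colnames(out) <- paste0("p", seq_len(P))
  }
  rownames(out) <- participant_ids
  attr(out, "modality") <- modality
  attr(out, "n_parcels") <- as.integer(P)
  out
}

#' Read a participant x feature table from delimited text
#'
#' Expects a header row of feature labels and a first column of participant
#' ids.
#'
#' @param path file path (CSV).
#' @return numeric matrix with participant ids as row names.
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write a participant x feature table to delimited text
#'
#' @param x numeric matrix with participant ids as row names.
#' @param path output file path (CSV).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
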
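validity_index_names <- c("silhouette", "davies_bouldin",
                          "calinski_harabasz", "sym_between_within")

feature_cols <- function(X) {
  setdiff(names(X)[vapply(X, is.numeric, TRUE)], c("n_markers"))
}

#' Standardize a feature table
#'
#' Centers every numeric feature column to zero mean and scales it to unit
#' sample standard deviation. Rows containing non-finite feature values
#' (e.g. flagged-undefined descriptors of degenerate traces) are dropped
#' with a message; constant columns are mapped to zero with a warning.
#' Mixed feature units (voxels, radians, bits) make raw Euclidean
#' distances meaningless, so clustering is run on standardized features by
#' default.
#'
#' @param X tibble of features; non-numeric columns (e.g. `trace_id`) pass
#'   through untouched.
#' @return The standardized tibble; dropped-row count in attribute
#'   `n_dropped`.
#' @export
standardize_features <- function(X) {
  X <- tibble::as_tibble(X)
  cols <- feature_cols(X)
  if (length(cols) == 0) stop("no numeric feature columns found", call. = FALSE)
  ok <- rowSums(!is.finite(as.matrix(X[, cols]))) == 0
  if (sum(ok) < 2) stop("fewer than 2 usable rows after dropping non-finite values",
                        call. = FALSE)
  if (any(!ok)) {
    message(sprintf("dropping %d row(s) with non-finite feature values",
                    sum(!ok)))
  }
  X <- X[ok, ]
  for (cc in cols) {
    v <- X[[cc]]
    s <- stats::sd(v)
    if (s == 0) {
      warning(sprintf("feature '%s' is constant; standardized to zero", cc))
      X[[cc]] <- rep(0, length(v))
    } else {
      X[[cc]] <- (v - mean(v)) / s
    }
  }
  attr(X, "n_dropped") <- sum(!ok)
  X
}

as_feature_matrix <- function(X) {
  if (is.matrix(X)) return(X)
  X <- tibble::as_tibble(X)
  as.matrix(X[, feature_cols(X)])
}

#' Fit a Gaussian mixture by expectation-maximization
#'
#' Diagonal-covariance Gaussian mixture fitted by EM, taking the best of
#' `n_init` randomly initialized restarts by log-likelihood. Hard labels
#' are maximum-responsibility assignments. The log-likelihood is checked
#' to be non-decreasing over the iterations of the winning restart;
#' restarts whose components empty out are re-seeded.
#'
#' @param X numeric matrix or tibble of observations (rows) by features.
#' @param k number of mixture components.
#' @param seed optional RNG seed.
#' @param n_init number of restarts.
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood
#'   improves by less than `tol`, or after `max_iter` iterations.
#' @return An `em_gmm` object: labels, mixing weights, component means and
#'   variances, log-likelihood and its per-iteration trace.
#' @export
fit_em_gmm <- function(X, k, seed = NULL, n_init = 10, max_iter = 500,
                       tol = 1e-6) {
  if (n_init < 1) stop("`n_init` must be >= 1", call. = FALSE)
  m <- as_feature_matrix(X)
  if (!all(is.finite(m))) stop("X must be finite", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  fit <- fit_em_gmm_cpp(m, k, n_init = n_init, max_iter = max_iter, tol = tol)
  tr <- fit$loglik_trace
  if (length(tr) > 1 && any(diff(tr) < -1e-8 * (1 + abs(tr[-length(tr)])))) {
    stop("EM log-likelihood decreased across iterations", call. = FALSE)
  }
  fit$data <- m
  class(fit) <- "em_gmm"
  fit
}

#' @export
print.em_gmm <- function(x, ...) {
  cat(sprintf("<em_gmm> k = %d on %d x %d data | loglik %.3f (%d iterations)\n",
              x$k, nrow(x$data), ncol(x$data), x$loglik, x$n_iter))
  cat("component sizes:", paste(tabulate(x$labels, x$k), collapse = ", "), "\n")
  invisible(x)
}

#' Clustering validity indices
#'
#' Scores a hard partition of `X`: mean silhouette width
#' (`(b - a)/max(a, b)` per point, in `[-1, 1]`, larger is better),
#' Davies-Bouldin (smaller is better), Calinski-Harabasz (larger is
#' better) and the between/within symmetry ratio, defined here as the
#' minimum between-centroid distance divided by the maximum mean
#' within-cluster distance to centroid (larger is better).
#'
#' @param X numeric matrix or tibble of observations by features.
#' @param labels integer cluster labels in `1..k`; at least two non-empty
#'   clusters.
#' @return A one-row tibble with the four index columns.
#' @export
validity_indices <- function(X, labels) {
  m <- as_feature_matrix(X)
  labels <- as.integer(labels)
  k <- max(labels)
  tibble::as_tibble(as.list(validity_indices_cpp(m, labels, k)))
}

subset_label <- function(cols) paste(cols, collapse = "+")

#' Exhaustive feature-subset by cluster-count search
#'
#' For every non-empty subset of the feature columns and every candidate
#' cluster count `k`, fits an EM Gaussian mixture and scores the partition
#' with the configured validity indices. Emits the sorted silhouette
#' profile per `k` (does a given `k` dominate across subsets?) and a
#' consensus winner by average rank across the indices (Davies-Bouldin
#' rank reversed, since lower is better).
#'
#' @param X tibble with feature columns (and optionally `trace_id`).
#' @param k_values candidate cluster counts.
#' @param indices which validity indices to score and rank on.
#' @param standardize z-score features first (recommended; see
#'   [standardize_features()]).
#' @param seed RNG seed; each fit draws a seed derived from it, so the
#'   full search is reproducible.
#' @param n_init EM restarts per fit.
#' @param max_features guard: refuse to enumerate more than
#'   `2^max_features - 1` subsets.
#' @return A `subset_search` object: `records` (one row per subset x k),
#'   `profiles` (sorted silhouettes per k), `best` (consensus winner) and
#'   `best_fit` (the winning [fit_em_gmm()] object).
#' @export
subset_search <- function(X, k_values = c(2, 3, 4),
                          indices = validity_index_names,
                          standardize = TRUE, seed = 1, n_init = 10,
                          max_features = 20) {
  indices <- match.arg(indices, validity_index_names, several.ok = TRUE)
  X <- tibble::as_tibble(X)
  if (standardize) X <- standardize_features(X)
  cols <- feature_cols(X)
  N <- length(cols)
  if (N > max_features) {
    stop(sprintf("%d features would enumerate 2^%d - 1 subsets; raise `max_features` to confirm",
                 N, N), call. = FALSE)
  }
  m <- as.matrix(X[, cols])
  n <- nrow(m)
  if (any(k_values >= n) || any(k_values < 2)) {
    stop("`k_values` must lie in [2, n_rows - 1]", call. = FALSE)
  }

  masks <- seq_len(2^N - 1)
  n_rec <- length(masks) * length(k_values)
  rec_subset <- character(n_rec)
  rec_mask <- integer(n_rec)
  rec_nfeat <- integer(n_rec)
  rec_k <- integer(n_rec)
  scores <- matrix(NA_real_, n_rec, 4,
                   dimnames = list(NULL, validity_index_names))
  idx <- 0L
  for (mask in masks) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, 0:(N - 1))) != 0L)
    sub <- m[, sel, drop = FALSE]
    lab <- subset_label(cols[sel])
    for (k in k_values) {
      idx <- idx + 1L
      set.seed(seed + idx)
      fit <- fit_em_gmm_cpp(sub, k, n_init = n_init)
      rec_subset[idx] <- lab
      rec_mask[idx] <- mask
      rec_nfeat[idx] <- length(sel)
      rec_k[idx] <- k
      kk <- max(fit$labels)
      if (length(unique(fit$labels)) >= 2) {
        scores[idx, ] <- validity_indices_cpp(sub, fit$labels, kk)
      }
    }
  }
  records <- tibble::tibble(
    subset = rec_subset, subset_mask = rec_mask, n_features = rec_nfeat,
    k = rec_k
  )
  records <- dplyr::bind_cols(records, tibble::as_tibble(scores))

  # consensus by average rank (higher better, except Davies-Bouldin)
  rank_of <- function(v, lower_better = FALSE) {
    v2 <- if (lower_better) v else -v
    rank(v2, ties.method = "average", na.last = "keep")
  }
  ranks <- sapply(indices, function(ix) {
    rank_of(records[[ix]], lower_better = ix == "davies_bouldin")
  })
  records$avg_rank <- rowMeans(ranks, na.rm = TRUE)
  best_idx <- which.min(records$avg_rank)
  best <- records[best_idx, ]

  profiles <- dplyr::bind_rows(lapply(k_values, function(k) {
    sil <- sort(records$silhouette[records$k == k], decreasing = TRUE,
                na.last = TRUE)
    tibble::tibble(k = k, rank = seq_along(sil), silhouette = sil)
  }))

  sel <- which(bitwAnd(best$subset_mask, bitwShiftL(1L, 0:(N - 1))) != 0L)
  best_fit <- fit_em_gmm(m[, sel, drop = FALSE], best$k,
                         seed = seed + best_idx, n_init = n_init)

  structure(
    list(records = records, profiles = profiles, best = best,
         best_fit = best_fit,
         config = list(k_values = k_values, indices = indices,
                       standardize = standardize, seed = seed,
                       n_init = n_init, features = cols)),
    class = "subset_search"
  )
}

#' @export
print.subset_search <- function(x, ...) {
  cat(sprintf("<subset_search> %d records (%d subsets x k in {%s})\n",
              nrow(x$records), length(unique(x$records$subset_mask)),
              paste(x$config$k_values, collapse = ", ")))
  cat(sprintf("consensus: k = %d with features %s (silhouette %.3f)\n",
              x$best$k, x$best$subset, x$best$silhouette))
  invisible(x)
}
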
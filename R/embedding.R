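## Spectral embedding of the trial-by-trial sequence correlation matrix:
## X holds pairwise Pearson correlations between sequence vectors, Q its
## leading eigenvectors by modulus, and P = XQ embeds trials in k-space.

#' Trial-by-trial sequence correlation matrix
#'
#' Pearson correlation between every pair of sequence vectors over the
#' components non-missing in both.  Pairs sharing fewer than `min_overlap`
#' components get a neutral correlation of 0, as do pairs undefined
#' because a vector is constant on the shared support; the diagonal is
#' forced to 1.
#'
#' @param seqs a `nas_sequences`, or a trials x units numeric matrix.
#' @param min_overlap minimum number of shared non-missing components
#'   (default 10).
#' @return T x T symmetric correlation matrix with unit diagonal.
#' @export
sequence_correlation_matrix <- function(seqs, min_overlap = 10) {
  S <- if (inherits(seqs, "nas_sequences")) seqs$S else as.matrix(seqs)
  if (nrow(S) < 2) stop("need at least 2 trials")
  obs <- !is.na(S)
  overlap <- tcrossprod(obs * 1)
  low <- which(rowSums(overlap >= min_overlap) <= 1)
  if (length(low) > 0)
    warning("trial(s) ", paste(utils::head(low, 5), collapse = ", "),
            if (length(low) > 5) ", ..." else "",
            " share fewer than ", min_overlap,
            " components with every other trial")
  X <- suppressWarnings(stats::cor(t(S), use = "pairwise.complete.obs"))
  X[is.na(X)] <- 0
  X[overlap < min_overlap] <- 0
  X <- (X + t(X)) / 2
  diag(X) <- 1
  X
}

#' Leading-eigenvector projection of a correlation matrix
#'
#' Computes the eigendecomposition of the symmetric matrix `X`, orders the
#' eigenpairs by decreasing eigenvalue modulus (ties by ascending original
#' index), fixes each eigenvector's sign so its largest-magnitude entry is
#' positive, and returns the trial coordinates `P = X Q` where `Q` holds
#' the first `k` eigenvectors.  All downstream distances are invariant to
#' the sign convention.
#'
#' @param X T x T symmetric matrix.
#' @param k embedding dimension (default 3).
#' @return object of class `nas_projection`: list with `values` (all T
#'   eigenvalues in modulus order), `Q` (T x k), `P` (T x k), `k`.
#' @export
spectral_projection <- function(X, k = 3) {
  X <- as.matrix(X)
  if (!isTRUE(all.equal(X, t(X), tolerance = 1e-8)))
    stop("X must be symmetric")
  if (k > nrow(X)) stop("k (", k, ") exceeds the number of trials (",
                        nrow(X), ")")
  e <- eigen((X + t(X)) / 2, symmetric = TRUE)
  ord <- order(-abs(e$values), seq_along(e$values))
  vals <- e$values[ord]
  Q <- e$vectors[, ord[seq_len(k)], drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(Q[, j]))
    if (Q[i, j] < 0) Q[, j] <- -Q[, j]
  }
  structure(list(values = vals, Q = Q, P = X %*% Q, k = k),
            class = "nas_projection")
}

#' @export
print.nas_projection <- function(x, ...) {
  cat("<nas_projection>", nrow(x$P), "trials in", x$k, "dims; |lambda| =",
      paste(format(abs(x$values[seq_len(min(3, length(x$values)))]),
                   digits = 3), collapse = ", "), "...\n")
  invisible(x)
}

#' Condition centroids and their distance matrix
#'
#' Averages the embedded coordinates of all trials sharing a condition and
#' computes the matrix of Euclidean distances between condition centroids,
#' normalized by its maximum entry.
#'
#' @param P T x k coordinate matrix (or a `nas_projection`).
#' @param labels length-T condition labels (any atomic type); conditions
#'   are ordered by `sort(unique(labels))` unless `levels` is given.
#' @param levels optional explicit condition ordering; conditions with no
#'   trials yield `NA` centroid rows (with a warning).
#' @return list with `centroids` (conditions x k), `dist` (normalized),
#'   `dist_raw`, and `levels`.
#' @export
condition_centroids <- function(P, labels, levels = NULL) {
  if (inherits(P, "nas_projection")) P <- P$P
  P <- as.matrix(P)
  stopifnot(nrow(P) == length(labels))
  if (is.null(levels)) levels <- sort(unique(labels))
  cent <- matrix(NA_real_, length(levels), ncol(P),
                 dimnames = list(as.character(levels), NULL))
  for (i in seq_along(levels)) {
    rows <- which(labels == levels[i])
    if (length(rows) == 0) {
      warning("condition ", levels[i], " has no trials; centroid is NA")
      next
    }
    cent[i, ] <- colMeans(P[rows, , drop = FALSE])
  }
  D <- as.matrix(stats::dist(cent))
  mx <- suppressWarnings(max(D, na.rm = TRUE))
  Dn <- if (is.finite(mx) && mx > 0) D / mx else D
  list(centroids = cent, dist = Dn, dist_raw = D, levels = levels)
}

#' Embed a session's sequences and compute target centroids
#'
#' Convenience wrapper: correlation matrix, spectral projection, and
#' 9-target centroid distances in one call.
#'
#' @param seqs a `nas_sequences`.
#' @param k embedding dimension.
#' @param min_overlap see [sequence_correlation_matrix()].
#' @param correct_only restrict to correct trials (default TRUE).
#' @return list with `X`, `proj` (`nas_projection`), `cent` (from
#'   [condition_centroids()] over target labels 0..8), and the retained
#'   trial indices.
#' @export
embed_session <- function(seqs, k = 3, min_overlap = 10,
                          correct_only = TRUE) {
  keep <- if (correct_only) which(seqs$trials$correct) else
    seq_len(nrow(seqs$S))
  S <- seqs$S[keep, , drop = FALSE]
  X <- sequence_correlation_matrix(S, min_overlap = min_overlap)
  proj <- spectral_projection(X, k = k)
  labels <- condition_of(seqs)[keep]
  cent <- condition_centroids(proj$P, labels, levels = 0:8)
  list(X = X, proj = proj, cent = cent, trial_rows = keep,
       labels = labels)
}
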
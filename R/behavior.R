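## Behavioral linkage: perspective projection of arena paths to screen
## coordinates, per-target average trajectories, discrete Frechet distance
## matrices, and the Spearman link between sequence-centroid geometry and
## trajectory geometry, with shuffle nulls and ablation curves.

#' Pinhole camera for world-to-screen projection
#'
#' Describes the subject's viewpoint: eye position, view direction, and a
#' horizontal field of view mapped onto a pixel screen.  The default sits
#' at the trial start position at avatar eye height, facing the target
#' grid, with a 90 degree horizontal field of view on a 1024 x 768 screen.
#'
#' @param eye 3D eye position in arena units.
#' @param look 3D view direction (need not be unit length).
#' @param fov_h horizontal field of view in radians, in (0, pi).
#' @param screen c(width, height) in pixels.
#' @param near near-plane depth; points closer are dropped.
#' @return object of class `nas_camera`.
#' @export
nas_camera <- function(eye = c(0, -150, 60), look = c(0, 1, 0),
                       fov_h = pi / 2, screen = c(1024, 768),
                       near = 1.0) {
  stopifnot(fov_h > 0, fov_h < pi, all(screen > 0), near > 0)
  f <- look / sqrt(sum(look^2))
  up <- c(0, 0, 1)
  if (abs(sum(f * up)) > 0.999) stop("view direction too close to vertical")
  right <- c(f[2] * up[3] - f[3] * up[2],
             f[3] * up[1] - f[1] * up[3],
             f[1] * up[2] - f[2] * up[1])
  right <- right / sqrt(sum(right^2))
  up2 <- c(right[2] * f[3] - right[3] * f[2],
           right[3] * f[1] - right[1] * f[3],
           right[1] * f[2] - right[2] * f[1])
  structure(list(eye = eye, forward = f, right = right, up = up2,
                 fov_h = fov_h, screen = screen, near = near,
                 focal_px = (screen[1] / 2) / tan(fov_h / 2)),
            class = "nas_camera")
}

#' Project a 3D path to screen coordinates
#'
#' Standard pinhole perspective mapping: a point at lateral offset s and
#' depth d from the eye lands `focal_px * s / d` pixels from the screen
#' center, so doubling the depth halves the screen offset.  Points behind
#' the near plane are dropped with a warning.
#'
#' @param path3d n x 3 matrix (or data frame) of world points.
#' @param camera a [nas_camera()].
#' @return m x 2 matrix of screen points (pixels; origin top-left, y down).
#' @export
project_trajectory <- function(path3d, camera = nas_camera()) {
  p <- as.matrix(path3d)
  if (nrow(p) == 0) stop("empty path")
  d <- sweep(p[, 1:3, drop = FALSE], 2, camera$eye)
  depth <- d %*% camera$forward
  keep <- depth >= camera$near
  if (!all(keep)) {
    warning(sum(!keep), " point(s) behind the near plane dropped")
    if (!any(keep)) stop("all points behind the near plane")
  }
  d <- d[keep, , drop = FALSE]; depth <- depth[keep]
  sx <- (d %*% camera$right) / depth
  sy <- (d %*% camera$up) / depth
  cbind(x = camera$screen[1] / 2 + camera$focal_px * as.numeric(sx),
        y = camera$screen[2] / 2 - camera$focal_px * as.numeric(sy))
}

#' Resample a polyline to a fixed number of points by arc length
#'
#' @param path n x d matrix of ordered points.
#' @param n_points number of output points (default 50).
#' @return n_points x d matrix, endpoints preserved.
#' @export
resample_path <- function(path, n_points = 50) {
  p <- as.matrix(path)
  if (nrow(p) == 1) return(p[rep(1, n_points), , drop = FALSE])
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] -
                         p[-nrow(p), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  if (s[length(s)] == 0) return(p[rep(1, n_points), , drop = FALSE])
  at <- seq(0, s[length(s)], length.out = n_points)
  apply(p, 2, function(col) stats::approx(s, col, xout = at, ties =
                                            "ordered")$y)
}

#' Average trajectory of one target's trials
#'
#' Resamples each trajectory to a common number of points by arc length,
#' removes outliers whose mean discrete Frechet distance to the other
#' trajectories has z-score > 1, and returns the pointwise mean.  If the
#' rule would flag every trajectory, no exclusion is applied (with a
#' warning).
#'
#' @param paths list of n x d point matrices (>= 2).
#' @param n_points common resampling length (default 50).
#' @param z_threshold outlier threshold on the z-scored mean Frechet
#'   distance (default 1).
#' @return list with `mean` (n_points x d), `outlier` (logical per path).
#' @export
average_trajectory <- function(paths, n_points = 50, z_threshold = 1) {
  if (length(paths) < 2) stop("need at least 2 trajectories")
  rs <- lapply(paths, resample_path, n_points = n_points)
  n <- length(rs)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- discrete_frechet(rs[[i]], rs[[j]])
  md <- rowSums(D) / (n - 1)
  sdm <- stats::sd(md)
  z <- if (is.na(sdm) || sdm == 0) rep(0, n) else (md - mean(md)) / sdm
  out <- z > z_threshold
  if (all(out)) {
    warning("all trajectories flagged as outliers; keeping all")
    out[] <- FALSE
  }
  keep <- rs[!out]
  acc <- Reduce(`+`, keep) / length(keep)
  list(mean = acc, outlier = out)
}

#' Discrete Frechet distance between two polylines
#'
#' Dynamic programming over the monotone coupling lattice with Euclidean
#' ground metric: the minimal over couplings of the maximal pointwise
#' leash length.
#'
#' @param A,B point matrices (rows = ordered points), same dimension.
#' @return the discrete Frechet distance.
#' @examples
#' discrete_frechet(rbind(c(0, 0), c(4, 0)), rbind(c(0, 3), c(4, 3)))  # 3
#' @export
discrete_frechet <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) == 0 || nrow(B) == 0) stop("empty trajectory")
  n <- nrow(A); m <- nrow(B)
  ## pairwise Euclidean distances
  G <- sqrt(outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B))
  G[G < 0 | is.na(G)] <- 0
  ca <- matrix(0, n, m)
  ca[1, 1] <- G[1, 1]
  for (j in seq_len(m)[-1]) ca[1, j] <- max(ca[1, j - 1], G[1, j])
  for (i in seq_len(n)[-1]) {
    ca[i, 1] <- max(ca[i - 1, 1], G[i, 1])
    for (j in seq_len(m)[-1])
      ca[i, j] <- max(min(ca[i - 1, j], ca[i - 1, j - 1], ca[i, j - 1]),
                      G[i, j])
  }
  ca[n, m]
}

## ---- per-target trajectory distance matrices -------------------------

## split a session's trajectory table into per-trial matrices of the
## requested columns, restricted to the given trial ids
trial_paths <- function(session, trial_ids, cols = c("x", "y", "z")) {
  tj <- session$trajectories
  tj <- tj[tj$trial_id %in% trial_ids, ]
  lapply(split(tj[, cols, drop = FALSE], tj$trial_id)[
    as.character(trial_ids)], as.matrix)
}

frechet_matrix_from_paths <- function(by_target, n_points, normalize) {
  avg <- vector("list", 9)
  for (g in 1:9) {
    if (length(by_target[[g]]) == 1) {
      avg[[g]] <- resample_path(by_target[[g]][[1]], n_points)
    } else {
      avg[[g]] <- average_trajectory(by_target[[g]], n_points)$mean
    }
  }
  D <- matrix(0, 9, 9, dimnames = list(0:8, 0:8))
  for (i in 1:8) for (j in (i + 1):9)
    D[i, j] <- D[j, i] <- discrete_frechet(avg[[i]], avg[[j]])
  if (normalize && max(D) > 0) D <- D / max(D)
  attr(D, "average_paths") <- avg
  D
}

#' Per-target trajectory distance matrices
#'
#' `screen_frechet_matrix()` projects each correct trial's arena path to
#' screen coordinates, averages per target, and returns the 9 x 9 discrete
#' Frechet matrix (normalized to max 1) — the subject's-viewpoint
#' trajectory geometry.  `world_frechet_matrix()` does the same in the
#' bird's-eye arena frame (x, y); `optimal_frechet_matrix()` uses the
#' straight start-to-target paths; `target_distance_matrix()` the plain
#' Euclidean distances between target locations.
#'
#' @param session a `nas_session` with trajectories.
#' @param camera a [nas_camera()] for the screen projection.
#' @param n_points common resampling length.
#' @param normalize divide by the matrix maximum (default TRUE).
#' @return 9 x 9 symmetric distance matrix (labels 0..8, row-major
#'   targets); average paths attached as attribute `average_paths`.
#' @export
screen_frechet_matrix <- function(session, camera = nas_camera(),
                                  n_points = 50, normalize = TRUE) {
  by_target <- lapply(0:8, function(g)
    lapply(trial_paths(session, correct_trial_ids(session, g)),
           function(p) project_trajectory(p, camera)))
  frechet_matrix_from_paths(by_target, n_points, normalize)
}

## correct trials of one target; falls back to all of that target's
## trials (with a warning) when none were correct
correct_trial_ids <- function(session, g) {
  tr <- session$trials
  of_target <- tr$target_row * 3 + tr$target_col == g
  ids <- tr$trial_id[of_target & tr$correct]
  if (length(ids) == 0) {
    ids <- tr$trial_id[of_target]
    if (length(ids) == 0) stop("no trials for target ", g)
    warning("no correct trials for target ", g,
            "; averaging over all its trials")
  }
  ids
}

#' @rdname screen_frechet_matrix
#' @export
world_frechet_matrix <- function(session, n_points = 50, normalize = TRUE) {
  by_target <- lapply(0:8, function(g)
    trial_paths(session, correct_trial_ids(session, g),
                cols = c("x", "y")))
  frechet_matrix_from_paths(by_target, n_points, normalize)
}

#' @rdname screen_frechet_matrix
#' @param target_spacing grid spacing for the optimal/target matrices when
#'   no session is given.
#' @export
optimal_frechet_matrix <- function(target_spacing = 290, n_points = 50,
                                   normalize = TRUE) {
  tw <- target_world_coords(target_spacing)
  tw <- tw[order(target_label(tw$row, tw$col)), ]
  by_target <- lapply(1:9, function(g)
    list(rbind(c(0, 0), c(tw$x[g], tw$y[g]))))
  frechet_matrix_from_paths(by_target, n_points, normalize)
}

#' @rdname screen_frechet_matrix
#' @export
target_distance_matrix <- function(target_spacing = 290, normalize = TRUE) {
  tw <- target_world_coords(target_spacing)
  tw <- tw[order(target_label(tw$row, tw$col)), ]
  D <- as.matrix(stats::dist(tw[, c("x", "y")]))
  dimnames(D) <- list(0:8, 0:8)
  if (normalize && max(D) > 0) D <- D / max(D)
  D
}

#' Spearman link between two condition distance matrices
#'
#' Rank correlation over the 36 upper-triangle off-diagonal entries of two
#' 9 x 9 condition distance matrices in matching label order.  A constant
#' matrix leaves the rank correlation undefined; 0 is returned with a
#' warning.
#'
#' @param centroid_D,frechet_D square distance matrices of equal size.
#' @return Spearman rho.
#' @export
link_correlation <- function(centroid_D, frechet_D) {
  stopifnot(all(dim(centroid_D) == dim(frechet_D)))
  ut <- upper.tri(centroid_D)
  a <- centroid_D[ut]; b <- frechet_D[ut]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2 || stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant distance matrix; rank correlation undefined, ",
            "returning 0")
    return(0)
  }
  stats::cor(a, b, method = "spearman")
}

#' Shuffle null for the sequence-trajectory link
#'
#' Permutes target labels across trials, recomputes condition centroids in
#' the fixed embedding and the Spearman link to the trajectory matrix, and
#' returns the null distribution of rho.
#'
#' @param P trial coordinate matrix (or `nas_projection`).
#' @param labels true target labels (0..8) per trial.
#' @param frechet_D 9 x 9 trajectory distance matrix.
#' @param n_shuffles number of label permutations (default 100).
#' @param seed integer seed.
#' @return numeric vector of null rho values.
#' @export
shuffle_link <- function(P, labels, frechet_D, n_shuffles = 100,
                         seed = 1L) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  if (inherits(P, "nas_projection")) P <- P$P
  run_seeded(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      cent <- suppressWarnings(
        condition_centroids(P, sample(labels), levels = 0:8))
      suppressWarnings(link_correlation(cent$dist, frechet_D))
    }, numeric(1))
  })
}

#' Ablation robustness of the sequence-trajectory link
#'
#' Randomly removes a fraction of units (their sequence entries are set to
#' missing), reruns correlation matrix, projection, centroids, and the
#' Spearman link, and averages over iterations at each fraction.
#'
#' @param seqs a `nas_sequences` (correct trials are used).
#' @param frechet_D 9 x 9 trajectory distance matrix.
#' @param fractions unit-removal fractions (default 0.1 to 0.9 by 0.1);
#'   values must be < 1 (0 reproduces the unablated analysis exactly).
#' @param iters iterations per fraction (default 100).
#' @param seed integer seed.
#' @param k,min_overlap embedding parameters.
#' @return data frame `(fraction, mean_rho, sd_rho)`.
#' @export
ablation_curve <- function(seqs, frechet_D,
                           fractions = seq(0.1, 0.9, by = 0.1),
                           iters = 100, seed = 1L, k = 3,
                           min_overlap = 10) {
  if (any(fractions >= 1) || any(fractions < 0))
    stop("fractions must lie in [0, 1)")
  keep <- which(seqs$trials$correct)
  S0 <- seqs$S[keep, , drop = FALSE]
  labels <- condition_of(seqs)[keep]
  nu <- ncol(S0)
  one_rho <- function(S) {
    X <- suppressWarnings(
      sequence_correlation_matrix(S, min_overlap = min_overlap))
    proj <- spectral_projection(X, k = k)
    cent <- suppressWarnings(
      condition_centroids(proj$P, labels, levels = 0:8))
    suppressWarnings(link_correlation(cent$dist, frechet_D))
  }
  run_seeded(seed, {
    res <- lapply(fractions, function(f) {
      n_drop <- round(f * nu)
      rhos <- vapply(seq_len(iters), function(i) {
        S <- S0
        if (n_drop > 0) S[, sample(nu, n_drop)] <- NA_real_
        one_rho(S)
      }, numeric(1))
      data.frame(fraction = f, mean_rho = mean(rhos),
                 sd_rho = stats::sd(rhos))
    })
    do.call(rbind, res)
  })
}
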
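## Decoders: unsupervised nearest-centroid classification in the sequence
## embedding (epoch, target, row, column, combined row x column), spike-time
## selectivity scores, persistent-cell detection, and the persistent-rate
## versus sequence-code comparison with linear maximum-margin classifiers.

## stratified fold assignment: within each class, trials are shuffled and
## dealt round-robin into k folds
stratified_folds <- function(labels, k_folds, seed) {
  run_seeded(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k_folds), length(idx))
    }
    fold
  })
}

#' Cross-validated nearest-centroid decoding
#'
#' Unsupervised distance-based decoder: on each fold, condition centroids
#' are computed from the training trials' embedded coordinates and every
#' test trial is assigned the label of the nearest centroid (Euclidean;
#' ties break to the lowest condition index).  Folds are stratified by
#' class.
#'
#' @param P trial coordinates (T x k matrix or `nas_projection`).
#' @param labels length-T class labels.
#' @param k_folds number of folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @param task name recorded in the report.
#' @return object of class `nas_decoder`: list with `task`, `accuracy`
#'   (mean over folds), `fold_accuracy`, `chance` (1 / number of classes),
#'   `predicted` (per trial, from its test fold), `labels`, `k_folds`,
#'   `seed`.
#' @export
nearest_centroid_cv <- function(P, labels, k_folds = 5, seed = 1L,
                                task = "decode") {
  if (inherits(P, "nas_projection")) P <- P$P
  P <- as.matrix(P)
  stopifnot(nrow(P) == length(labels))
  classes <- sort(unique(labels))
  cnt <- table(labels)
  if (any(cnt < k_folds))
    stop("class ", names(cnt)[which.min(cnt)], " has fewer trials (",
         min(cnt), ") than folds (", k_folds, ")")
  fold <- stratified_folds(labels, k_folds, seed)
  pred <- rep(classes[1], length(labels))
  fold_acc <- numeric(k_folds)
  for (f in seq_len(k_folds)) {
    tr <- fold != f; te <- !tr
    miss <- setdiff(classes, unique(labels[tr]))
    if (length(miss) > 0)
      stop("class ", miss[1], " absent from training fold ", f)
    cent <- t(vapply(classes, function(cl)
      colMeans(P[tr & labels == cl, , drop = FALSE]), numeric(ncol(P))))
    d2 <- outer(rowSums(P[te, , drop = FALSE]^2), rowSums(cent^2), `+`) -
      2 * P[te, , drop = FALSE] %*% t(cent)
    pred[te] <- classes[apply(d2, 1, which.min)]  # first = lowest index
    fold_acc[f] <- mean(pred[te] == labels[te])
  }
  structure(list(task = task, accuracy = mean(fold_acc),
                 fold_accuracy = fold_acc,
                 chance = 1 / length(classes), predicted = pred,
                 labels = labels, k_folds = k_folds, seed = seed),
            class = "nas_decoder")
}

#' @export
print.nas_decoder <- function(x, ...) {
  cat(sprintf("<nas_decoder> %s: accuracy %.3f (chance %.3f, %d-fold)\n",
              x$task, x$accuracy, x$chance, x$k_folds))
  invisible(x)
}

#' Decode the trial epoch from epoch-masked sequences
#'
#' Each trial contributes three sequence vectors masked to the cue, delay,
#' and navigation epochs (neural boundaries preferred, task boundaries as
#' fallback).  The pooled set is embedded and a 3-class nearest-centroid
#' decoder is cross-validated; chance is 1/3.
#'
#' The embedding dimension defaults to six here (not the three used for
#' target-level analyses): the pooled correlation matrix holds three
#' near-disconnected epoch blocks, each with its own internal condition
#' geometry, so the three block-mean directions need not be the top three
#' eigenvectors by modulus; two dimensions per epoch class span both the
#' means and the leading within-block structure.
#'
#' @param seqs a `nas_sequences` (full-trial).
#' @param bounds optional `nas_boundaries`; `NULL` uses task boundaries.
#' @param k,min_overlap embedding parameters (see Details for the `k`
#'   default).
#' @param k_folds,seed cross-validation parameters.
#' @param permute_labels if `TRUE`, epoch labels are permuted uniformly at
#'   random before decoding (chance calibration).
#' @return a `nas_decoder` (task `"epoch"`).
#' @export
epoch_decode <- function(seqs, bounds = NULL, k = 6, min_overlap = 5,
                         k_folds = 5, seed = 1L, permute_labels = FALSE) {
  win <- epoch_windows(bounds, seqs$trials)
  if (any(vapply(win, diff, numeric(1)) <= 0))
    stop("degenerate epoch window; epoch decoding needs 3 classes")
  masked <- lapply(win, function(w) mask_epoch(seqs, w)$S)
  S <- do.call(rbind, masked)
  labels <- rep(c("cue", "delay", "nav"), each = nrow(seqs$S))
  X <- suppressWarnings(
    sequence_correlation_matrix(S, min_overlap = min_overlap))
  proj <- spectral_projection(X, k = k)
  if (permute_labels)
    labels <- run_seeded(seed + 1L, sample(labels))
  nearest_centroid_cv(proj$P, labels, k_folds = k_folds, seed = seed,
                      task = "epoch")
}

#' Spike-time selectivity scores
#'
#' For every unit, Cohen's d (pooled-SD standardized mean difference) is
#' computed between its peak-time distributions for each pair of
#' conditions under the chosen grouping; the score is the maximum |d|
#' across pairs.  A pair with zero pooled SD but different means scores
#' infinite (with a warning).
#'
#' @param seqs a `nas_sequences`.
#' @param grouping `"row"`, `"column"`, or `"target"`.
#' @param min_trials minimum trials per condition for a pair to count.
#' @param correct_only use correct trials only.
#' @return data frame `(unit_id, score)`.
#' @export
selectivity_scores <- function(seqs, grouping = c("row", "column",
                                                  "target"),
                               min_trials = 5, correct_only = TRUE) {
  grouping <- match.arg(grouping)
  keep <- if (correct_only) seqs$trials$correct else
    rep(TRUE, nrow(seqs$S))
  S <- seqs$S[keep, , drop = FALSE]
  g <- switch(grouping,
              row = seqs$trials$target_row,
              column = seqs$trials$target_col,
              target = condition_of(seqs))[keep]
  conds <- sort(unique(g))
  conds <- conds[vapply(conds, function(cl) sum(g == cl) >= min_trials,
                        logical(1))]
  if (length(conds) < 2)
    stop("need at least 2 conditions with ", min_trials, " trials")
  pairs <- utils::combn(conds, 2)
  warned <- FALSE
  score <- vapply(seq_len(ncol(S)), function(u) {
    best <- 0
    for (p in seq_len(ncol(pairs))) {
      a <- S[g == pairs[1, p], u]; a <- a[!is.na(a)]
      b <- S[g == pairs[2, p], u]; b <- b[!is.na(b)]
      if (length(a) < 2 || length(b) < 2) next
      sp <- sqrt(((length(a) - 1) * stats::var(a) +
                    (length(b) - 1) * stats::var(b)) /
                   (length(a) + length(b) - 2))
      d <- if (sp == 0) {
        if (mean(a) == mean(b)) 0 else Inf
      } else abs(mean(a) - mean(b)) / sp
      if (is.infinite(d) && !warned) {
        warning("zero pooled SD with unequal means; score set to Inf")
        warned <<- TRUE
      }
      best <- max(best, d)
    }
    best
  }, numeric(1))
  data.frame(unit_id = seqs$unit_id, score = score)
}

#' Select units above a selectivity percentile
#'
#' @param scores data frame from [selectivity_scores()].
#' @param percentile threshold percentile in [0, 100).
#' @return unit ids with score strictly above the percentile.
#' @export
select_units <- function(scores, percentile) {
  th <- stats::quantile(scores$score, percentile / 100, na.rm = TRUE,
                        names = FALSE)
  scores$unit_id[!is.na(scores$score) & scores$score > th]
}

## decode one grouping (row or column) from the subsequences of selected
## units, tuning the selectivity percentile over a coarse grid by
## cross-validated accuracy
axis_decode <- function(seqs, grouping, percentile_grid, k, min_overlap,
                        k_folds, seed) {
  keep <- which(seqs$trials$correct)
  labels <- switch(grouping, row = seqs$trials$target_row,
                   column = seqs$trials$target_col)[keep]
  scores <- selectivity_scores(seqs, grouping)
  best <- NULL
  for (pc in percentile_grid) {
    units <- select_units(scores, pc)
    if (length(units) < 2) next
    S <- seqs$S[keep, seqs$unit_id %in% units, drop = FALSE]
    dec <- tryCatch({
      X <- suppressWarnings(
        sequence_correlation_matrix(S, min_overlap = min_overlap))
      proj <- spectral_projection(X, k = k)
      nearest_centroid_cv(proj$P, labels, k_folds = k_folds, seed = seed,
                          task = paste0(grouping, "@p", pc))
    }, error = function(e) NULL)
    if (!is.null(dec) && (is.null(best) || dec$accuracy > best$accuracy)) {
      best <- dec
      best$percentile <- pc
      best$units <- units
    }
  }
  if (is.null(best)) {
    warning("no usable ", grouping,
            "-selective set; falling back to all units")
    S <- seqs$S[keep, , drop = FALSE]
    X <- suppressWarnings(
      sequence_correlation_matrix(S, min_overlap = min_overlap))
    proj <- spectral_projection(X, k = k)
    best <- nearest_centroid_cv(proj$P, labels, k_folds = k_folds,
                                seed = seed,
                                task = paste0(grouping, "@all"))
    best$percentile <- NA_real_
    best$units <- seqs$unit_id
  }
  best
}

#' Combined target decoding from row and column subsequences
#'
#' Decodes target row from row-selective subsequences and target column
#' from column-selective subsequences (each a 3-class nearest-centroid
#' decoder in its own embedding, selectivity percentile tuned over a
#' coarse grid); the (predicted row, predicted column) pair uniquely
#' specifies one of the 9 targets.  Reported alongside direct 9-class
#' decoding from the full sequences.  Chance for both is 1/9.
#'
#' @param seqs a `nas_sequences`.
#' @param percentile_grid candidate selectivity percentiles.
#' @param k,min_overlap embedding parameters.
#' @param k_folds,seed cross-validation parameters.
#' @return list with `combined_accuracy`, `row`, `column`, `all_cell`
#'   (`nas_decoder`s), and `chance` (1/9).
#' @export
combined_target_decode <- function(seqs, percentile_grid = c(50, 70, 90),
                                   k = 3, min_overlap = 10, k_folds = 5,
                                   seed = 1L) {
  keep <- which(seqs$trials$correct)
  rowd <- axis_decode(seqs, "row", percentile_grid, k, min_overlap,
                      k_folds, seed)
  cold <- axis_decode(seqs, "column", percentile_grid, k, min_overlap,
                      k_folds, seed)
  target <- condition_of(seqs)[keep]
  comb_pred <- rowd$predicted * 3L + cold$predicted
  comb_acc <- mean(comb_pred == target)
  S <- seqs$S[keep, , drop = FALSE]
  X <- suppressWarnings(
    sequence_correlation_matrix(S, min_overlap = min_overlap))
  proj <- spectral_projection(X, k = k)
  alld <- nearest_centroid_cv(proj$P, target, k_folds = k_folds,
                              seed = seed, task = "all_cell_target")
  list(combined_accuracy = comb_acc, row = rowd, column = cold,
       all_cell = alld, chance = 1 / 9)
}

#' Detect persistent delay-activity cells
#'
#' A unit is persistent if (1) a one-way ANOVA of its delay-period firing
#' rate across the 9 targets is significant, and (2) its delay rate on
#' preferred-target trials (the target with the highest mean delay rate)
#' exceeds its inter-trial-interval baseline rate (one-sided Welch test).
#' Both tests share the p threshold, and relaxing the threshold grows the
#' set monotonically.
#'
#' @param session a `nas_session` whose trials carry `iti_start`/`iti_end`.
#' @param p_threshold significance threshold (default 0.05).
#' @param correct_only use correct trials only.
#' @return object of class `nas_persistent`: list with `members` (unit
#'   ids), `table` (per unit: ANOVA p, tuning p, preferred target, mean
#'   delay and baseline rates), `p_threshold`.
#' @export
find_persistent_cells <- function(session, p_threshold = 0.05,
                                  correct_only = TRUE) {
  tr <- session$trials
  if (!all(c("iti_start", "iti_end") %in% names(tr)) ||
      any(tr$iti_end <= tr$iti_start))
    stop("no inter-trial-interval data; baseline rates not computable")
  if (correct_only) tr <- tr[tr$correct, ]
  sp <- session$spikes[session$spikes$trial_id %in% tr$trial_id, ]
  tidx <- match(sp$trial_id, tr$trial_id)
  ddur <- tr$t_nav_on - tr$t_delay_on
  idur <- tr$iti_end - tr$iti_start
  in_delay <- sp$t_s >= tr$t_delay_on[tidx] & sp$t_s < tr$t_nav_on[tidx]
  in_iti <- sp$t_s >= tr$iti_start[tidx] & sp$t_s < tr$iti_end[tidx]
  units <- session$units$unit_id
  uf <- factor(sp$unit_id, levels = units)
  tf <- factor(sp$trial_id, levels = tr$trial_id)
  dcount <- table(uf[in_delay], tf[in_delay])
  icount <- table(uf[in_iti], tf[in_iti])
  drate <- sweep(unclass(dcount), 2, ddur, `/`)
  irate <- sweep(unclass(icount), 2, idur, `/`)
  target <- tr$target_row * 3L + tr$target_col
  tab <- data.frame(unit_id = units, p_anova = NA_real_,
                    p_tuning = NA_real_, pref_target = NA_integer_,
                    delay_rate_hz = NA_real_, baseline_rate_hz = NA_real_)
  for (i in seq_along(units)) {
    y <- drate[i, ]
    mu <- tapply(y, target, mean)
    pref <- as.integer(names(mu)[which.max(mu)])
    p1 <- tryCatch(
      stats::anova(stats::lm(y ~ factor(target)))[["Pr(>F)"]][1],
      error = function(e) NA_real_)
    yp <- y[target == pref]
    p2 <- tryCatch(
      stats::t.test(yp, irate[i, ], alternative = "greater")$p.value,
      error = function(e) NA_real_)
    tab$p_anova[i] <- p1
    tab$p_tuning[i] <- p2
    tab$pref_target[i] <- pref
    tab$delay_rate_hz[i] <- mean(yp)
    tab$baseline_rate_hz[i] <- mean(irate[i, ])
  }
  members <- tab$unit_id[!is.na(tab$p_anova) & tab$p_anova < p_threshold &
                           !is.na(tab$p_tuning) &
                           tab$p_tuning < p_threshold]
  structure(list(members = members, table = tab,
                 p_threshold = p_threshold),
            class = "nas_persistent")
}

#' @export
print.nas_persistent <- function(x, ...) {
  cat("<nas_persistent>", length(x$members), "persistent cells at p <",
      x$p_threshold, "\n")
  invisible(x)
}

## z-score columns with an SD floor so constant features stay finite
standardize_cols <- function(M) {
  mu <- colMeans(M)
  sd <- apply(M, 2, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  sweep(sweep(M, 2, mu), 2, sd, `/`)
}

svm_cv <- function(features, labels, folds, seed, task) {
  fold <- stratified_folds(labels, folds, seed)
  acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- e1071::svm(x = features[tr, , drop = FALSE],
                      y = factor(labels[tr]), kernel = "linear",
                      scale = FALSE)
    pred <- stats::predict(fit, features[!tr, , drop = FALSE])
    acc[f] <- mean(as.character(pred) == as.character(labels[!tr]))
  }
  structure(list(task = task, accuracy = mean(acc), fold_accuracy = acc,
                 chance = 1 / length(unique(labels)), predicted = NULL,
                 labels = labels, k_folds = folds, seed = seed),
            class = "nas_decoder")
}

#' Compare persistent-rate and sequence codes with linear SVM decoders
#'
#' Two cross-validated linear maximum-margin classifiers predict the trial
#' target: one from the mean delay-period firing rates of persistent cells
#' ([find_persistent_cells()]), one from the trials' sequence-projection
#' coordinates (delay-epoch sequences, task delay window).  Both use
#' stratified 10-fold cross-validation by default.
#'
#' @param session a `nas_session`.
#' @param seqs optional precomputed full-trial `nas_sequences`.
#' @param folds number of folds (default 10).
#' @param seed integer seed.
#' @param p_threshold persistent-cell threshold.
#' @param k,min_overlap embedding parameters.
#' @param min_rate_hz sequence inclusion criterion.
#' @param permute_labels permute target labels (chance calibration).
#' @return list with `persistent` and `sequence` (`nas_decoder`s; the
#'   persistent one is `NULL` with attribute `empty` when no persistent
#'   cell passes), and `persistent_cells`.
#' @export
compare_codes <- function(session, seqs = NULL, folds = 10, seed = 1L,
                          p_threshold = 0.05, k = 3, min_overlap = 5,
                          min_rate_hz = 0.5, permute_labels = FALSE) {
  if (is.null(seqs)) seqs <- build_sequences(session, min_rate_hz)
  keep <- which(seqs$trials$correct)
  labels <- condition_of(seqs)[keep]
  if (permute_labels) labels <- run_seeded(seed + 1L, sample(labels))

  pers <- find_persistent_cells(session, p_threshold)
  persistent_dec <- NULL
  if (length(pers$members) > 0) {
    tr <- session$trials[session$trials$correct, ]
    sp <- session$spikes
    sp <- sp[sp$unit_id %in% pers$members & sp$trial_id %in% tr$trial_id, ]
    tidx <- match(sp$trial_id, tr$trial_id)
    in_delay <- sp$t_s >= tr$t_delay_on[tidx] & sp$t_s < tr$t_nav_on[tidx]
    cnt <- table(factor(sp$trial_id[in_delay], levels = tr$trial_id),
                 factor(sp$unit_id[in_delay], levels = pers$members))
    rates <- unclass(cnt) / (tr$t_nav_on - tr$t_delay_on)
    persistent_dec <- tryCatch(
      svm_cv(standardize_cols(rates), labels, folds, seed, "persistent_svm"),
      error = function(e) NULL)
  }

  win <- c(seqs$trials$t_delay_on[1], seqs$trials$t_nav_on[1])
  Sd <- mask_epoch(seqs, win)$S[keep, , drop = FALSE]
  X <- suppressWarnings(
    sequence_correlation_matrix(Sd, min_overlap = min_overlap))
  proj <- spectral_projection(X, k = k)
  sequence_dec <- svm_cv(proj$P, labels, folds, seed, "sequence_svm")

  list(persistent = persistent_dec, sequence = sequence_dec,
       persistent_cells = pers)
}

#' Same-trial replay test between delay and navigation sequences
#'
#' For each trial, correlates its delay-epoch sequence with every trial's
#' navigation-epoch sequence (pairwise-complete Pearson) and asks whether
#' the same-trial correlation ranks in the top 5% of that distribution.
#' Returns the fraction of trials for which it does; independent delay and
#' navigation structure gives a fraction near 0.05.
#'
#' @param delay_S,nav_S trials x units matrices of delay- and
#'   navigation-masked peak times (matched rows).
#' @param min_overlap minimum shared components for a defined correlation;
#'   undefined correlations rank last.
#' @return list with `fraction` (trials whose same-trial correlation is in
#'   the top 5%) and `rank` (per-trial rank, 1 = most correlated).
#' @export
same_trial_replay_test <- function(delay_S, nav_S, min_overlap = 5) {
  delay_S <- as.matrix(delay_S); nav_S <- as.matrix(nav_S)
  stopifnot(all(dim(delay_S) == dim(nav_S)))
  n <- nrow(delay_S)
  if (n < 2) stop("need at least 2 trials")
  obs_d <- !is.na(delay_S); obs_n <- !is.na(nav_S)
  C <- suppressWarnings(stats::cor(t(delay_S), t(nav_S),
                                   use = "pairwise.complete.obs"))
  ov <- obs_d %*% t(obs_n)
  C[ov < min_overlap] <- NA
  rk <- vapply(seq_len(n), function(i) {
    ci <- C[i, ]
    if (is.na(ci[i])) return(NA_real_)
    sum(ci >= ci[i], na.rm = TRUE)
  }, numeric(1))
  top <- ceiling(0.05 * n)
  list(fraction = mean(rk <= top, na.rm = TRUE), rank = rk)
}
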
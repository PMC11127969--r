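## Trial-to-trial timing consistency: per-(unit, condition) standard
## deviations of peak firing times, compared against a shuffle null.

#' Per-(unit, condition) standard deviation of peak firing times
#'
#' For every target condition with at least `min_trials` trials, computes
#' the sample SD (n - 1 denominator) of each unit's non-missing peak times
#' across that condition's trials.  A (unit, condition) cell with fewer
#' than two non-missing peaks gets a missing SD.
#'
#' @param seqs a `nas_sequences`.
#' @param min_trials minimum trials per condition (default 5); conditions
#'   below it are excluded entirely.
#' @param correct_only if `TRUE` (default), use correct trials only —
#'   correct and incorrect trials are analyzed separately.
#' @return data frame `(unit_id, condition, n, sd_s)`, one row per
#'   included (unit, condition).
#' @export
peak_sd <- function(seqs, min_trials = 5, correct_only = TRUE) {
  stopifnot(inherits(seqs, "nas_sequences"))
  keep <- if (correct_only) seqs$trials$correct else !seqs$trials$correct
  S <- seqs$S[keep, , drop = FALSE]
  cond <- condition_of(seqs)[keep]
  out <- vector("list", 9)
  for (cd in 0:8) {
    rows <- which(cond == cd)
    if (length(rows) < min_trials) next
    sub <- S[rows, , drop = FALSE]
    n_ok <- colSums(!is.na(sub))
    sds <- suppressWarnings(apply(sub, 2, stats::sd, na.rm = TRUE))
    sds[n_ok < 2] <- NA_real_
    out[[cd + 1]] <- data.frame(unit_id = seqs$unit_id, condition = cd,
                                n = n_ok, sd_s = sds)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0)
    stop("no condition has at least ", min_trials, " trials")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Permute the assignment of peak times to units within each trial
## (missing entries keep their positions); the trial's time marginal is
## preserved while unit identity is destroyed.
shuffle_within_trial <- function(S) {
  for (i in seq_len(nrow(S))) {
    ok <- which(!is.na(S[i, ]))
    if (length(ok) > 1) S[i, ok] <- S[i, sample(ok)]
  }
  S
}

## Alternative semantics: permute each unit's peak times across trials.
shuffle_across_trial <- function(S) {
  for (j in seq_len(ncol(S))) {
    ok <- which(!is.na(S[, j]))
    if (length(ok) > 1) S[ok, j] <- S[sample(ok), j]
  }
  S
}

#' Shuffled peak-time SD distribution
#'
#' Repeatedly permutes peak times and recomputes [peak_sd()], pooling the
#' repeats into one shuffled SD distribution.  The default semantics
#' permute the assignment of peak times to units within each trial; the
#' alternative permutes each unit's peak times across trials.
#'
#' @param seqs a `nas_sequences`.
#' @param n_repeats number of shuffle repeats (default 100).
#' @param seed integer seed for reproducible shuffles.
#' @param semantics `"within_trial"` (default) or `"across_trial"`.
#' @param min_trials,correct_only passed to [peak_sd()].
#' @return data frame as [peak_sd()] plus a `repeat_id` column.
#' @export
shuffle_null <- function(seqs, n_repeats = 100, seed = 1L,
                         semantics = c("within_trial", "across_trial"),
                         min_trials = 5, correct_only = TRUE) {
  stopifnot(inherits(seqs, "nas_sequences"))
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  semantics <- match.arg(semantics)
  fn <- switch(semantics, within_trial = shuffle_within_trial,
               across_trial = shuffle_across_trial)
  run_seeded(seed, {
    out <- vector("list", n_repeats)
    for (r in seq_len(n_repeats)) {
      sh <- seqs
      sh$S <- fn(seqs$S)
      tab <- peak_sd(sh, min_trials = min_trials,
                     correct_only = correct_only)
      tab$repeat_id <- r
      out[[r]] <- tab
    }
    do.call(rbind, out)
  })
}

#' Summarize real versus shuffled consistency
#'
#' The headline statistic is the difference of distribution means,
#' `mean(shuffled SDs) - mean(real SDs)`, in milliseconds: positive values
#' mean peak times recur across trials more consistently than chance.
#' Also reports, per threshold, the fraction of units whose best-condition
#' SD (minimum across conditions) falls below it.
#'
#' @param real data frame from [peak_sd()].
#' @param shuffled data frame from [shuffle_null()].
#' @param thresholds_ms thresholds for the best-condition SD fractions
#'   (default 1000 and 1500 ms).
#' @return list with `mean_difference_ms`, `mean_real_ms`,
#'   `mean_shuffled_ms`, `best_sd_ms` (named per unit), and
#'   `fraction_below` (named per threshold).
#' @export
consistency_summary <- function(real, shuffled,
                                thresholds_ms = c(1000, 1500)) {
  rv <- real$sd_s[!is.na(real$sd_s)]
  sv <- shuffled$sd_s[!is.na(shuffled$sd_s)]
  if (length(rv) == 0 || length(sv) == 0)
    stop("empty SD distribution")
  best <- tapply(real$sd_s, real$unit_id, function(x)
    if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)) * 1000
  frac <- vapply(thresholds_ms,
                 function(th) mean(best < th, na.rm = TRUE), numeric(1))
  names(frac) <- paste0("below_", thresholds_ms, "ms")
  list(mean_difference_ms = 1000 * (mean(sv) - mean(rv)),
       mean_real_ms = 1000 * mean(rv),
       mean_shuffled_ms = 1000 * mean(sv),
       best_sd_ms = best,
       fraction_below = frac)
}
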
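## Top-level estimator: nas_fit() runs the full sequence analysis of one
## session and returns a classed object with the usual accessor methods.

#' Control parameters for [nas_fit()]
#'
#' Collects every stage tunable with its default.  Defaults follow the
#' analysis conventions of the pipeline: 100 ms density kernel, 0.5 Hz
#' inclusion rate, 5-trial condition minimum, 1 s FWHM threshold with
#' 100 ms bandwidth and bins, k = 3 embedding with a 10-component overlap
#' floor, 50-point trajectory resampling, 5-fold nearest-centroid and
#' 10-fold SVM cross-validation.
#'
#' @param kernel_sd,step spike-density parameters (s).
#' @param min_rate_hz unit inclusion criterion.
#' @param min_trials minimum trials per condition.
#' @param n_shuffles shuffle repeats for the consistency null.
#' @param fwhm_threshold_s,fwhm_bandwidth_s,boundary_bin_s boundary-stage
#'   parameters.
#' @param k,min_overlap embedding parameters.
#' @param camera a [nas_camera()].
#' @param n_points trajectory resampling length.
#' @param k_folds,svm_folds decoder fold counts.
#' @param p_threshold persistent-cell threshold.
#' @param percentile_grid selectivity percentile grid.
#' @param ablation_fractions,ablation_iters ablation-curve settings.
#' @param epoch one of `"delay"` (memory-period sequences, the main
#'   analysis), `"full"` (no masking).
#' @param use_neural_boundaries mask epochs at neural boundaries when
#'   found (task boundaries otherwise).
#' @param stages character vector of optional stages to run in addition to
#'   sequences/boundaries/embedding/behavior: any of `"consistency"`,
#'   `"decoding"`, `"ablation"`, `"shuffle_link"`.
#' @param seed integer seed for all stochastic stages.
#' @return a list of class `nas_control`.
#' @export
nas_control <- function(kernel_sd = 0.1, step = 0.001, min_rate_hz = 0.5,
                        min_trials = 5, n_shuffles = 100,
                        fwhm_threshold_s = 1.0, fwhm_bandwidth_s = 0.3,
                        boundary_bin_s = 0.1, k = 3, min_overlap = 10,
                        camera = nas_camera(), n_points = 50,
                        k_folds = 5, svm_folds = 10, p_threshold = 0.05,
                        percentile_grid = c(50, 70, 90),
                        ablation_fractions = seq(0.1, 0.9, by = 0.1),
                        ablation_iters = 100,
                        epoch = c("delay", "full"),
                        use_neural_boundaries = TRUE,
                        stages = character(0), seed = 1L) {
  epoch <- match.arg(epoch)
  if (length(setdiff(stages, c("consistency", "decoding", "ablation",
                               "shuffle_link"))) > 0)
    stop("unknown stage(s): ",
         paste(setdiff(stages, c("consistency", "decoding", "ablation",
                                 "shuffle_link")), collapse = ", "))
  structure(as.list(environment()), class = "nas_control")
}

#' Fit the sequence analysis to a session
#'
#' Runs the pipeline on one session: sequence extraction, boundary-cell
#' analysis, epoch masking (memory-period sequences by default, at neural
#' boundaries when found), spectral embedding with target centroids,
#' screen-trajectory Frechet distances, and the Spearman link between the
#' two distance matrices.  Optional stages (consistency statistics, the
#' decoder battery, the shuffle null of the link, and the ablation curve)
#' are selected through `control$stages`.
#'
#' @param session a `nas_session`.
#' @param control a [nas_control()].
#' @return an object of class `nas_fit` with components `seqs`,
#'   `boundaries`, `epoch_seqs`, `embedding`, `frechet_D`, `rho`, and the
#'   optional stage results; supports `print`, `summary`, `coef`,
#'   `predict`, and `plot`.
#' @examples
#' \donttest{
#' sess <- simulate_session(nas_config(n_units = 60,
#'                                     n_trials_per_target = 6))
#' fit <- nas_fit(sess)
#' summary(fit)
#' }
#' @export
nas_fit <- function(session, control = nas_control()) {
  stopifnot(inherits(session, "nas_session"),
            inherits(control, "nas_control"))
  ct <- control
  seqs <- build_sequences(session, min_rate_hz = ct$min_rate_hz,
                          kernel_sd = ct$kernel_sd, step = ct$step)
  bounds <- boundary_analysis(seqs, bandwidth_s = ct$fwhm_bandwidth_s,
                              fwhm_threshold_s = ct$fwhm_threshold_s,
                              bin_s = ct$boundary_bin_s)
  epoch_seqs <- seqs
  if (ct$epoch == "delay") {
    win <- suppressWarnings(
      epoch_windows(if (ct$use_neural_boundaries) bounds else NULL,
                    seqs$trials))
    epoch_seqs <- mask_epoch(seqs, win$delay)
  }
  emb <- embed_session(epoch_seqs, k = ct$k, min_overlap = ct$min_overlap)
  frechet_D <- screen_frechet_matrix(session, camera = ct$camera,
                                     n_points = ct$n_points)
  rho <- link_correlation(emb$cent$dist, frechet_D)

  fit <- list(seqs = seqs, boundaries = bounds, epoch_seqs = epoch_seqs,
              embedding = emb, frechet_D = frechet_D, rho = rho,
              control = ct, session = session)

  if ("consistency" %in% ct$stages) {
    real <- peak_sd(seqs, min_trials = ct$min_trials)
    shuf <- shuffle_null(seqs, n_repeats = ct$n_shuffles, seed = ct$seed,
                         min_trials = ct$min_trials)
    fit$consistency <- list(real = real, shuffled = shuf,
                            summary = consistency_summary(real, shuf))
  }
  if ("shuffle_link" %in% ct$stages) {
    fit$link_null <- shuffle_link(emb$proj, emb$labels, frechet_D,
                                  n_shuffles = ct$n_shuffles,
                                  seed = ct$seed)
  }
  if ("decoding" %in% ct$stages) {
    fit$decoding <- list(
      epoch = epoch_decode(seqs, bounds, k = ct$k, k_folds = ct$k_folds,
                           seed = ct$seed),
      target = combined_target_decode(seqs,
                                      percentile_grid = ct$percentile_grid,
                                      k = ct$k,
                                      min_overlap = ct$min_overlap,
                                      k_folds = ct$k_folds,
                                      seed = ct$seed),
      codes = compare_codes(session, seqs = seqs, folds = ct$svm_folds,
                            seed = ct$seed,
                            p_threshold = ct$p_threshold, k = ct$k))
  }
  if ("ablation" %in% ct$stages) {
    fit$ablation <- ablation_curve(epoch_seqs, frechet_D,
                                   fractions = ct$ablation_fractions,
                                   iters = ct$ablation_iters,
                                   seed = ct$seed, k = ct$k,
                                   min_overlap = ct$min_overlap)
  }
  class(fit) <- "nas_fit"
  fit
}

#' Run the full pipeline on session files or a synthetic config
#'
#' Thin orchestration wrapper: loads (or simulates) the session, fits it,
#' and optionally writes every stage's tables to a results directory.
#'
#' @param input a `nas_session`, a session directory path, or a
#'   [nas_config()].
#' @param control a [nas_control()].
#' @param out_dir optional output directory for stage tables.
#' @return the `nas_fit`, invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(input, control = nas_control(), out_dir = NULL) {
  session <- if (inherits(input, "nas_session")) input
  else if (inherits(input, "nas_config")) simulate_session(input)
  else if (is.character(input)) read_session(input)
  else stop("input must be a session, a config, or a directory path")
  rep_v <- validate_session(session)
  if (nrow(rep_v$violations) > 0)
    stop("session failed validation: ", rep_v$violations$message[1])
  fit <- nas_fit(session, control)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    wt <- function(df, f)
      utils::write.table(df, file.path(out_dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    wt(sequences_table(fit$seqs), "sequences.tsv")
    wt(data.frame(unit_id = names(fit$boundaries$fwhm),
                  fwhm_s = fit$boundaries$fwhm),
       "boundary_fwhm.tsv")
    wt(data.frame(coord = c("pre_delay", "pre_nav"),
                  t_s = c(fit$boundaries$boundaries$pre_delay,
                          fit$boundaries$boundaries$pre_nav)),
       "neural_boundaries.tsv")
    P <- fit$embedding$proj$P
    wt(data.frame(trial_id =
                    fit$epoch_seqs$trial_id[fit$embedding$trial_rows],
                  x = P[, 1], y = P[, 2],
                  z = if (ncol(P) >= 3) P[, 3] else NA,
                  condition = fit$embedding$labels),
       "projection.tsv")
    wt(as.data.frame(fit$embedding$cent$dist), "centroid_dist.tsv")
    wt(as.data.frame(unclass(fit$frechet_D)), "frechet_dist.tsv")
    wt(data.frame(stat = "spearman_rho", value = fit$rho), "link.tsv")
    if (!is.null(fit$consistency))
      wt(fit$consistency$real, "consistency_real.tsv")
    if (!is.null(fit$ablation)) wt(fit$ablation, "ablation.tsv")
    return(invisible(fit))
  }
  fit
}

#' @export
print.nas_fit <- function(x, ...) {
  cat("<nas_fit>", nrow(x$seqs$S), "trials x", ncol(x$seqs$S),
      "included units\n")
  cat(sprintf("  sequence-trajectory link: Spearman rho = %.3f\n", x$rho))
  invisible(x)
}

#' @export
summary.nas_fit <- function(object, ...) {
  x <- object
  cat("Neuronal activation sequence analysis\n")
  cat("  included units:     ", ncol(x$seqs$S), "of",
      nrow(x$session$units), "\n")
  cat("  trials:             ", nrow(x$seqs$S), "\n")
  b <- x$boundaries
  cat(sprintf("  time-selective:      %d units (%.1f%%)\n",
              length(b$time_selective_units),
              100 * b$fraction_selective))
  cat("  neural boundaries:  ",
      "pre-delay", format(b$boundaries$pre_delay), "s,",
      "pre-nav", format(b$boundaries$pre_nav), "s\n")
  ev <- abs(x$embedding$proj$values)
  cat(sprintf("  embedding:           k = %d, top |lambda| share = %.2f\n",
              x$embedding$proj$k, sum(ev[1:x$embedding$proj$k]) / sum(ev)))
  cat(sprintf("  link rho:            %.3f\n", x$rho))
  if (!is.null(x$link_null))
    cat(sprintf("    shuffle null 95%%:  [%.3f, %.3f]\n",
                stats::quantile(x$link_null, 0.025),
                stats::quantile(x$link_null, 0.975)))
  if (!is.null(x$consistency))
    cat(sprintf("  consistency:         mean difference = %.1f ms\n",
                x$consistency$summary$mean_difference_ms))
  if (!is.null(x$decoding)) {
    cat(sprintf("  epoch decoding:      %.3f (chance %.3f)\n",
                x$decoding$epoch$accuracy, x$decoding$epoch$chance))
    cat(sprintf("  target decoding:     all-cell %.3f, combined %.3f (chance %.3f)\n",
                x$decoding$target$all_cell$accuracy,
                x$decoding$target$combined_accuracy, 1 / 9))
  }
  invisible(x)
}

#' @export
coef.nas_fit <- function(object, ...) object$embedding$cent$centroids

#' Predict target labels by nearest centroid
#'
#' Assigns each trial (rows of `newdata`, or the fitted trials) the target
#' whose fitted centroid is nearest in the embedding space.
#'
#' @param object a `nas_fit`.
#' @param newdata optional coordinate matrix (columns matching the
#'   embedding dimension).
#' @param ... unused.
#' @return integer target labels (0..8).
#' @export
predict.nas_fit <- function(object, newdata = NULL, ...) {
  P <- if (is.null(newdata)) object$embedding$proj$P else
    as.matrix(newdata)
  cent <- object$embedding$cent$centroids
  ok <- !is.na(cent[, 1])
  d2 <- outer(rowSums(P^2), rowSums(cent[ok, , drop = FALSE]^2), `+`) -
    2 * P %*% t(cent[ok, , drop = FALSE])
  as.integer(rownames(cent)[ok][apply(d2, 1, which.min)])
}

#' Plot a fitted sequence analysis
#'
#' Panels: the embedded trials colored by target, the centroid distance
#' matrix, the trajectory Frechet matrix, and (when present) the ablation
#' curve.
#'
#' @param x a `nas_fit`.
#' @param ... passed to the scatter panel.
#' @export
plot.nas_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  P <- x$embedding$proj$P
  cols <- grDevices::hcl.colors(9, "Dark 3")
  graphics::plot(P[, 2], P[, 3], col = cols[x$embedding$labels + 1],
                 pch = 19, xlab = "dim 2", ylab = "dim 3",
                 main = "trial embedding", ...)
  img <- function(D, main) {
    graphics::image(1:9, 1:9, t(D[9:1, ]), xlab = "target",
                    ylab = "target", main = main, axes = FALSE,
                    col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE))
    graphics::box()
  }
  img(x$embedding$cent$dist, "centroid distances")
  img(unclass(x$frechet_D), "trajectory Frechet distances")
  if (!is.null(x$ablation)) {
    graphics::plot(x$ablation$fraction, x$ablation$mean_rho, type = "b",
                   xlab = "fraction of units removed",
                   ylab = "mean Spearman rho", main = "ablation")
  } else {
    graphics::hist(x$seqs$S, breaks = 40, main = "peak firing times",
                   xlab = "time (s)")
  }
  invisible(x)
}
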
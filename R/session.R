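## Session container and on-disk interchange format.
##
## A session is stored as a directory of TSV tables (spikes, trials,
## trajectories) plus a MANIFEST and an optional ground-truth sidecar in
## DCF key-value form.  Times are seconds from cue onset per trial;
## row/column indices are 0-based; all windows are half-open [start, end).

#' Construct a session object from component tables
#'
#' @param units data frame with `unit_id` and optionally `role`.
#' @param trials data frame with trial metadata (`trial_id`, `target_row`,
#'   `target_col`, `t_cue_on`, `t_delay_on`, `t_nav_on`, `t_end`, `correct`,
#'   `iti_start`, `iti_end`).
#' @param spikes data frame with `unit_id`, `trial_id`, `t_s`.
#' @param trajectories data frame with `trial_id`, `t_s`, `x`, `y`, `z`, or
#'   `NULL`.
#' @param ground_truth optional list of planted parameters.
#' @return an object of class `nas_session`.
#' @export
nas_session <- function(units, trials, spikes, trajectories = NULL,
                        ground_truth = NULL) {
  s <- list(units = units, trials = trials, spikes = spikes,
            trajectories = trajectories, ground_truth = ground_truth)
  class(s) <- "nas_session"
  rep_v <- validate_session(s)
  if (nrow(rep_v$violations) > 0)
    stop("invalid session: ", rep_v$violations$message[1],
         if (nrow(rep_v$violations) > 1)
           sprintf(" (and %d more violations)", nrow(rep_v$violations) - 1))
  s
}

#' @export
print.nas_session <- function(x, ...) {
  cat("<nas_session>", nrow(x$units), "units,", nrow(x$trials), "trials,",
      nrow(x$spikes), "spikes\n")
  if (!is.null(x$ground_truth))
    cat("  synthetic (", x$ground_truth$mode, " mode, seed ",
        x$ground_truth$config$seed, ")\n", sep = "")
  invisible(x)
}

#' @export
summary.nas_session <- function(object, ...) {
  dur <- object$trials$t_end - object$trials$t_cue_on
  rate <- nrow(object$spikes) / (nrow(object$units) *
                                   sum(object$trials$iti_end))
  cat("Session summary\n")
  cat("  units:          ", nrow(object$units), "\n")
  cat("  trials:         ", nrow(object$trials),
      sprintf("(%d correct)", sum(object$trials$correct)), "\n")
  cat("  trial length:   ", format(mean(dur), digits = 3), "s analysis +",
      format(mean(object$trials$iti_end - object$trials$iti_start),
             digits = 3), "s ITI\n")
  cat("  spikes:         ", nrow(object$spikes),
      sprintf("(mean %.2f Hz/unit)", rate), "\n")
  invisible(object)
}

#' Validate session tables
#'
#' Checks schema, ordering, and referential integrity of a session (or of a
#' raw list of tables).  Nothing is repaired; every violation is reported.
#'
#' @param session a `nas_session` or list with `units`, `trials`, `spikes`,
#'   and optionally `trajectories`.
#' @return list with `counts` (units, trials, spikes) and `violations`, a
#'   data frame of `(table, message)` rows; zero rows means a valid session.
#' @export
validate_session <- function(session) {
  v <- list()
  bad <- function(table, message)
    v[[length(v) + 1]] <<- data.frame(table = table, message = message)

  tr <- session$trials
  need_tr <- c("trial_id", "target_row", "target_col", "t_delay_on",
               "t_nav_on", "t_end", "correct")
  miss <- setdiff(need_tr, names(tr))
  if (length(miss) > 0)
    bad("trials", paste("missing columns:", paste(miss, collapse = ", ")))
  else {
    if (anyDuplicated(tr$trial_id))
      bad("trials", "duplicate trial_id")
    if (!all(tr$target_row %in% 0:2 & tr$target_col %in% 0:2))
      bad("trials", "target_row/target_col must be in 0..2")
    t0 <- if ("t_cue_on" %in% names(tr)) tr$t_cue_on else 0
    ok <- t0 < tr$t_delay_on & tr$t_delay_on < tr$t_nav_on &
      tr$t_nav_on < tr$t_end
    if (!all(ok))
      bad("trials", paste("epoch onsets not strictly increasing in trials:",
                          paste(tr$trial_id[!ok], collapse = ", ")))
  }

  sp <- session$spikes
  if (!all(c("unit_id", "trial_id", "t_s") %in% names(sp)))
    bad("spikes", "missing columns: unit_id, trial_id, t_s required")
  else {
    if (any(sp$t_s < 0)) bad("spikes", "negative spike times")
    if (!all(sp$unit_id %in% session$units$unit_id))
      bad("spikes", sprintf("%d spikes reference unknown unit_id",
                            sum(!sp$unit_id %in% session$units$unit_id)))
    if (!all(sp$trial_id %in% session$trials$trial_id))
      bad("spikes", sprintf("%d spikes reference unknown trial_id",
                            sum(!sp$trial_id %in% session$trials$trial_id)))
    ## ascending within (unit, trial)
    key <- paste(sp$unit_id, sp$trial_id)
    dt <- c(1, diff(sp$t_s))
    samegrp <- c(FALSE, key[-1] == key[-length(key)])
    viol <- samegrp & dt < 0
    if (any(viol)) {
      w <- which(viol)[1]
      bad("spikes", sprintf(
        "spike times not ascending within unit %s trial %s",
        sp$unit_id[w], sp$trial_id[w]))
    }
  }

  tj <- session$trajectories
  if (!is.null(tj) && nrow(tj) > 0) {
    if (!all(c("trial_id", "t_s", "x", "y", "z") %in% names(tj)))
      bad("trajectories", "missing columns: trial_id, t_s, x, y, z required")
    else if (!all(tj$trial_id %in% session$trials$trial_id))
      bad("trajectories", "trajectory rows reference unknown trial_id")
  }

  violations <- if (length(v) > 0) do.call(rbind, v) else
    data.frame(table = character(0), message = character(0))
  list(
    counts = c(units = nrow(session$units), trials = nrow(session$trials),
               spikes = nrow(session$spikes)),
    violations = violations
  )
}

#' Write a session to a directory of TSV tables
#'
#' Canonical interchange layout: `spikes.tsv`, `trials.tsv`,
#' `trajectories.tsv`, a `MANIFEST` naming the dialect, and, for synthetic
#' sessions, `ground_truth.dcf` carrying the generator configuration and a
#' `planted_peaks.tsv` sidecar.
#'
#' @param session a `nas_session`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, f)
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wt(session$units, "units.tsv")
  wt(session$trials, "trials.tsv")
  wt(session$spikes, "spikes.tsv")
  if (!is.null(session$trajectories))
    wt(session$trajectories, "trajectories.tsv")
  manifest <- data.frame(
    format = "naseq-session", version = "1", dialect = "tsv",
    tables = paste(c("units", "trials", "spikes",
                     if (!is.null(session$trajectories)) "trajectories"),
                   collapse = ","))
  write.dcf(manifest, file.path(dir, "MANIFEST"))
  gt <- session$ground_truth
  if (!is.null(gt)) {
    cfg <- gt$config
    scal <- cfg[!vapply(cfg, function(x) length(x) > 1, logical(1))]
    rec <- c(mode = gt$mode,
             lapply(scal, as.character),
             boundary_offsets_s = paste(cfg$boundary_offsets_s,
                                        collapse = ","),
             target_span_range_s = paste(cfg$target_span_range_s,
                                         collapse = ","),
             target_order_weights = paste(cfg$target_order_weights,
                                          collapse = ","),
             selective_effect_range_s = paste(cfg$selective_effect_range_s,
                                              collapse = ","))
    write.dcf(as.data.frame(rec), file.path(dir, "ground_truth.dcf"))
    pk <- as.data.frame(gt$planted_peaks)
    names(pk) <- paste0("target_", 0:8)
    pk <- cbind(unit_id = session$units$unit_id,
                boundary_time = gt$boundary_time,
                pref_target = gt$pref_target, pk)
    wt(pk, "planted_peaks.tsv")
  }
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir session directory.
#' @return a `nas_session`.  The full generator config is not
#'   reconstructed; the ground-truth sidecar tables are reattached verbatim.
#' @export
read_session <- function(dir) {
  rt <- function(f) utils::read.delim(file.path(dir, f))
  if (!file.exists(file.path(dir, "MANIFEST")))
    stop("not a session directory (no MANIFEST): ", dir)
  s <- list(
    units = rt("units.tsv"),
    trials = rt("trials.tsv"),
    spikes = rt("spikes.tsv"),
    trajectories = if (file.exists(file.path(dir, "trajectories.tsv")))
      rt("trajectories.tsv") else NULL,
    ground_truth = NULL
  )
  gtf <- file.path(dir, "ground_truth.dcf")
  if (file.exists(gtf)) {
    rec <- as.data.frame(read.dcf(gtf), stringsAsFactors = FALSE)
    pk <- rt("planted_peaks.tsv")
    s$ground_truth <- list(
      mode = rec$mode,
      planted_peaks = as.matrix(pk[, paste0("target_", 0:8)]),
      boundary_time = pk$boundary_time,
      pref_target = pk$pref_target,
      boundary_offsets_s = as.numeric(strsplit(
        rec$boundary_offsets_s, ",")[[1]]),
      config_record = rec
    )
  }
  class(s) <- "nas_session"
  s
}
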
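## Time-boundary cells: units whose peak firing time is consistent across
## trials of all targets.  Their pooled peak-time histogram shows two
## anticipatory peaks that define "neural boundaries" between task epochs.

#' Full width at half maximum of a peak-time distribution
#'
#' Gaussian kernel density estimate of the across-trial peak times,
#' evaluated on a fine grid; the FWHM is the width of the contiguous
#' region around the global mode in which the density stays above half its
#' maximum, with the crossing points located by linear interpolation.  A
#' distribution with several well-separated modes therefore reports only
#' the taller mode's lobe width.
#'
#' @param peaks numeric vector of peak times (s); `NA`s dropped.
#' @param bandwidth_s KDE bandwidth in seconds (default 0.1).
#' @param step evaluation grid step (default 0.001 s).
#' @return FWHM in seconds, or `NA_real_` with fewer than 2 peaks.
#' @examples
#' unit_fwhm(rep(2, 10))              # point mass: 2.3548 * bandwidth
#' @export
unit_fwhm <- function(peaks, bandwidth_s = 0.1, step = 0.001) {
  peaks <- peaks[!is.na(peaks)]
  if (length(peaks) < 2) return(NA_real_)
  lo <- min(peaks) - 5 * bandwidth_s
  hi <- max(peaks) + 5 * bandwidth_s
  grid <- seq(lo, hi, by = step)
  dens <- sdf_values(peaks, grid, bandwidth_s, step)
  m <- which.max(dens)
  half <- dens[m] / 2
  cross <- function(i, j) {
    ## linear interpolation of the half-max crossing between grid i and j
    grid[i] + (half - dens[i]) / (dens[j] - dens[i]) * (grid[j] - grid[i])
  }
  l <- m
  while (l > 1 && dens[l - 1] >= half) l <- l - 1
  left <- if (l == 1) grid[1] else cross(l - 1, l)
  r <- m
  while (r < length(dens) && dens[r + 1] >= half) r <- r + 1
  right <- if (r == length(dens)) grid[length(dens)] else cross(r + 1, r)
  right - left
}

#' Identify time-selective (boundary) units
#'
#' Units whose across-trial peak-time FWHM falls below a threshold fire at
#' the same sequence position regardless of target and are labeled
#' time-selective.  A single default threshold of 1 s is used; the exact
#' value is exposed because moderate changes do not alter which pooled
#' histogram peaks emerge.
#'
#' @param fwhm named numeric vector of per-unit FWHMs (s), names = unit
#'   ids, as produced by [boundary_analysis()] or by applying
#'   [unit_fwhm()] per unit.
#' @param fwhm_threshold_s selection threshold in seconds (default 1).
#' @return integer vector of selected unit ids.
#' @export
find_time_selective <- function(fwhm, fwhm_threshold_s = 1.0) {
  sel <- !is.na(fwhm) & fwhm < fwhm_threshold_s
  as.integer(names(fwhm)[sel])
}

#' Neural epoch boundaries from pooled boundary-cell peak times
#'
#' Histograms the pooled peak times of time-selective units (all trials,
#' all such units; default 100 ms bins) and locates the tallest bin before
#' delay onset (the pre-delay boundary) and the tallest bin between delay
#' and navigation onset (the pre-navigation boundary).  Either boundary is
#' `NA`, with a warning, when its region holds no counts — as happens in a
#' perception-guided control with no anticipatory cells.
#'
#' @param peaks pooled peak times (s) of time-selective units.
#' @param delay_on,nav_on task epoch onsets (s from cue onset).
#' @param t_end end of the analysis window (s).
#' @param bin_s histogram bin width (default 0.1 s).
#' @return list with `pre_delay`, `pre_nav` (bin centers, s) and the
#'   histogram (`breaks`, `counts`).
#' @export
neural_boundaries <- function(peaks, delay_on, nav_on, t_end, bin_s = 0.1) {
  peaks <- peaks[!is.na(peaks)]
  breaks <- seq(0, t_end + bin_s, by = bin_s)
  if (length(peaks) == 0) {
    warning("no time-selective peak times; no neural boundaries found")
    return(list(pre_delay = NA_real_, pre_nav = NA_real_,
                breaks = breaks, counts = integer(length(breaks) - 1L)))
  }
  h <- graphics::hist(peaks, breaks = breaks, right = FALSE,
                      plot = FALSE)  # half-open [lo, hi) bins
  centers <- h$mids
  pick <- function(region, label) {
    idx <- which(region & h$counts > 0)
    if (length(idx) == 0) {
      warning("no ", label, " boundary peak found")
      return(NA_real_)
    }
    idx[which.max(h$counts[idx])]
  }
  i1 <- pick(centers < delay_on, "pre-delay")
  i2 <- pick(centers >= delay_on & centers < nav_on, "pre-navigation")
  list(pre_delay = if (is.na(i1)) NA_real_ else centers[i1],
       pre_nav = if (is.na(i2)) NA_real_ else centers[i2],
       breaks = h$breaks, counts = h$counts)
}

#' Boundary-cell analysis of a session's sequences
#'
#' Runs the full boundary stage: per-unit FWHM of across-trial peak times,
#' time-selective unit labeling, and neural boundary estimation from the
#' pooled peak histogram.
#'
#' The classification bandwidth defaults to 0.3 s — the scale of the
#' transient firing bump — rather than the 0.1 s used for density
#' estimation: with precise within-condition timing, a narrow bandwidth
#' resolves each target condition of a target-dependent cell as its own
#' mode, and the width of the tallest mode alone would mimic a
#' time-locked cell.  Smoothing at the bump scale merges condition
#' structure into one broad lump (FWHM well above threshold) while a true
#' boundary cell's distribution stays far below it.
#'
#' @param seqs a `nas_sequences`.
#' @param bandwidth_s KDE bandwidth for [unit_fwhm()] (default 0.3 s, see
#'   Details).
#' @param fwhm_threshold_s selection threshold for [find_time_selective()].
#' @param bin_s histogram bin width for [neural_boundaries()].
#' @return object of class `nas_boundaries`: list with `fwhm` (named per
#'   unit), `time_selective_units`, `fraction_selective`, `boundaries`
#'   (from [neural_boundaries()]), and the epoch onsets used.
#' @export
boundary_analysis <- function(seqs, bandwidth_s = 0.3,
                              fwhm_threshold_s = 1.0, bin_s = 0.1) {
  stopifnot(inherits(seqs, "nas_sequences"))
  fw <- apply(seqs$S, 2, unit_fwhm, bandwidth_s = bandwidth_s)
  names(fw) <- seqs$unit_id
  sel <- find_time_selective(fw, fwhm_threshold_s)
  pooled <- as.numeric(seqs$S[, seqs$unit_id %in% sel, drop = FALSE])
  delay_on <- seqs$trials$t_delay_on[1]
  nav_on <- seqs$trials$t_nav_on[1]
  nb <- neural_boundaries(pooled, delay_on, nav_on, seqs$t_end,
                          bin_s = bin_s)
  structure(list(fwhm = fw, time_selective_units = sel,
                 fraction_selective = length(sel) / length(fw),
                 boundaries = nb, delay_on = delay_on, nav_on = nav_on,
                 t_end = seqs$t_end),
            class = "nas_boundaries")
}

#' @export
print.nas_boundaries <- function(x, ...) {
  cat("<nas_boundaries>", length(x$time_selective_units),
      sprintf("time-selective units (%.1f%%)", 100 * x$fraction_selective),
      "\n  neural boundaries: pre-delay",
      format(x$boundaries$pre_delay), "s, pre-nav",
      format(x$boundaries$pre_nav), "s\n")
  invisible(x)
}

#' Epoch windows from neural boundaries with task fallback
#'
#' Returns the three half-open epoch windows (cue, delay, navigation).
#' Neural boundaries are preferred where available; missing ones fall back
#' to task onsets with a warning.
#'
#' @param bounds a `nas_boundaries`, or `NULL` to use task boundaries.
#' @param trials a session `trials` table (used for task onsets and
#'   `t_end`).
#' @return named list of length-2 windows: `cue`, `delay`, `nav`.
#' @export
epoch_windows <- function(bounds, trials) {
  d_on <- trials$t_delay_on[1]; n_on <- trials$t_nav_on[1]
  t_end <- trials$t_end[1]
  b1 <- d_on; b2 <- n_on
  if (!is.null(bounds)) {
    nb <- bounds$boundaries
    if (!is.na(nb$pre_delay)) b1 <- nb$pre_delay else
      warning("pre-delay neural boundary missing; using task boundary")
    if (!is.na(nb$pre_nav)) b2 <- nb$pre_nav else
      warning("pre-navigation neural boundary missing; using task boundary")
  }
  list(cue = c(0, b1), delay = c(b1, b2), nav = c(b2, t_end))
}
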
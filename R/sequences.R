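## Spike-density functions and sequence vectors.
##
## A trial's sequence vector S holds, for every included unit, the time t_n
## at which that unit's spike-density function (Gaussian kernel, SD 100 ms
## by default) attains its maximum within the analysis window.  Densities
## are evaluated on a 1 ms grid with the kernel truncated at +/- 5 SD and no
## boundary renormalization; argmax ties break to the earliest grid point.

#' Spike-density function of one spike train
#'
#' Convolves a spike train with a Gaussian kernel, evaluated on a uniform
#' time grid over the trial window.
#'
#' @param spike_times sorted numeric vector of spike times (s), inside the
#'   window.
#' @param window length-2 numeric, half-open trial window `[start, end)`.
#' @param kernel_sd Gaussian kernel SD in seconds (default 0.1).
#' @param step grid step in seconds (default 0.001).
#' @return object of class `nas_sdf`: list with `time` (grid, s) and
#'   `value` (rate estimate, spikes/s).  The integral over the window
#'   approximates the spike count up to kernel truncation at the edges.
#' @examples
#' d <- spike_density(2.0, c(0, 4))
#' d$time[which.max(d$value)]   # 2.0
#' max(d$value)                 # ~ 1 / (0.1 * sqrt(2*pi))
#' @export
spike_density <- function(spike_times, window, kernel_sd = 0.1,
                          step = 0.001) {
  if (length(window) != 2 || !(window[2] > window[1]))
    stop("window must be a non-empty interval [start, end)")
  if (is.unsorted(spike_times))
    stop("spike times must be sorted ascending")
  grid <- seq(window[1], window[2], by = step)
  value <- sdf_values(spike_times, grid, kernel_sd, step)
  structure(list(time = grid, value = value, kernel_sd = kernel_sd,
                 step = step), class = "nas_sdf")
}

## Density on a given grid: binned spike counts convolved with the sampled
## kernel (exact for on-grid spikes; off-grid spikes are assigned to the
## nearest grid point, an error bounded by step/2 in time).
sdf_values <- function(spike_times, grid, kernel_sd, step) {
  ng <- length(grid)
  if (length(spike_times) == 0) return(numeric(ng))
  bin <- round((spike_times - grid[1]) / step) + 1L
  bin <- bin[bin >= 1L & bin <= ng]
  if (length(bin) == 0) return(numeric(ng))
  counts <- tabulate(bin, nbins = ng)
  half <- ceiling(5 * kernel_sd / step)
  kern <- stats::dnorm(seq(-half, half) * step, sd = kernel_sd)
  full <- convolve_open(counts, kern)
  full[half + seq_len(ng)]
}

## Linear ("open") convolution via FFT; returns length n + m - 1.
convolve_open <- function(x, k) {
  n <- length(x); m <- length(k)
  L <- stats::nextn(n + m - 1L, 2)
  fx <- stats::fft(c(x, numeric(L - n)))
  fk <- stats::fft(c(k, numeric(L - m)))
  out <- Re(stats::fft(fx * fk, inverse = TRUE)) / L
  pmax(out[seq_len(n + m - 1L)], 0)
}

#' Peak firing time of a spike-density function
#'
#' Grid time of the global density maximum; ties (including plateaus) break
#' to the earliest grid point.  An identically-zero density has no peak and
#' yields `NA`.
#'
#' @param density a `nas_sdf` from [spike_density()].
#' @return peak time in seconds, or `NA_real_` for an all-zero density.
#' @export
peak_time <- function(density) {
  stopifnot(inherits(density, "nas_sdf"))
  if (all(density$value == 0)) return(NA_real_)
  density$time[which.max(density$value)]
}

#' @export
print.nas_sdf <- function(x, ...) {
  cat("<nas_sdf>", length(x$time), "grid points,",
      format(x$time[1]), "to", format(x$time[length(x$time)]),
      "s, kernel SD", x$kernel_sd, "s\n")
  invisible(x)
}

#' @export
plot.nas_sdf <- function(x, ...) {
  graphics::plot(x$time, x$value, type = "l", xlab = "time (s)",
                 ylab = "rate (Hz)", ...)
}

#' Build per-trial sequence vectors for a session
#'
#' For every trial, computes each included unit's spike-density function
#' over the analysis window `[0, t_end)` and records its peak firing time
#' t_n.  Units whose session-mean firing rate (total analysis-window spikes
#' divided by total analysis time) falls below `min_rate_hz` are excluded
#' for all trials; the remaining unit order is fixed across trials.  A unit
#' with no spikes in a given trial contributes a missing entry for that
#' trial but keeps its column.
#'
#' @param session a `nas_session`.
#' @param min_rate_hz inclusion criterion on session-mean rate (default
#'   0.5 Hz).
#' @param kernel_sd,step density parameters, see [spike_density()].
#' @return object of class `nas_sequences`: list with `S` (trials x units
#'   matrix of peak times, `NA` = missing), `trial_id`, `unit_id`
#'   (included units, ascending), and the session's `trials` table.
#' @export
build_sequences <- function(session, min_rate_hz = 0.5, kernel_sd = 0.1,
                            step = 0.001) {
  trials <- session$trials
  t_end <- trials$t_end[1]
  sp <- session$spikes
  sp <- sp[sp$t_s >= 0 & sp$t_s < t_end, ]

  total_time <- nrow(trials) * t_end
  cnt <- table(factor(sp$unit_id, levels = session$units$unit_id))
  rate <- as.numeric(cnt) / total_time
  included <- session$units$unit_id[rate >= min_rate_hz]
  if (length(included) == 0)
    stop("no unit passes the firing-rate criterion (min_rate_hz = ",
         min_rate_hz, " Hz)")
  sp <- sp[sp$unit_id %in% included, ]

  n_grid <- length(seq(0, t_end, by = step))
  half <- ceiling(5 * kernel_sd / step)
  kseq <- stats::dnorm(seq(-half, half) * step, sd = kernel_sd)
  L <- stats::nextn(n_grid + length(kseq) - 1L, 2)
  fk <- stats::fft(c(kseq, numeric(L - length(kseq))))

  uidx <- match(sp$unit_id, included)
  tidx <- match(sp$trial_id, trials$trial_id)
  bin <- round(sp$t_s / step) + 1L
  ok <- bin >= 1L & bin <= n_grid
  nu <- length(included)
  S <- matrix(NA_real_, nrow(trials), nu)

  for (tr in seq_len(nrow(trials))) {
    rows <- which(tidx == tr & ok)
    if (length(rows) == 0) next
    flat <- (uidx[rows] - 1L) * L + bin[rows]
    counts <- matrix(tabulate(flat, nbins = L * nu), L, nu)
    used <- which(colSums(counts) > 0)
    if (length(used) == 0) next
    fx <- stats::mvfft(counts[, used, drop = FALSE])
    dens <- Re(stats::mvfft(fx * fk, inverse = TRUE)) / L
    dens <- dens[half + seq_len(n_grid), , drop = FALSE]
    S[tr, used] <- (apply(dens, 2, which.max) - 1L) * step
  }

  structure(list(S = S, trial_id = trials$trial_id, unit_id = included,
                 trials = trials, t_end = t_end, kernel_sd = kernel_sd,
                 step = step),
            class = "nas_sequences")
}

#' @export
print.nas_sequences <- function(x, ...) {
  cat("<nas_sequences>", nrow(x$S), "trials x", ncol(x$S), "units;",
      sprintf("%.1f%% entries missing", 100 * mean(is.na(x$S))), "\n")
  invisible(x)
}

#' Mask a sequence object to one epoch
#'
#' Peak times outside the half-open window `[start, end)` are set to
#' missing; entries inside are unchanged.  The window may come from task
#' boundaries (trial metadata) or neural boundaries
#' ([neural_boundaries()]).
#'
#' @param seqs a `nas_sequences`.
#' @param window length-2 numeric `[start, end)`.
#' @return a `nas_sequences` with masked `S`.
#' @export
mask_epoch <- function(seqs, window) {
  stopifnot(inherits(seqs, "nas_sequences"))
  if (length(window) != 2 || window[2] < window[1])
    stop("window must be [start, end) with end >= start")
  S <- seqs$S
  S[!(S >= window[1] & S < window[2])] <- NA_real_
  seqs$S <- S
  seqs
}

#' Export sequence vectors as a wide table
#'
#' @param seqs a `nas_sequences`.
#' @param missing_token value written for missing entries (default `NA`).
#' @return data frame: `trial_id`, `target_row`, `target_col`, then one
#'   column per included unit.
#' @export
sequences_table <- function(seqs, missing_token = NA) {
  S <- seqs$S
  if (!is.na(missing_token)) S[is.na(S)] <- missing_token
  out <- data.frame(trial_id = seqs$trial_id,
                    target_row = seqs$trials$target_row,
                    target_col = seqs$trials$target_col)
  colnames(S) <- paste0("u", seqs$unit_id)
  cbind(out, S)
}

## target condition labels (0..8, row-major) for a sequences object
condition_of <- function(seqs)
  seqs$trials$target_row * 3L + seqs$trials$target_col
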
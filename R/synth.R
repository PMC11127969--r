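## Synthetic session generator: sessions with planted neuronal activation
## sequences (NAS), time-boundary cells, persistent delay activity, or no
## structure at all, plus 3D movement trajectories through the virtual arena.

#' Configuration for a synthetic recording session
#'
#' Builds the parameter set describing one simulated delayed-navigation
#' session: task epoch durations, unit counts and role fractions, bump shape
#' and timing noise, and the generative mode.
#'
#' The defaults emulate the task conditions of the source recordings: a 3 s
#' visual cue, a 2 s memory delay, a 1.5 s analyzed navigation window, nine
#' targets on a 3x3 grid spaced 290 arena units apart, roughly 200
#' simultaneously recorded units, transient firing bumps whose width at 80%
#' of maximum is about 220 ms, and a small population of time-boundary cells
#' anticipating the delay and navigation onsets by 750 ms and 500 ms.
#'
#' @param n_units number of simultaneously recorded units.
#' @param n_trials_per_target trials per target condition (9 targets).
#' @param cue_s,delay_s,nav_s,iti_s epoch durations in seconds.  The
#'   analyzed navigation window is fixed at `nav_s`; the inter-trial
#'   interval supplies baseline firing for persistent-rate analyses.
#' @param background_rate_hz homogeneous Poisson background rate per unit.
#' @param bump_amplitude_hz peak firing rate of the planted Gaussian bump.
#' @param bump_sd_s standard deviation of the Gaussian bump rate profile.
#'   The default is calibrated so the bump's width at 80% of maximum is
#'   0.22 s (`0.22 / (2 * sqrt(2 * log(1.25)))`).
#' @param peak_jitter_sd_s trial-to-trial SD of the planted peak time.
#' @param frac_boundary_cells fraction of units that are time-boundary cells.
#' @param boundary_offsets_s anticipation offsets (s) before delay onset and
#'   before navigation onset at which boundary cells fire.
#' @param frac_row_selective,frac_col_selective fractions of units whose
#'   peak time depends only on target row (resp. column).
#' @param target_span_range_s two-vector: range (s) of the full span over
#'   which a target-dependent unit's nine peak times are evenly spaced.
#'   Even spacing over a span well above the time-selectivity threshold
#'   guarantees such cells are never mistaken for time-boundary cells.
#' @param target_order_weights two-vector: magnitude range of the random
#'   per-unit weights on the normalized target screen coordinates; the
#'   weighted screen position (plus noise) determines the *order* of the
#'   unit's nine peak times, tying sequence geometry to the viewpoint.
#' @param target_order_noise half-width of the idiosyncratic per-target
#'   noise added to the ordering score (same scale as the normalized
#'   screen coordinates).
#' @param selective_effect_range_s two-vector: range of per-grid-step slopes
#'   (s) for row-/column-selective units.
#' @param incorrect_frac fraction of trials marked incorrect.
#' @param incorrect_jitter_multiplier multiplier applied to
#'   `peak_jitter_sd_s` on incorrect trials.
#' @param mode one of `"sequence"`, `"persistent"`, `"unstructured"`,
#'   `"perception_control"`.
#' @param persistent_tuned_rate_hz,persistent_baseline_hz delay firing rate
#'   for the preferred target and rate elsewhere, for persistent-mode units.
#' @param target_spacing arena distance between adjacent targets.
#' @param speed movement speed in arena units per second (spacing / 0.5 s).
#' @param trajectory_noise_sd lateral path noise SD in arena units.
#' @param trajectory_hz trajectory sampling rate.
#' @param seed integer seed; the same config and seed give byte-identical
#'   sessions.
#' @return an object of class `nas_config`.
#' @seealso [simulate_session()]
#' @export
nas_config <- function(n_units = 200L,
                       n_trials_per_target = 20L,
                       cue_s = 3.0, delay_s = 2.0, nav_s = 1.5, iti_s = 2.0,
                       background_rate_hz = 1.0,
                       bump_amplitude_hz = 25.0,
                       bump_sd_s = 0.22 / (2 * sqrt(2 * log(1.25))),
                       peak_jitter_sd_s = 0.1,
                       frac_boundary_cells = 0.05,
                       boundary_offsets_s = c(0.75, 0.5),
                       frac_row_selective = 0.20,
                       frac_col_selective = 0.20,
                       target_span_range_s = c(1.4, 2.2),
                       target_order_weights = c(0.35, 0.55),
                       target_order_noise = 0.3,
                       selective_effect_range_s = c(0.45, 0.50),
                       incorrect_frac = 0,
                       incorrect_jitter_multiplier = 2,
                       mode = c("sequence", "persistent", "unstructured",
                                "perception_control"),
                       persistent_tuned_rate_hz = 10,
                       persistent_baseline_hz = 2,
                       target_spacing = 290,
                       speed = 580,
                       trajectory_noise_sd = 5,
                       trajectory_hz = 50,
                       seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(
    n_units >= 1, n_trials_per_target >= 1,
    cue_s > 0, delay_s > 0, nav_s > 0, iti_s > 0,
    background_rate_hz >= 0, bump_amplitude_hz > 0, bump_sd_s > 0,
    peak_jitter_sd_s >= 0,
    length(boundary_offsets_s) == 2, all(boundary_offsets_s > 0),
    incorrect_frac >= 0, incorrect_frac <= 1,
    incorrect_jitter_multiplier > 0,
    persistent_tuned_rate_hz > 0, persistent_baseline_hz > 0,
    target_spacing > 0, speed > 0, trajectory_noise_sd >= 0,
    trajectory_hz > 0
  )
  fr <- c(frac_boundary_cells, frac_row_selective, frac_col_selective)
  if (any(fr < 0) || any(fr > 1))
    stop("role fractions must lie in [0, 1]")
  if (sum(fr) > 1)
    stop("configuration error: role fractions sum to more than 1")
  if (length(seed) != 1 || is.na(seed) || seed != as.integer(seed))
    stop("seed must be a single integer")
  cfg <- list(
    n_units = as.integer(n_units),
    n_trials_per_target = as.integer(n_trials_per_target),
    cue_s = cue_s, delay_s = delay_s, nav_s = nav_s, iti_s = iti_s,
    background_rate_hz = background_rate_hz,
    bump_amplitude_hz = bump_amplitude_hz,
    bump_sd_s = bump_sd_s,
    peak_jitter_sd_s = peak_jitter_sd_s,
    frac_boundary_cells = frac_boundary_cells,
    boundary_offsets_s = boundary_offsets_s,
    frac_row_selective = frac_row_selective,
    frac_col_selective = frac_col_selective,
    target_span_range_s = target_span_range_s,
    target_order_weights = target_order_weights,
    target_order_noise = target_order_noise,
    selective_effect_range_s = selective_effect_range_s,
    incorrect_frac = incorrect_frac,
    incorrect_jitter_multiplier = incorrect_jitter_multiplier,
    mode = mode,
    persistent_tuned_rate_hz = persistent_tuned_rate_hz,
    persistent_baseline_hz = persistent_baseline_hz,
    target_spacing = target_spacing,
    speed = speed,
    trajectory_noise_sd = trajectory_noise_sd,
    trajectory_hz = trajectory_hz,
    seed = as.integer(seed)
  )
  class(cfg) <- "nas_config"
  cfg
}

#' @export
print.nas_config <- function(x, ...) {
  cat("<nas_config>", x$mode, "mode:", x$n_units, "units,",
      9L * x$n_trials_per_target, "trials, seed", x$seed, "\n")
  cat("  epochs (s): cue", x$cue_s, "| delay", x$delay_s,
      "| nav", x$nav_s, "| iti", x$iti_s, "\n")
  invisible(x)
}

## Arena geometry: start at the origin, camera axis along +y, targets on a
## 3x3 grid two spacings ahead.  z is up; paths run on the ground plane.
target_world_coords <- function(spacing) {
  g <- expand.grid(col = 0:2, row = 0:2)
  data.frame(row = g$row, col = g$col,
             x = (g$col - 1) * spacing,
             y = 2 * spacing + g$row * spacing,
             z = 0)
}

target_label <- function(row, col) row * 3L + col  # 0..8, row-major

## reflect values into [lo, hi] (fold at the edges); unlike clamping this
## leaves no point mass at the boundary
fold_into <- function(x, lo, hi) {
  L <- hi - lo
  z <- (x - lo) %% (2 * L)
  lo + ifelse(z <= L, z, 2 * L - z)
}

## Screen positions of the nine targets under the default camera, centred
## per axis and scaled by one common factor (largest offset = 1): the true
## screen-space anisotropy (perspective compression of rows) is preserved,
## so timing planted in these coordinates carries the subject's-viewpoint
## geometry, not the bird's-eye grid.
target_screen_coords <- function(cfg, camera = nas_camera()) {
  tw <- target_world_coords(cfg$target_spacing)
  sc <- project_trajectory(as.matrix(tw[, c("x", "y", "z")]), camera)
  cx <- sc[, 1] - mean(range(sc[, 1]))
  cy <- sc[, 2] - mean(range(sc[, 2]))
  s <- max(abs(c(cx, cy)))
  data.frame(row = tw$row, col = tw$col, sx = cx / s, sy = cy / s)
}

run_seeded <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic recording session
#'
#' Draws a full session — unit roles, planted peak times, trial metadata,
#' spike events, and movement trajectories — from a [nas_config()].  All
#' randomness flows from `config$seed`; calling twice with the same config
#' yields identical sessions.
#'
#' In `"sequence"` mode every non-boundary unit carries one planted peak
#' time per target.  Base peak times tile the whole trial; target-dependent
#' units shift their peak linearly in the target's screen position,
#' row-(column-)selective units linearly in target row (column) only.
#' Boundary cells fire at a fixed anticipation offset before the delay or
#' navigation onset on every trial regardless of target.  Spikes are an
#' inhomogeneous Poisson draw from background plus a Gaussian rate bump
#' centred on the planted peak plus per-trial jitter (doubled by default on
#' incorrect trials).  `"persistent"` mode replaces the timing code with
#' sustained tuned delay firing; `"unstructured"` redraws every peak
#' uniformly per trial with no condition structure and no boundary cells;
#' `"perception_control"` is sequence mode without boundary cells.
#'
#' @param config a [nas_config()].
#' @return an object of class `nas_session`: a list with `units`, `trials`,
#'   `spikes`, `trajectories` data frames and a `ground_truth` list.
#' @examples
#' s <- simulate_session(nas_config(n_units = 20, n_trials_per_target = 2))
#' s
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "nas_config"))
  run_seeded(config$seed, generate_session_impl(config))
}

#' @rdname simulate_session
#' @export
generate_session <- simulate_session

generate_session_impl <- function(cfg) {
  n <- cfg$n_units
  t_delay <- cfg$cue_s
  t_nav <- cfg$cue_s + cfg$delay_s
  t_end <- t_nav + cfg$nav_s
  t_iti_end <- t_end + cfg$iti_s

  ## ---- roles ----
  use_boundary <- cfg$mode %in% c("sequence", "persistent")
  n_b <- if (use_boundary) round(cfg$frac_boundary_cells * n) else 0L
  n_r <- if (cfg$mode == "sequence" || cfg$mode == "perception_control")
    round(cfg$frac_row_selective * n) else 0L
  n_c <- if (cfg$mode == "sequence" || cfg$mode == "perception_control")
    round(cfg$frac_col_selective * n) else 0L
  role <- rep("target", n)
  if (n_b > 0) role[seq_len(n_b)] <- "boundary"
  if (n_r > 0) role[n_b + seq_len(n_r)] <- "row"
  if (n_c > 0) role[n_b + n_r + seq_len(n_c)] <- "col"
  if (cfg$mode == "persistent") role[role != "boundary"] <- "persistent"
  if (cfg$mode == "unstructured") role[] <- "unstructured"

  ## ---- trials ----
  n_trials <- 9L * cfg$n_trials_per_target
  targ <- sample(rep(0:8, cfg$n_trials_per_target))
  correct <- stats::runif(n_trials) >= cfg$incorrect_frac
  trials <- data.frame(
    trial_id = seq_len(n_trials),
    target_row = targ %/% 3L,
    target_col = targ %% 3L,
    t_cue_on = 0,
    t_delay_on = t_delay,
    t_nav_on = t_nav,
    t_end = t_end,
    correct = correct,
    iti_start = t_end,
    iti_end = t_iti_end
  )

  ## ---- planted per-target peak times (units x 9 targets) ----
  scr <- target_screen_coords(cfg)
  scr <- scr[order(target_label(scr$row, scr$col)), ]
  planted <- matrix(NA_real_, n, 9)
  boundary_time <- rep(NA_real_, n)
  pref_target <- rep(NA_integer_, n)
  rsign <- function(k) sample(c(-1, 1), k, replace = TRUE)
  er <- cfg$target_order_weights
  es <- cfg$selective_effect_range_s

  ## Structured units are confined to one task epoch, with a guard margin
  ## of about two bump SDs from the epoch edges: peak times then carry
  ## the target code while epoch spike counts stay target-invariant, so
  ## the timing code does not leak into a firing-rate code.
  guard <- 0.35
  regions <- rbind(cue = c(guard, t_delay - guard),
                   delay = c(t_delay + guard, t_nav - guard),
                   nav = c(t_nav + 0.3, t_end - 0.3))
  rw <- pmax(regions[, 2] - regions[, 1], 0.2)
  pick_region <- function(which_rows) {
    i <- which_rows[sample.int(length(which_rows), 1,
                               prob = rw[which_rows])]
    c(regions[i, ], rw[i])
  }
  for (u in seq_len(n)) {
    switch(role[u],
      boundary = {
        boundary_time[u] <- if (u %% 2L == 1L)
          t_delay - cfg$boundary_offsets_s[1]
        else
          t_nav - cfg$boundary_offsets_s[2]
        planted[u, ] <- boundary_time[u]
      },
      row = ,
      col = {
        reg <- pick_region(c(1, 3))  # cue or navigation
        a <- rsign(1) * min(stats::runif(1, es[1], es[2]), reg[3] / 2)
        b0 <- stats::runif(1, reg[1] + abs(a), reg[2] - abs(a))
        gc_ <- if (role[u] == "row") scr$row else scr$col
        planted[u, ] <- b0 + a * (gc_ - 1)
      },
      target = {
        ## order the nine targets by a random direction in screen space
        ## plus idiosyncratic noise, then space the peak times evenly
        ## over a guaranteed span: sequence timing follows viewpoint
        ## geometry while the pooled peak distribution of such a cell
        ## can never collapse to a time-locked lump
        ## cue or delay (nav is too short for nine spaced peaks); the
        ## delay is favoured — memory-period sequences carry the target
        i <- sample(1:2, 1, prob = c(0.35, 0.65))
        reg <- c(regions[i, ], rw[i])
        ab <- rsign(2) * stats::runif(2, er[1], er[2])
        score <- ab[1] * scr$sx + ab[2] * scr$sy +
          stats::runif(9, -cfg$target_order_noise, cfg$target_order_noise)
        span <- min(stats::runif(1, cfg$target_span_range_s[1],
                                 cfg$target_span_range_s[2]), reg[3])
        b0 <- stats::runif(1, reg[1] + span / 2, reg[2] - span / 2)
        planted[u, ] <- b0 + (rank(score, ties.method = "first") - 5) /
          4 * (span / 2)
      },
      persistent = {
        pref_target[u] <- sample(0:8, 1)
      },
      unstructured = NULL
    )
  }
  planted <- fold_into(planted, 0.15, t_end - 0.15)

  ## ---- spikes: exact inhomogeneous-Poisson superposition sampling ----
  ## Counts are Poisson with mean equal to the integrated rate; event times
  ## are drawn iid from the normalized rate profile.
  grid_ut <- expand.grid(unit = seq_len(n), trial = seq_len(n_trials))
  tlab <- targ[grid_ut$trial] + 1L
  jit_mult <- ifelse(correct[grid_ut$trial], 1, cfg$incorrect_jitter_multiplier)

  spikes_u <- integer(0); spikes_tr <- integer(0); spikes_t <- numeric(0)
  add_spikes <- function(u, tr, t) {
    spikes_u <<- c(spikes_u, u)
    spikes_tr <<- c(spikes_tr, tr)
    spikes_t <<- c(spikes_t, t)
  }

  ## background / baseline: homogeneous over [0, iti_end)
  bg_rate <- ifelse(role[grid_ut$unit] == "persistent",
                    cfg$persistent_baseline_hz, cfg$background_rate_hz)
  nbg <- stats::rpois(nrow(grid_ut), bg_rate * t_iti_end)
  if (sum(nbg) > 0) {
    add_spikes(rep(grid_ut$unit, nbg), rep(grid_ut$trial, nbg),
               stats::runif(sum(nbg), 0, t_iti_end))
  }

  has_bump <- role[grid_ut$unit] %in% c("boundary", "row", "col", "target",
                                        "unstructured")
  if (any(has_bump)) {
    idx <- which(has_bump)
    u <- grid_ut$unit[idx]; tr <- grid_ut$trial[idx]
    if (cfg$mode == "unstructured") {
      mu <- stats::runif(length(idx), 0.2, t_end - 0.2)
    } else {
      mu <- planted[cbind(u, tlab[idx])] +
        stats::rnorm(length(idx), 0, cfg$peak_jitter_sd_s * jit_mult[idx])
      mu <- fold_into(mu, 0.05, t_end - 0.05)
    }
    ## integrated bump rate inside [0, t_end)
    cover <- stats::pnorm(t_end, mu, cfg$bump_sd_s) -
      stats::pnorm(0, mu, cfg$bump_sd_s)
    lam <- cfg$bump_amplitude_hz * cfg$bump_sd_s * sqrt(2 * pi) * cover
    nb <- stats::rpois(length(idx), lam)
    if (sum(nb) > 0) {
      st <- stats::rnorm(sum(nb), rep(mu, nb), cfg$bump_sd_s)
      keep <- st >= 0 & st < t_end
      add_spikes(rep(u, nb)[keep], rep(tr, nb)[keep], st[keep])
    }
  }

  is_pers <- role[grid_ut$unit] == "persistent"
  if (any(is_pers)) {
    idx <- which(is_pers & pref_target[grid_ut$unit] == targ[grid_ut$trial])
    if (length(idx) > 0) {
      extra <- cfg$persistent_tuned_rate_hz - cfg$persistent_baseline_hz
      ne <- stats::rpois(length(idx), extra * cfg$delay_s)
      if (sum(ne) > 0) {
        add_spikes(rep(grid_ut$unit[idx], ne), rep(grid_ut$trial[idx], ne),
                   stats::runif(sum(ne), t_delay, t_nav))
      }
    }
  }

  o <- order(spikes_u, spikes_tr, spikes_t)
  spikes <- data.frame(unit_id = spikes_u[o], trial_id = spikes_tr[o],
                       t_s = spikes_t[o])

  trajectories <- generate_trajectories(cfg, trials)

  units <- data.frame(unit_id = seq_len(n), role = role)
  session <- list(
    units = units,
    trials = trials,
    spikes = spikes,
    trajectories = trajectories,
    ground_truth = list(
      mode = cfg$mode,
      planted_peaks = planted,
      boundary_time = boundary_time,
      boundary_offsets_s = cfg$boundary_offsets_s,
      pref_target = pref_target,
      target_screen = scr,
      config = cfg
    )
  )
  class(session) <- "nas_session"
  session
}

#' Generate movement trajectories for a set of trials
#'
#' Produces 3D arena paths for each trial: straight-line travel from the
#' fixed start position to the trial's target at fixed speed, with smoothed
#' lateral noise tapered to zero at both endpoints so the path starts and
#' ends exactly on its endpoints.  Incorrect trials end off-target at a
#' perturbed endpoint roughly one target-spacing away from the true target.
#'
#' The 3x3 target grid is spaced `config$target_spacing` arena units apart,
#' and the default speed of two spacings per second makes the travel time
#' between adjacent targets 0.5 s.
#'
#' @param config a [nas_config()].
#' @param trials trial metadata data frame (as in a session's `trials`).
#' @return data frame with columns `trial_id`, `t_s`, `x`, `y`, `z`; times
#'   are seconds from cue onset, starting at navigation onset.
#' @export
generate_trajectories <- function(config, trials) {
  tw <- target_world_coords(config$target_spacing)
  tw <- tw[order(target_label(tw$row, tw$col)), ]
  out <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    lab <- target_label(trials$target_row[i], trials$target_col[i]) + 1L
    endpt <- c(tw$x[lab], tw$y[lab])
    if (!trials$correct[i]) {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 0.8, 1.6) * config$target_spacing
      endpt <- endpt + rad * c(cos(ang), sin(ang))
    }
    dist <- sqrt(sum(endpt^2))
    dur <- dist / config$speed
    nt <- max(2L, ceiling(dur * config$trajectory_hz) + 1L)
    frac <- seq(0, 1, length.out = nt)
    px <- endpt[1] * frac
    py <- endpt[2] * frac
    if (config$trajectory_noise_sd > 0 && nt > 4) {
      raw <- stats::rnorm(nt, 0, config$trajectory_noise_sd)
      sm <- stats::filter(raw, rep(1 / 5, 5), sides = 2)
      sm[is.na(sm)] <- 0
      lat <- as.numeric(sm) * sin(pi * frac)  # taper: exact endpoints
      perp <- c(-endpt[2], endpt[1]) / max(dist, 1e-9)
      px <- px + lat * perp[1]
      py <- py + lat * perp[2]
    }
    out[[i]] <- data.frame(
      trial_id = trials$trial_id[i],
      t_s = trials$t_nav_on[i] + (frac * dur),
      x = px, y = py, z = 0
    )
  }
  do.call(rbind, out)
}
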
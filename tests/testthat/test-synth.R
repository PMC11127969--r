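test_that("same config and seed give identical sessions", {
  cfg <- nas_config(n_units = 20, n_trials_per_target = 2, seed = 7)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$trajectories, s2$trajectories)
})

test_that("config validation rejects impossible settings", {
  expect_error(nas_config(frac_boundary_cells = 0.5,
                          frac_row_selective = 0.4,
                          frac_col_selective = 0.3),
               "configuration error")
  expect_error(nas_config(frac_row_selective = -0.1), "fractions")
  expect_error(nas_config(seed = 1.5), "seed")
  expect_error(nas_config(cue_s = 0), "cue_s")
})

test_that("background spike counts match the Poisson expectation", {
  # 5 Hz homogeneous background over the whole recorded window
  cfg <- nas_config(n_units = 2, n_trials_per_target = 112,
                    background_rate_hz = 5, bump_amplitude_hz = 1e-9,
                    mode = "unstructured", trajectory_noise_sd = 0,
                    seed = 21)
  s <- simulate_session(cfg)
  n_trials <- nrow(s$trials)
  expect_gte(n_trials, 1000)
  dur <- s$trials$t_end[1]
  counts <- table(factor(s$spikes$unit_id, levels = 1:2),
                  factor(s$spikes$trial_id, levels = s$trials$trial_id))
  in_window <- s$spikes$t_s < dur
  per_trial <- sum(in_window) / (2 * n_trials)
  expected <- 5 * dur            # 32.5 for the 6.5 s analysis window
  se <- sqrt(expected / (2 * n_trials))
  expect_lt(abs(per_trial - expected), 3 * se)
})

test_that("spike tables honor ordering and window invariants", {
  s <- small_session(seed = 3, incorrect_frac = 0.2)
  sp <- s$spikes
  key <- paste(sp$unit_id, sp$trial_id)
  dt <- diff(sp$t_s)
  same <- key[-1] == key[-length(key)]
  expect_true(all(dt[same] >= 0))
  expect_true(all(sp$t_s >= 0 & sp$t_s < s$trials$iti_end[1]))
  with(s$trials, {
    expect_true(all(t_cue_on < t_delay_on & t_delay_on < t_nav_on &
                      t_nav_on < t_end))
  })
  expect_equal(sum(!s$trials$correct) > 0, TRUE)
})

test_that("noiseless planting yields constant within-condition peaks", {
  cfg <- nas_config(n_units = 30, n_trials_per_target = 6,
                    peak_jitter_sd_s = 0, background_rate_hz = 0,
                    bump_amplitude_hz = 120, seed = 5)
  s <- simulate_session(cfg)
  gt <- s$ground_truth$planted_peaks
  expect_true(all(apply(gt, 1, function(x) all(x >= 0 & x < 6.5)),
                  na.rm = TRUE))
  seqs <- build_sequences(s, min_rate_hz = 0)
  lab <- s$trials$target_row * 3 + s$trials$target_col
  sds <- vapply(seq_len(ncol(seqs$S)), function(u)
    mean(tapply(seqs$S[, u], lab, stats::sd, na.rm = TRUE), na.rm = TRUE),
    numeric(1))
  # planted timing is exact; residual spread is density-estimation noise
  # from the finite Poisson bump draw, well under the kernel SD
  expect_lt(stats::median(sds, na.rm = TRUE), 0.05)
})

test_that("mode contracts shape the planted roles", {
  expect_setequal(unique(small_session(1)$units$role),
                  c("boundary", "row", "col", "target"))
  expect_setequal(unique(small_session(1, "perception_control")$units$role),
                  c("row", "col", "target"))
  expect_setequal(unique(small_session(1, "unstructured")$units$role),
                  "unstructured")
  roles <- small_session(1, "persistent")$units$role
  expect_setequal(unique(roles), c("boundary", "persistent"))
})

test_that("trajectories run to the target grid at fixed speed", {
  cfg <- nas_config(n_units = 5, n_trials_per_target = 1,
                    trajectory_noise_sd = 0, seed = 2)
  s <- simulate_session(cfg)
  tw <- s$trajectories
  for (i in seq_len(nrow(s$trials))) {
    tr <- s$trials[i, ]
    path <- tw[tw$trial_id == tr$trial_id, ]
    endpt <- unlist(path[nrow(path), c("x", "y")])
    target <- c((tr$target_col - 1) * 290, 580 + tr$target_row * 290)
    expect_equal(unname(endpt), target, tolerance = 1e-8)
    # fixed speed: duration = distance / 580
    dur <- max(path$t_s) - min(path$t_s)
    expect_equal(dur, sqrt(sum(target^2)) / 580, tolerance = 0.05)
  }
  # adjacent targets are 290 apart, i.e. 0.5 s of travel
  g <- expand.grid(row = 0:2, col = 0:2)
  xy <- cbind((g$col - 1) * 290, 580 + g$row * 290)
  d <- as.matrix(dist(xy))
  expect_equal(min(d[d > 0]), 290)
  expect_equal(min(d[d > 0]) / 580, 0.5)
})

test_that("incorrect trials end away from their target", {
  cfg <- nas_config(n_units = 5, n_trials_per_target = 3,
                    trajectory_noise_sd = 0, incorrect_frac = 1, seed = 8)
  s <- simulate_session(cfg)
  for (i in seq_len(min(5, nrow(s$trials)))) {
    tr <- s$trials[i, ]
    path <- s$trajectories[s$trajectories$trial_id == tr$trial_id, ]
    endpt <- unlist(path[nrow(path), c("x", "y")])
    target <- c((tr$target_col - 1) * 290, 580 + tr$target_row * 290)
    expect_gt(sqrt(sum((endpt - target)^2)), 0.5 * 290)
  }
})
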
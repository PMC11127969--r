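test_that("spike density matches the Gaussian closed form", {
  expect_equal(spike_density(numeric(0), c(0, 4))$value, rep(0, 4001))

  d <- spike_density(2.0, c(0, 4))
  expect_equal(d$time[which.max(d$value)], 2.0)
  expect_equal(max(d$value), 1 / (0.1 * sqrt(2 * pi)), tolerance = 1e-6)

  # two well-separated spikes: two equal local maxima at the spike times
  d2 <- spike_density(c(1, 3), c(0, 4))
  v1 <- d2$value[d2$time == 1]
  v3 <- d2$value[d2$time == 3]
  expect_equal(v1, v3, tolerance = 1e-9)
  expect_equal(max(d2$value), v1, tolerance = 1e-9)

  expect_error(spike_density(1, c(2, 2)), "window")
  expect_error(spike_density(c(3, 1), c(0, 4)), "sorted")
})

test_that("peak_time uses the earliest global maximum and NA for silence", {
  d <- spike_density(2.0, c(0, 4))
  expect_equal(peak_time(d), 2.0)
  zero <- structure(list(time = seq(0, 1, 0.001),
                         value = rep(0, 1001)), class = "nas_sdf")
  expect_true(is.na(peak_time(zero)))
  plateau <- structure(list(time = seq(0, 2, 0.001),
                            value = ifelse(seq(0, 2, 0.001) >= 1 &
                                             seq(0, 2, 0.001) <= 1.2,
                                           5, 0)), class = "nas_sdf")
  expect_equal(peak_time(plateau), 1.0)
})

test_that("peak times are shift-equivariant and kernel-scale stable", {
  spikes <- c(1.2, 1.25, 1.31, 2.4)
  base <- peak_time(spike_density(spikes, c(0, 6)))
  for (delta in c(0.5, 1.0, 2.2)) {
    shifted <- peak_time(spike_density(spikes + delta, c(0, 6)))
    expect_equal(shifted, base + delta, tolerance = 1e-9)
  }
  for (sd in c(0.05, 0.1, 0.2))
    expect_equal(peak_time(spike_density(2.0, c(0, 4), kernel_sd = sd)),
                 2.0)
})

test_that("build_sequences applies the rate criterion and keeps unit order", {
  units <- data.frame(unit_id = 1:3)
  trials <- data.frame(trial_id = 1:2, target_row = 0, target_col = 0:1,
                       t_cue_on = 0, t_delay_on = 3, t_nav_on = 5,
                       t_end = 6.5, correct = TRUE, iti_start = 6.5,
                       iti_end = 8.5)
  # unit 1 fires well, unit 2 never, unit 3 sparsely (below 0.5 Hz)
  spikes <- rbind(
    data.frame(unit_id = 1, trial_id = 1, t_s = seq(1, 6, by = 0.4)),
    data.frame(unit_id = 1, trial_id = 2, t_s = seq(1, 6, by = 0.4)),
    data.frame(unit_id = 3, trial_id = 1, t_s = 2.2))
  s <- nas_session(units, trials, spikes)
  seqs <- build_sequences(s)
  expect_equal(seqs$unit_id, 1L)
  # identical spike tables in both trials give identical vectors
  expect_equal(seqs$S[1, ], seqs$S[2, ])
  expect_error(build_sequences(s, min_rate_hz = 100), "criterion")
})

test_that("planted peaks are recovered within the kernel SD", {
  cfg <- nas_config(n_units = 60, n_trials_per_target = 20,
                    peak_jitter_sd_s = 0.05, seed = 13)
  s <- simulate_session(cfg)
  seqs <- build_sequences(s)
  gt <- s$ground_truth$planted_peaks[
    match(seqs$unit_id, s$units$unit_id), , drop = FALSE]
  lab <- s$trials$target_row * 3 + s$trials$target_col
  err <- abs(seqs$S - t(gt[, lab + 1, drop = FALSE]))
  expect_lt(mean(err, na.rm = TRUE), 0.1)
})

test_that("sorting units by peak time reproduces a monotone band", {
  fx <- planted_fixture()
  s <- fx$session; seqs <- fx$seqs
  rec_mean <- colMeans(seqs$S, na.rm = TRUE)
  gt <- s$ground_truth$planted_peaks[
    match(seqs$unit_id, s$units$unit_id), , drop = FALSE]
  planted_mean <- rowMeans(gt)
  ok <- !is.na(planted_mean)
  expect_gt(cor(rec_mean[ok], planted_mean[ok], method = "spearman"),
            0.9)
})

test_that("epoch masking is half-open and order-preserving", {
  S <- matrix(c(1.0, 2.0, 3.0, 4.999, 5.0, NA), nrow = 2, byrow = TRUE)
  seqs <- make_seqs(S)
  expect_equal(mask_epoch(seqs, c(0, 6.5))$S, S)
  expect_true(all(is.na(mask_epoch(seqs, c(2, 2))$S)))
  m <- mask_epoch(seqs, c(3, 5))$S
  expect_true(is.na(m[1, 1]) && is.na(m[1, 2]))  # below window
  expect_equal(m[1, 3], 3.0)                     # at start: retained
  expect_equal(m[2, 1], 4.999)
  expect_true(is.na(m[2, 2]))                    # at end: masked
  expect_error(mask_epoch(seqs, c(5, 3)), "window")
})

test_that("sequences export as a wide table with missing tokens", {
  seqs <- make_seqs(matrix(c(1, NA, 2, 3), 2))
  tab <- sequences_table(seqs)
  expect_equal(dim(tab), c(2L, 5L))
  expect_true(is.na(tab$u1[2]))
  tab2 <- sequences_table(seqs, missing_token = -1)
  expect_equal(tab2$u1[2], -1)
})
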
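test_that("peak_sd computes sample SDs per qualifying condition", {
  # 5 trials of one condition, 4 of another: the latter is excluded
  S <- matrix(NA_real_, 9, 2)
  S[1:5, 1] <- 2                      # constant peaks
  S[1:2, 2] <- c(1, 2)                # two non-missing peaks
  seqs <- make_seqs(S, target_row = c(rep(0, 5), rep(1, 4)),
                    target_col = rep(0, 9))
  tab <- peak_sd(seqs, min_trials = 5)
  expect_setequal(unique(tab$condition), 0)
  expect_equal(tab$sd_s[tab$unit_id == 1], 0)
  expect_equal(tab$sd_s[tab$unit_id == 2], sqrt(0.5), tolerance = 1e-12)

  # single non-missing peak -> missing SD
  S2 <- matrix(NA_real_, 5, 1); S2[1, 1] <- 2
  expect_true(is.na(peak_sd(make_seqs(S2), min_trials = 5)$sd_s))
  expect_error(peak_sd(make_seqs(S2), min_trials = 6), "at least")
})

test_that("within-trial shuffling is invariant when units are synchronous", {
  # every unit peaks at the same time within a trial: permuting the
  # assignment changes nothing
  S <- matrix(rep(seq(1, 2, length.out = 6), 4), 6, 4)
  seqs <- make_seqs(S)
  real <- peak_sd(seqs, min_trials = 5)
  shuf <- shuffle_null(seqs, n_repeats = 5, seed = 1, min_trials = 5)
  expect_equal(sort(unique(round(shuf$sd_s, 12))),
               sort(unique(round(real$sd_s, 12))))
  expect_equal(consistency_summary(real, shuf)$mean_difference_ms, 0,
               tolerance = 1e-9)
})

test_that("shuffle_null is reproducible and validates n_repeats", {
  fx <- planted_fixture()
  sub <- fx$seqs
  a <- shuffle_null(sub, n_repeats = 3, seed = 11)
  b <- shuffle_null(sub, n_repeats = 3, seed = 11)
  expect_identical(a, b)
  expect_error(shuffle_null(sub, n_repeats = 0, seed = 1), "n_repeats")
  # alternative semantics runs and differs from within-trial shuffling
  d <- shuffle_null(sub, n_repeats = 3, seed = 11,
                    semantics = "across_trial")
  expect_false(identical(a$sd_s, d$sd_s))
})

test_that("planted sessions fire more consistently than their shuffle null", {
  fx <- planted_fixture()
  real <- peak_sd(fx$seqs)
  shuf <- shuffle_null(fx$seqs, n_repeats = 30, seed = 2)
  sm <- consistency_summary(real, shuf)
  expect_gt(sm$mean_difference_ms, 200)
  # well above the leave-one-out null spread of the shuffled repeats
  null <- mean_difference_null(shuf)
  expect_gt(sm$mean_difference_ms, quantile(null, 0.975) + 100)
})

test_that("mean_difference is invariant to unit and trial relabeling", {
  fx <- planted_fixture()
  seqs <- fx$seqs
  real <- peak_sd(seqs)
  set.seed(4)
  perm_units <- sample(ncol(seqs$S))
  seqs2 <- seqs
  seqs2$S <- seqs$S[, perm_units]
  seqs2$unit_id <- seq_len(ncol(seqs$S))
  real2 <- peak_sd(seqs2)
  expect_equal(sort(round(real$sd_s, 10)), sort(round(real2$sd_s, 10)))
  shuf <- shuffle_null(seqs, n_repeats = 5, seed = 9)
  expect_equal(consistency_summary(real, shuf)$mean_difference_ms,
               consistency_summary(real2, shuf)$mean_difference_ms)
})

test_that("summary reports threshold fractions from best-condition SDs", {
  real <- data.frame(unit_id = rep(1:3, each = 2),
                     condition = rep(0:1, 3), n = 5,
                     sd_s = c(0.5, 2.0, 1.2, 1.4, 1.6, 1.9))
  shuf <- data.frame(unit_id = 1, condition = 0, n = 5, sd_s = 1.5,
                     repeat_id = 1)
  sm <- consistency_summary(real, shuf, thresholds_ms = c(1000, 1500))
  # best-condition SDs are 500, 1200, 1600 ms
  expect_equal(unname(sm$fraction_below["below_1000ms"]), 1 / 3)
  expect_equal(unname(sm$fraction_below["below_1500ms"]), 2 / 3)
  expect_error(consistency_summary(real[0, ], shuf), "empty")
})

test_that("consistency degrades monotonically with timing jitter", {
  md <- vapply(c(1, 2, 4), function(mult) {
    mean(vapply(1:4, function(sd) {
      s <- simulate_session(nas_config(
        n_units = 40, n_trials_per_target = 6, seed = 100 + sd,
        peak_jitter_sd_s = 0.1 * mult))
      seqs <- build_sequences(s)
      consistency_summary(
        peak_sd(seqs), shuffle_null(seqs, n_repeats = 5,
                                    seed = sd))$mean_difference_ms
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(md) < 0))
})
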
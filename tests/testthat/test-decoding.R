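test_that("nearest-centroid decoding separates what is separable", {
  set.seed(3)
  centers <- matrix(rnorm(9 * 3, sd = 10), 9, 3)
  labels <- rep(0:8, each = 20)
  P <- centers[labels + 1, ] + matrix(rnorm(length(labels) * 3, sd = 0.1),
                                      ncol = 3)
  dec <- nearest_centroid_cv(P, labels, k_folds = 5, seed = 1)
  expect_equal(dec$accuracy, 1.0)
  expect_equal(dec$chance, 1 / 9)

  # labels carrying no information decode at chance
  set.seed(4)
  Pn <- matrix(rnorm(1080 * 3), ncol = 3)
  ln <- sample(rep(0:8, each = 120))
  decn <- nearest_centroid_cv(Pn, ln, k_folds = 5, seed = 2)
  se <- sqrt((1 / 9) * (8 / 9) / length(ln))
  expect_lt(abs(decn$accuracy - 1 / 9), 3 * se)

  expect_error(nearest_centroid_cv(P[1:9, ], 0:8, k_folds = 5),
               "fewer trials")
})

test_that("decoder accuracy is invariant to rigid motions of the embedding", {
  set.seed(6)
  P <- matrix(rnorm(180 * 3), ncol = 3) +
    3 * matrix(rep(diag(3)[rep(1:3, each = 60), ], 1), ncol = 3)
  labels <- rep(1:3, each = 60)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  a1 <- nearest_centroid_cv(P, labels, seed = 5)$accuracy
  a2 <- nearest_centroid_cv(P %*% R, labels, seed = 5)$accuracy
  expect_equal(a1, a2)
})

test_that("epoch decoding recovers planted epoch structure", {
  fx <- planted_fixture()
  ed <- epoch_decode(fx$seqs, fx$bounds, seed = 1)
  expect_equal(ed$chance, 1 / 3)
  expect_gt(ed$accuracy, 0.9)
  edp <- epoch_decode(fx$seqs, fx$bounds, seed = 1, permute_labels = TRUE)
  expect_lt(abs(edp$accuracy - 1 / 3), 0.1)
  bad <- structure(list(boundaries = list(pre_delay = 0, pre_nav = 0)),
                   class = "nas_boundaries")
  expect_error(epoch_decode(fx$seqs, bad), "3 classes")
})

test_that("selectivity scores implement pooled-SD Cohen's d", {
  # unit 1: identical distributions; unit 2: means 1 and 2, common SD 0.5
  set.seed(8)
  n <- 6
  S <- cbind(rep(2, 2 * n),
             c(stats::rnorm(n, 1, 0.5), stats::rnorm(n, 2, 0.5)))
  S[, 2] <- c(scale(S[1:n, 2]) * 0.5 + 1, scale(S[n + 1:n, 2]) * 0.5 + 2)
  seqs <- make_seqs(S, target_row = rep(0:1, each = n),
                    target_col = rep(0, 2 * n))
  sc <- selectivity_scores(seqs, "row")
  expect_equal(sc$score[1], 0)
  expect_equal(sc$score[2], 2, tolerance = 1e-9)
  # degenerate zero pooled SD with unequal means
  S3 <- cbind(rep(c(1, 2), each = n))
  expect_warning(sc3 <- selectivity_scores(
    make_seqs(S3, target_row = rep(0:1, each = n),
              target_col = rep(0, 2 * n)), "row"), "Inf")
  expect_true(is.infinite(sc3$score[1]))

  # selected sets shrink as the percentile threshold rises
  scores <- data.frame(unit_id = 1:100, score = runif(100))
  s50 <- select_units(scores, 50)
  s90 <- select_units(scores, 90)
  expect_true(all(s90 %in% s50))
  expect_lt(length(s90), length(s50))
})

test_that("planted row-selective units score highest for rows", {
  fx <- planted_fixture()
  sc <- selectivity_scores(fx$seqs, "row")
  role <- fx$session$units$role[match(fx$seqs$unit_id,
                                      fx$session$units$unit_id)]
  expect_gt(mean(sc$score[role == "row"], na.rm = TRUE),
            mean(sc$score[role %in% c("boundary", "col")], na.rm = TRUE))
})

test_that("combined row x column decoding recovers planted targets", {
  fx <- planted_fixture()
  dec <- combined_target_decode(fx$seqs, seed = 2)
  expect_equal(dec$chance, 1 / 9)
  expect_gt(dec$combined_accuracy, 0.8)
  expect_gt(dec$all_cell$accuracy, 0.8)
  expect_equal(dec$row$chance, 1 / 3)
})

test_that("persistent cells are detected by rate tuning and elevation", {
  s <- simulate_session(nas_config(n_units = 40, n_trials_per_target = 10,
                                   seed = 23, mode = "persistent"))
  pc <- find_persistent_cells(s, p_threshold = 0.05)
  planted <- s$units$unit_id[s$units$role == "persistent"]
  expect_gt(mean(planted %in% pc$members), 0.9)
  # membership grows monotonically as the threshold relaxes
  m1 <- find_persistent_cells(s, 0.001)$members
  m2 <- find_persistent_cells(s, 0.01)$members
  m3 <- find_persistent_cells(s, 0.05)$members
  expect_true(all(m1 %in% m2) && all(m2 %in% m3))
  # homogeneous units produce few false positives
  s0 <- simulate_session(nas_config(n_units = 60, n_trials_per_target = 8,
                                    background_rate_hz = 3,
                                    bump_amplitude_hz = 1e-9,
                                    mode = "unstructured", seed = 29))
  pc0 <- find_persistent_cells(s0, 0.05)
  expect_lt(length(pc0$members) / 60, 0.08)
  bad <- s
  bad$trials$iti_end <- bad$trials$iti_start
  expect_error(find_persistent_cells(bad), "inter-trial")
})

test_that("each code wins on its matched session mode", {
  seq_s <- simulate_session(nas_config(n_units = 60,
                                       n_trials_per_target = 10,
                                       seed = 31))
  pers_s <- simulate_session(nas_config(n_units = 60,
                                        n_trials_per_target = 10,
                                        seed = 31, mode = "persistent"))
  cc_seq <- compare_codes(seq_s, folds = 5, seed = 1)
  cc_pers <- compare_codes(pers_s, folds = 5, seed = 1)
  acc <- function(d) if (is.null(d)) 1 / 9 else d$accuracy
  expect_gt(cc_seq$sequence$accuracy, acc(cc_seq$persistent))
  expect_gte(acc(cc_pers$persistent), cc_pers$sequence$accuracy)
  expect_gt(acc(cc_pers$persistent), 0.8)
})

test_that("same-trial replay ranking behaves at its extremes", {
  set.seed(41)
  D <- matrix(runif(40 * 30), 40, 30)
  expect_equal(same_trial_replay_test(D, D)$fraction, 1.0)
  N <- matrix(runif(40 * 30), 40, 30)
  r <- same_trial_replay_test(D, N)
  expect_lt(abs(r$fraction - 0.05), 0.12)
  expect_error(same_trial_replay_test(D[1, , drop = FALSE],
                                      N[1, , drop = FALSE]), "2 trials")
})
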
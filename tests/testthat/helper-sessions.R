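# Shared fixtures, generated in code and cached for the test run.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# medium planted session reused across module tests (built once)
planted_fixture <- function() {
  cached("planted", {
    session <- simulate_session(nas_config(n_units = 120,
                                           n_trials_per_target = 10,
                                           seed = 42))
    seqs <- build_sequences(session)
    bounds <- boundary_analysis(seqs)
    delay_seqs <- mask_epoch(seqs, epoch_windows(bounds, session$trials)$delay)
    list(session = session, seqs = seqs, bounds = bounds,
         delay_seqs = delay_seqs,
         emb = embed_session(delay_seqs),
         frechet = screen_frechet_matrix(session))
  })
}

small_session <- function(seed = 1, mode = "sequence", n_units = 50,
                          n_trials_per_target = 6, ...) {
  simulate_session(nas_config(n_units = n_units,
                              n_trials_per_target = n_trials_per_target,
                              seed = seed, mode = mode, ...))
}

# hand-built sequences object (trials x units matrix + metadata)
make_seqs <- function(S, target_row = NULL, target_col = NULL,
                      correct = NULL, t_end = 6.5) {
  n <- nrow(S)
  if (is.null(target_row)) target_row <- rep(0L, n)
  if (is.null(target_col)) target_col <- rep(0L, n)
  if (is.null(correct)) correct <- rep(TRUE, n)
  trials <- data.frame(trial_id = seq_len(n), target_row = target_row,
                       target_col = target_col, t_cue_on = 0,
                       t_delay_on = 3, t_nav_on = 5, t_end = t_end,
                       correct = correct, iti_start = t_end,
                       iti_end = t_end + 2)
  structure(list(S = S, trial_id = trials$trial_id,
                 unit_id = seq_len(ncol(S)), trials = trials,
                 t_end = t_end, kernel_sd = 0.1, step = 0.001),
            class = "nas_sequences")
}

# exhaustive brute-force discrete Frechet: enumerate every monotone
# coupling path and minimize the maximal leash (no memoization)
frechet_brute <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  n <- nrow(A); m <- nrow(B)
  G <- sqrt(outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B))
  G[G < 0 | is.na(G)] <- 0
  rec <- function(i, j) {
    if (i == n && j == m) return(G[i, j])
    best <- Inf
    if (i < n) best <- min(best, rec(i + 1, j))
    if (j < m) best <- min(best, rec(i, j + 1))
    if (i < n && j < m) best <- min(best, rec(i + 1, j + 1))
    max(G[i, j], best)
  }
  rec(1, 1)
}

# leave-one-out null for the consistency mean difference: treat each
# shuffle repeat as pseudo-real data against the pooled remainder
mean_difference_null <- function(shuffled) {
  reps <- unique(shuffled$repeat_id)
  vapply(reps, function(r) {
    a <- shuffled$sd_s[shuffled$repeat_id == r]
    b <- shuffled$sd_s[shuffled$repeat_id != r]
    1000 * (mean(b, na.rm = TRUE) - mean(a, na.rm = TRUE))
  }, numeric(1))
}
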
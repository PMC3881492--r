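# Shared fixture builders. Everything is generated in code from fixed
# seeds; no data files.

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# k equal-length random targets
toy_targets <- function(k = 2L, len = 100L, seed = 7) {
  set.seed(seed)
  lapply(seq_len(k), function(i) {
    target_record(sprintf("t%02d", i), i - 1L, seq = random_seq(len))
  })
}

# an error-free single-end fragment aligned (at position 0) to each target
# id in `tids`
toy_fragment <- function(name, tids, read_len = 10L, pos = 0L) {
  alns <- lapply(tids, function(t) {
    fragment_alignment(t, read_l = read_alignment(TRUE, pos, pos + read_len - 1L))
  })
  fragment_record(name, FALSE, alns)
}

# the closed-form instance: unique counts (3, 1) on two equal-length
# targets plus 4 fragments shared between both
toy_closedform <- function() {
  targets <- toy_targets(2L)
  frags <- c(lapply(1:3, function(i) toy_fragment(paste0("a", i), 0L)),
             list(toy_fragment("b1", 1L)),
             lapply(1:4, function(i) toy_fragment(paste0("s", i), c(0L, 1L))))
  list(targets = targets, fragments = frags)
}

# config with all auxiliaries frozen from the start (uniform), no bias
frozen_cfg <- function(...) {
  em_config(bias_enabled = FALSE, aux_full_iters = 0L, aux_freeze_at = 0L, ...)
}

# random multi-target instance over equal-length targets: every unique
# count >= 1, plus random ambiguous fragments
random_rescue_instance <- function(seed) {
  set.seed(seed)
  k <- sample(3:6, 1L)
  targets <- toy_targets(k, len = 120L, seed = seed + 1000L)
  uniq <- sample(1:6, k, replace = TRUE)
  frags <- list()
  for (t in seq_len(k)) {
    for (j in seq_len(uniq[t])) {
      frags[[length(frags) + 1L]] <- toy_fragment(sprintf("u%d_%d", t, j), t - 1L)
    }
  }
  n_amb <- sample(3:8, 1L)
  for (j in seq_len(n_amb)) {
    ts <- sort(sample(0:(k - 1L), sample(2:k, 1L)))
    frags[[length(frags) + 1L]] <- toy_fragment(sprintf("amb%d", j), ts)
  }
  list(targets = targets, fragments = frags, unique_counts = uniq)
}

# small simulated dataset for pipeline-level tests
small_sim <- function(seed = 5, n_fragments = 3000L, bias_strength = 0, ...) {
  cfg <- sim_config(n_targets = 45L, n_groups = 15L, len_range = c(300L, 600L),
                    n_fragments = n_fragments, fld_mean = 150, fld_sd = 25,
                    bias_strength = bias_strength, seed = seed, ...)
  tg <- simulate_targets(cfg)
  sim <- simulate_experiment(tg, cfg)
  list(cfg = cfg, targets = tg, fragments = sim$fragments, truth = sim$truth)
}

# independent grid-search oracle for the 2-target likelihood with shared
# fragments: maximizes u1 log(tau) + u2 log(1-tau) (+ constant shared term)
grid_oracle_2target <- function(u1, u2, step = 1e-4) {
  tau <- seq(step, 1 - step, by = step)
  ll <- u1 * log(tau) + u2 * log(1 - tau)
  tau[which.max(ll)]
}
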
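# EM engine: M-step smoothing, freezing schedule, convergence rule,
# E-step posteriors, the full loop against grid-search oracles, and the
# rescue reference method.

test_that("M-step normalization applies Laplace smoothing", {
  expect_equal(m_step_normalize(c(3, 1), 1), c(4 / 6, 2 / 6))
  expect_equal(m_step_normalize(c(0, 0, 0), 1), rep(1 / 3, 3))
  for (i in 1:5) {
    set.seed(i)
    x <- m_step_normalize(runif(7) * 10, runif(1))
    expect_equal(sum(x), 1)
    expect_true(all(x > 0))
  }
  expect_error(m_step_normalize(c(-1, 2), 1), "negative")
})

test_that("auxiliary updates follow the 20 / every-100 / freeze-at-1000 schedule", {
  cfg <- em_config()
  expect_true(aux_update_due(5, cfg))
  expect_true(aux_update_due(20, cfg))
  expect_false(aux_update_due(21, cfg))
  expect_true(aux_update_due(100, cfg))
  expect_false(aux_update_due(150, cfg))
  expect_true(aux_update_due(1000, cfg))
  expect_false(aux_update_due(1100, cfg))
  due <- vapply(1:1200, aux_update_due, logical(1), cfg = cfg)
  expect_identical(which(due), c(1:20, seq(100L, 1000L, by = 100L)))
})

test_that("convergence requires <= 1e-2 relative change on targets above the 1e-7 floor", {
  cfg <- em_config()
  expect_true(check_convergence(c(0.6, 0.4), c(0.6, 0.4), cfg))
  # changes of 1.0% and 1.5%: not converged
  expect_false(check_convergence(c(0.6, 0.4), c(0.606, 0.394), cfg))
  # a tiny target moving a lot below the floor is ignored
  prev <- c(0.7, 0.3 - 5e-8, 5e-8)
  curr <- c(0.7 - 4e-8, 0.3 - 9e-8, 9e-8)
  expect_true(check_convergence(prev, curr, cfg))
  expect_error(check_convergence(c(0.5, 0.5), c(1)), "length")
})

test_that("single-fragment E-step gives normalized posteriors and conserving counts", {
  targets <- toy_targets(3L, len = 150L, seed = 13)
  params <- new_model_params(3, bias_enabled = FALSE)
  cfg <- em_config(bias_enabled = FALSE)
  one <- e_step_fragment(toy_fragment("u", 1L), params, targets, cfg)
  expect_equal(one$posteriors, 1.0)
  expect_equal(one$contribution$counts, c(0, 1, 0))
  two <- e_step_fragment(toy_fragment("s", c(0L, 2L)), params, targets, cfg)
  expect_equal(two$posteriors, c(0.5, 0.5))
  # with uniform auxiliaries and equal lengths posteriors reduce to tau
  p2 <- fragem:::.params_set_tau(params, c(0.8, 1e-12, 0.2))
  post <- e_step_fragment(toy_fragment("s", c(0L, 2L)), p2, targets, cfg)$posteriors
  expect_equal(post, c(0.8, 0.2), tolerance = 1e-9)
  expect_error(e_step_fragment(structure(list(name = "x", paired = FALSE,
                                              alignments = list()),
                                         class = "fragment_record"),
                               params, targets, cfg), "zero alignments")
})

test_that("engine E-step matches the record-at-a-time reference implementation", {
  sm <- small_sim(seed = 51, n_fragments = 150L)
  cfg <- em_config(bias_enabled = TRUE)
  params <- new_model_params(length(sm$targets))
  set.seed(2)
  params <- fragem:::.params_set_tau(params, {
    x <- rgamma(length(sm$targets), 1); x / sum(x)
  })
  part <- partition_fragments(sm$fragments, 1e9)[[1]]
  eng <- map_partition_estep(part, broadcast_params(params, 1L), sm$targets, cfg)
  ref <- Reduce(fragem:::.acc_add,
                lapply(sm$fragments,
                       function(f) e_step_fragment(f, params, sm$targets, cfg)$contribution))
  expect_equal(eng$counts, ref$counts, tolerance = 1e-10)
  expect_equal(eng$fld_counts, ref$fld_counts, tolerance = 1e-10)
  expect_equal(eng$err_counts, ref$err_counts, tolerance = 1e-10)
  expect_equal(eng$b5_counts, ref$b5_counts, tolerance = 1e-10)
  expect_equal(eng$b3_counts, ref$b3_counts, tolerance = 1e-10)
  expect_equal(eng$loglik, ref$loglik, tolerance = 1e-10)
})

test_that("EM recovers the closed-form optimum on the 2-target toy", {
  toy <- toy_closedform()
  res <- run_em(toy$fragments, toy$targets,
                frozen_cfg(max_rel_change = 1e-6, max_iters = 500L))
  expect_true(res$converged)
  # independent oracle: grid search over the 1-parameter likelihood
  # (the 4 perfectly shared fragments contribute a constant)
  oracle <- grid_oracle_2target(3, 1)
  expect_equal(oracle, 0.75, tolerance = 1e-4 / 2)
  expect_equal(res$tau, c(0.75, 0.25), tolerance = 1e-3)
  expect_equal(sum(res$counts), 8)
})

test_that("EM matches a grid-search oracle on a 3-target instance with frozen auxiliaries", {
  targets <- toy_targets(3L, len = 150L, seed = 17)
  frags <- c(lapply(1:5, function(i) toy_fragment(paste0("a", i), 0L)),
             lapply(1:2, function(i) toy_fragment(paste0("b", i), 1L)),
             lapply(1:1, function(i) toy_fragment(paste0("c", i), 2L)),
             lapply(1:6, function(i) toy_fragment(paste0("ab", i), c(0L, 1L))),
             lapply(1:3, function(i) toy_fragment(paste0("bc", i), c(1L, 2L))))
  res <- run_em(frags, targets, frozen_cfg(max_rel_change = 1e-8, max_iters = 2000L,
                                           abundance_pseudocount = 1e-300))
  # oracle: 2-parameter grid over the log-linear objective
  grid <- seq(0.001, 0.999, by = 0.001)
  best <- c(NA, NA, NA); best_ll <- -Inf
  for (t1 in grid) for (t2 in grid[grid < 1 - t1]) {
    t3 <- 1 - t1 - t2
    ll <- 5 * log(t1) + 2 * log(t2) + 1 * log(t3) +
      6 * log(t1 + t2) + 3 * log(t2 + t3)
    if (ll > best_ll) { best_ll <- ll; best <- c(t1, t2, t3) }
  }
  expect_equal(res$tau, best, tolerance = 2e-3)
})

test_that("rescue splits ambiguous fragments by unique counts with uniform tie-break", {
  toy <- toy_closedform()
  expect_equal(run_rescue(toy$fragments, toy$targets), c(6, 2))
  # no ambiguous fragments: totals equal unique counts
  uonly <- toy$fragments[1:4]
  expect_equal(run_rescue(uonly, toy$targets), c(3, 1))
  # all-zero unique counts: uniform split
  targets <- toy_targets(3L, seed = 19)
  amb <- list(toy_fragment("s1", c(0L, 1L, 2L)), toy_fragment("s2", c(0L, 2L)))
  expect_equal(run_rescue(amb, targets), c(1 / 3 + 1 / 2, 1 / 3, 1 / 3 + 1 / 2))
})

test_that("rescue equals a single E-step initialized at the unique-count abundances", {
  for (seed in 1:10) {
    inst <- random_rescue_instance(seed)
    rc <- run_rescue(inst$fragments, inst$targets)
    init <- inst$unique_counts / sum(inst$unique_counts)
    r1 <- run_em(inst$fragments, inst$targets,
                 frozen_cfg(abundance_pseudocount = 1e-300),
                 init_tau = init, n_iters = 1L)
    expect_equal(r1$counts, rc, tolerance = 1e-9)
  }
})

test_that("log-likelihood is non-decreasing and mass is conserved with frozen auxiliaries", {
  sm <- small_sim(seed = 61, n_fragments = 2000L)
  res <- run_em(sm$fragments, sm$targets, frozen_cfg(), n_iters = 60L)
  expect_true(all(diff(res$loglik_trace) > -1e-7 * abs(res$loglik_trace[-1])))
  expect_true(all(abs(res$mass_trace - length(sm$fragments)) < 1e-6))
  expect_equal(sum(res$params$tau), 1, tolerance = 1e-12)
  expect_true(all(res$params$tau > 0))
})

test_that("one further iteration after convergence stays within the threshold", {
  sm <- small_sim(seed = 71, n_fragments = 2000L)
  cfg <- frozen_cfg()   # frozen auxiliaries: the restarted iteration sees
                        # the same (uniform) auxiliaries the run converged under
  res <- run_em(sm$fragments, sm$targets, cfg)
  expect_true(res$converged)
  more <- run_em(sm$fragments, sm$targets, cfg, init_tau = res$tau, n_iters = 1L)
  sel <- more$params$tau >= cfg$min_prob
  rel <- abs(more$params$tau[sel] - res$tau[sel]) / res$tau[sel]
  expect_true(all(rel <= cfg$max_rel_change))
})

test_that("expected bias chains equal empirical window frequencies under uniform weights", {
  t1 <- list(target_record("t", 0L, seq = random_seq(400, seed = 23)))
  cfg <- em_config(bias_enabled = TRUE, pseudocount = 1e-9)
  params <- new_model_params(1, bias_enabled = TRUE,
                             bias_order = cfg$bias_order)
  up <- update_bias_expected(t1, params, cfg)
  # direct empirical frequency oracle: count (slot, nucleotide) pairs over
  # all full sliding windows, weighted by the fld mass at each anchor
  tmpl <- fragem:::.chain_uniform(cfg$bias_up, cfg$bias_down, cfg$bias_order)
  codes <- fragem:::.unpack_codes(t1[[1]]$seq, 400L)
  m <- fragem:::.chain_slot_idx(tmpl, codes, 0:399)
  cumF <- cumsum(params$fld$pmf)
  F5 <- function(x) { o <- cumF[pmax(pmin(x, 800L), 1L)]; o[x <= 0] <- 0; o }
  w <- F5(400L - 0:399)
  cnt <- numeric(tmpl$n)
  for (j in seq_len(ncol(m))) {
    ok <- !is.na(m[, j])
    cs <- rowsum(w[ok], m[ok, j])
    cnt[as.integer(rownames(cs))] <- cnt[as.integer(rownames(cs))] + cs[, 1]
  }
  grp <- rep(seq_len(tmpl$n %/% 4L), each = 4L)
  tot <- rowsum(cnt, grp)
  expected <- cnt / tot[grp]
  expect_equal(up$bias$exp5$p, expected, tolerance = 1e-6)
  # duplicating the target leaves the expected chains unchanged
  t2 <- list(t1[[1]], target_record("t2", 1L, seq = random_seq(400, seed = 23)))
  p2 <- new_model_params(2, bias_enabled = TRUE, bias_order = cfg$bias_order)
  p2 <- fragem:::.params_set_tau(p2, c(0.9, 0.1))
  up2 <- update_bias_expected(t2, p2, cfg)
  expect_equal(up2$bias$exp5$p, up$bias$exp5$p, tolerance = 1e-9)
})

test_that("on unbiased data the learned bias weights stay near one", {
  sm <- small_sim(seed = 81, n_fragments = 4000L)
  res <- run_em(sm$fragments, sm$targets, em_config(bias_enabled = TRUE))
  lw <- log(res$params$bias$obs5$p) - log(res$params$bias$exp5$p)
  # positional weights: no systematic deviation beyond sampling noise
  expect_lt(mean(abs(lw)), 0.2)
  expect_lt(max(abs(lw)), 1.0)
})
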
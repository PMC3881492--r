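# Generative simulator and the idealized exhaustive aligner.

test_that("target simulation is seed-deterministic with lengths in range", {
  cfg <- sim_config(n_targets = 30L, n_groups = 10L, len_range = c(300L, 600L),
                    seed = 7)
  t1 <- simulate_targets(cfg)
  t2 <- simulate_targets(cfg)
  expect_identical(t1, t2)
  lens <- vapply(t1, `[[`, integer(1), "length")
  expect_true(all(lens >= 300L & lens <= 600L))
  expect_identical(vapply(t1, `[[`, integer(1), "id"), 0:29)
  # shared_frac >= 1 is rejected
  expect_error(sim_config(shared_frac = 1), "shared_frac")
})

test_that("with shared fraction zero no fragment-length k-mer is shared between targets", {
  cfg <- sim_config(n_targets = 20L, n_groups = 5L, shared_frac = 0,
                    len_range = c(300L, 500L), seed = 9)
  tg <- simulate_targets(cfg)
  k <- 50L
  kmers <- lapply(tg, function(t) {
    s <- unpack_nucleotides(t$seq, t$length)
    vapply(1:(t$length - k + 1L), function(p) substr(s, p, p + k - 1L), character(1))
  })
  tab <- table(unlist(lapply(kmers, unique)))
  expect_true(all(tab == 1L))   # exhaustive k-mer index: no cross-target hits
})

test_that("group members share an identical internal segment inducing ambiguity", {
  cfg <- sim_config(n_targets = 6L, n_groups = 2L, shared_frac = 0.5,
                    len_range = c(400L, 500L), n_fragments = 300L,
                    fld_mean = 150, fld_sd = 20, seed = 13)
  tg <- simulate_targets(cfg)
  sim <- simulate_experiment(tg, cfg)
  n_multi <- sum(vapply(sim$fragments, function(f) {
    length(unique(vapply(f$alignments, `[[`, integer(1), "target_id"))) > 1L
  }, logical(1)))
  expect_gt(n_multi, 10L)
})

test_that("error-free simulation reconstructs reference windows exactly", {
  cfg <- sim_config(n_targets = 10L, n_groups = 5L, n_fragments = 300L,
                    len_range = c(300L, 400L), fld_mean = 150, fld_sd = 20,
                    error_rate = 0, seed = 15)
  tg <- simulate_targets(cfg)
  sim <- simulate_experiment(tg, cfg)
  expect_identical(sim$truth$n_dropped, 0L)
  # every fragment keeps a mismatch-free placement (its true origin);
  # other reported placements are near-misses within the threshold
  has_exact <- vapply(sim$fragments, function(f) {
    any(vapply(f$alignments, function(a) {
      length(a$read_l$mismatch_indices) + length(a$read_r$mismatch_indices) == 0L
    }, logical(1)))
  }, logical(1))
  expect_true(all(has_exact))
  worst <- max(vapply(sim$fragments, function(f) {
    max(vapply(f$alignments, function(a) {
      max(length(a$read_l$mismatch_indices), length(a$read_r$mismatch_indices))
    }, integer(1)))
  }, integer(1)))
  expect_lte(worst, cfg$max_mismatches)
})

test_that("realized per-target counts follow the multinomial within 4 sigma over seeds", {
  worst <- 0
  for (seed in 1:20) {
    cfg <- sim_config(n_targets = 20L, n_groups = 20L, n_fragments = 2000L,
                      len_range = c(300L, 400L), seed = seed)
    tg <- simulate_targets(cfg)
    # truth draw happens inside simulate_experiment; cheap because the
    # heavy part (alignment) is skipped by simulating few fragments
    sim <- simulate_experiment(tg, cfg)
    mu <- cfg$n_fragments * sim$truth$tau
    sd <- sqrt(cfg$n_fragments * sim$truth$tau * (1 - sim$truth$tau))
    z <- abs(sim$truth$counts - mu) / pmax(sd, 1e-9)
    worst <- max(worst, max(z[mu > 5]))
  }
  expect_lt(worst, 4)
})

test_that("unbiased simulations have background 5'-end window frequencies", {
  cfg <- sim_config(n_targets = 10L, n_groups = 10L, n_fragments = 8000L,
                    len_range = c(500L, 800L), seed = 17)
  tg <- simulate_targets(cfg)
  sim <- simulate_experiment(tg, cfg)
  # direct counting oracle: nucleotide at the 5' end base across fragments
  # versus the position-available background of the same targets
  tseqs <- lapply(tg, function(t) fragem:::.unpack_codes(t$seq, t$length))
  endnuc <- integer(0)
  for (f in sim$fragments) {
    a <- f$alignments[[1]]
    endnuc <- c(endnuc, tseqs[[a$target_id + 1L]][a$read_l$left_pos + 1L])
  }
  obs <- tabulate(endnuc + 1L, nbins = 4L)
  bg <- tabulate(unlist(tseqs) + 1L, nbins = 4L)
  p_bg <- bg / sum(bg)
  mu <- length(endnuc) * p_bg
  z <- abs(obs - mu) / sqrt(length(endnuc) * p_bg * (1 - p_bg))
  expect_true(all(z < 3.5))
})

test_that("the exhaustive aligner finds exactly the placements within the threshold", {
  cfg <- sim_config(n_targets = 6L, n_groups = 2L, shared_frac = 0.6,
                    len_range = c(400L, 500L), seed = 19)
  tg <- simulate_targets(cfg)
  tseqs <- lapply(tg, function(t) unpack_nucleotides(t$seq, t$length))
  # a read from a flank (outside the shared segment w.h.p. at the very start)
  r_uniq <- substr(tseqs[[1]], 1, 76)
  hits <- emulate_aligner(r_uniq, tg, max_mismatches = 3L)
  expect_length(hits, 1L)
  expect_identical(hits[[1]]$target_id, 0L)
  expect_identical(hits[[1]]$read_l$left_pos, 0L)
  # brute-force oracle on a small instance: all placements <= 2 mismatches
  small_tg <- lapply(1:2, function(i) {
    target_record(paste0("s", i), i - 1L, seq = random_seq(200, seed = 20 + i))
  })
  sseqs <- lapply(small_tg, function(t) unpack_nucleotides(t$seq, t$length))
  read <- substr(sseqs[[2]], 50, 50 + 39)   # 40-nt read
  brute <- list()
  for (t in 1:2) for (p in 1:(200 - 40 + 1)) {
    w <- substr(sseqs[[t]], p, p + 39)
    mm <- sum(fragem:::nuc_codes(w) != fragem:::nuc_codes(read))
    if (mm <= 2) brute[[length(brute) + 1L]] <- c(t - 1L, p - 1L)
  }
  got <- emulate_aligner(read, small_tg, max_mismatches = 2L)
  got_keys <- sort(vapply(got, function(a) {
    a$target_id * 1000L + a$read_l$left_pos
  }, integer(1)))
  brute_keys <- sort(vapply(brute, function(x) x[1] * 1000L + x[2], integer(1)))
  expect_identical(got_keys, brute_keys)
})

test_that("a read with more errors than the threshold at its only locus is dropped", {
  tg <- list(target_record("only", 0L, seq = random_seq(300, seed = 25)))
  s <- unpack_nucleotides(tg[[1]]$seq, 300)
  read <- substr(s, 10, 85)
  codes <- fragem:::nuc_codes(read)
  at <- c(5L, 20L, 40L, 60L)                  # 4 planted substitutions
  codes[at] <- (codes[at] + 1L) %% 4L
  bad <- fragem:::codes_to_string(codes)
  expect_length(emulate_aligner(bad, tg, max_mismatches = 3L), 0L)
  expect_length(emulate_aligner(bad, tg, max_mismatches = 4L), 1L)
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- sim_config(n_targets = 10L, n_groups = 5L, n_fragments = 200L,
                    len_range = c(300L, 400L), bias_strength = 0.5, seed = 29)
  tg <- simulate_targets(cfg)
  s1 <- simulate_experiment(tg, cfg)
  s2 <- simulate_experiment(tg, cfg)
  expect_identical(s1$fragments, s2$fragments)
  expect_identical(s1$truth, s2$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_experiment(tg, cfg, out_dir = d1)
  simulate_experiment(tg, cfg, out_dir = d2)
  for (f in c("targets.fa", "fragments.sam", "fragments.pb64", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})
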
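# Generative simulator. Produces targets organized into isoform-like
# groups that share an identical internal segment (the source of
# ambiguous fragments), draws ground-truth abundances from a symmetric
# Dirichlet, samples fragments from the generative model (optionally with
# sequence-specific bias at the 5' end), applies i.i.d. substitution
# errors, and aligns the reads back with the idealized exhaustive aligner
# so that the produced records carry genuine multi-mapping structure.

#' Simulator configuration
#'
#' Defaults describe the desk-scale study condition: 300 targets in 100
#' isoform groups sharing half their minimum length, 50,000 paired-end
#' fragments of truncated-normal length 200 +/- 40, 76-nt reads, 0.5%
#' per-base substitution error, abundances from a symmetric
#' Dirichlet(0.3).
#'
#' @param n_targets Number of targets.
#' @param len_range Target length range (uniform draw), both ends >=
#'   `read_len`.
#' @param n_groups Number of isoform groups (targets per group share an
#'   identical internal segment).
#' @param shared_frac Fraction (in `[0,1)`) of the group's minimum target
#'   length used as the shared segment; 0 means fully independent targets.
#' @param n_fragments Number of fragments to simulate.
#' @param fld_mean,fld_sd Mean/sd of the truncated-normal fragment length
#'   law (truncated to `[read_len, min(max_frag_len, target length)]`).
#' @param read_len Read length (both ends).
#' @param error_rate Per-base substitution probability.
#' @param bias_strength In `[0,1]`: exponent on the 5'-end sequence bias
#'   weights; 0 gives an unbiased dataset.
#' @param alpha Symmetric Dirichlet concentration for the molar abundance
#'   draw.
#' @param paired Sequence both ends?
#' @param max_mismatches Aligner mismatch threshold.
#' @param max_frag_len Upper fragment length bound (pairing and fld
#'   support).
#' @param seed Integer seed; the full simulation is reproducible from it.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_targets = 300L, len_range = c(500L, 1500L),
                       n_groups = 100L, shared_frac = 0.5,
                       n_fragments = 50000L,
                       fld_mean = 200, fld_sd = 40, read_len = 76L,
                       error_rate = 0.005, bias_strength = 0,
                       alpha = 0.3, paired = TRUE,
                       max_mismatches = 3L, max_frag_len = 800L,
                       seed = 1L) {
  stopifnot(n_targets >= 1L, n_groups >= 1L, n_groups <= n_targets,
            length(len_range) == 2L, len_range[1L] <= len_range[2L],
            len_range[1L] >= read_len,
            n_fragments >= 1L, fld_mean > 0, fld_sd > 0,
            read_len >= 8L, error_rate >= 0, error_rate < 1,
            bias_strength >= 0, bias_strength <= 1, alpha > 0)
  if (shared_frac < 0 || shared_frac >= 1) {
    stop("shared_frac must be in [0, 1)", call. = FALSE)
  }
  structure(list(n_targets = as.integer(n_targets),
                 len_range = as.integer(len_range),
                 n_groups = as.integer(n_groups), shared_frac = shared_frac,
                 n_fragments = as.integer(n_fragments),
                 fld_mean = fld_mean, fld_sd = fld_sd,
                 read_len = as.integer(read_len),
                 error_rate = error_rate, bias_strength = bias_strength,
                 alpha = alpha, paired = isTRUE(paired),
                 max_mismatches = as.integer(max_mismatches),
                 max_frag_len = as.integer(max_frag_len),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a target set with shared segments
#'
#' Draws `n_targets` random sequences with lengths uniform in
#' `len_range`, grouped into `n_groups` groups. Within a group an
#' identical internal segment of `shared_frac` times the group's minimum
#' length is planted at a random offset of every member, so fragments
#' falling inside it are ambiguous by construction. Deterministic given
#' the config seed.
#'
#' @param cfg A [sim_config()].
#' @return List of [target_record()]s (ids `0..n_targets-1`).
#' @export
simulate_targets <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_targets
  lens <- sample(cfg$len_range[1L]:cfg$len_range[2L], n, replace = TRUE)
  group <- sort(rep(seq_len(cfg$n_groups), length.out = n))
  codes <- lapply(lens, function(L) sample(0:3, L, replace = TRUE))
  if (cfg$shared_frac > 0) {
    for (g in seq_len(cfg$n_groups)) {
      members <- which(group == g)
      if (length(members) < 2L) next
      S <- floor(cfg$shared_frac * min(lens[members]))
      if (S < 1L) next
      shared <- sample(0:3, S, replace = TRUE)
      for (m in members) {
        s0 <- sample.int(lens[m] - S + 1L, 1L)
        codes[[m]][s0:(s0 + S - 1L)] <- shared
      }
    }
  }
  lapply(seq_len(n), function(i) {
    target_record(sprintf("T%04d", i), i - 1L, seq = codes_to_string(codes[[i]]))
  })
}

# truncated-normal integer lengths in [lo, hi]; hi may be a vector
.rtrunc_len <- function(n, mean, sd, lo, hi) {
  hi <- rep_len(hi, n)
  out <- integer(n)
  need <- seq_len(n)
  for (tries in 1:100) {
    x <- as.integer(round(stats::rnorm(length(need), mean, sd)))
    ok <- x >= lo & x <= hi[need]
    out[need[ok]] <- x[ok]
    need <- need[!ok]
    if (length(need) == 0L) break
  }
  if (length(need) > 0L) out[need] <- as.integer(pmin(pmax(round(mean), lo), hi[need]))
  out
}

# Random bias chain emulating priming bias: each window position has a
# base preference shared across contexts (log-scale sd `sd_pos`) plus a
# mild per-context modulation (`sd_ctx`). Real fragment-end bias is
# dominated by such position-specific nucleotide preferences; a chain
# with independent conditionals per context would encode bias with no
# low-order structure, which no estimator (nor real protocol) exhibits.
.random_bias_chain <- function(cfg_em, sd_pos = 0.5, sd_ctx = 0.15) {
  chain <- .chain_uniform(cfg_em$bias_up, cfg_em$bias_down, cfg_em$bias_order)
  n_rows <- chain$n %/% 4L
  W <- chain$W
  base <- matrix(stats::rnorm(4L * W, sd = sd_pos), nrow = 4L)      # per (nuc, j)
  j_of_row <- rep(seq_len(W), times = 4L^chain$ord)
  lo <- base[, j_of_row] + matrix(stats::rnorm(4L * n_rows, sd = sd_ctx), nrow = 4L)
  p <- exp(lo)
  p <- sweep(p, 2L, colSums(p), "/")
  chain$p <- as.vector(p)
  chain
}

#' Simulate a sequencing experiment from the generative model
#'
#' For each fragment: the origin target is drawn with probability
#' proportional to molar abundance times effective length (so the
#' returned `tau` is the fragment sampling probability the quantifier
#' estimates), the length from the truncated-normal law, the start site
#' uniformly — or, when `bias_strength > 0`, weighted by an order-3
#' Markov-chain bias at the 5' end raised to `bias_strength` — and
#' substitution errors land i.i.d. at `error_rate`. Reads are then placed
#' back on the full target set with the exhaustive aligner
#' ([emulate_aligner()] semantics), so records carry every placement
#' within the mismatch threshold; fragments whose reads no longer align
#' anywhere are dropped (counted in `truth$n_dropped`).
#'
#' @param targets List of [target_record()]s (typically from
#'   [simulate_targets()]).
#' @param cfg A [sim_config()].
#' @param out_dir If non-`NULL`, write the FASTA/SAM mirror, the two
#'   record files and a truth TSV into this directory.
#' @return List with `fragments` (list of [fragment_record()]s), `truth`
#'   (class `"sim_truth"`: `tau`, `counts`, `rho`, `n_dropped`, and the
#'   true bias chain when biased) and, when `out_dir` is given, the
#'   written `paths`.
#' @export
simulate_experiment <- function(targets, cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  emcfg <- em_config(bias_enabled = cfg$bias_strength > 0,
                     max_frag_len = cfg$max_frag_len,
                     max_read_len = max(cfg$read_len, 1L))
  ti <- .target_info(targets, emcfg)
  n_t <- ti$n
  rl <- cfg$read_len

  # ground truth: molar abundances, fragment-origin probabilities
  rho <- stats::rgamma(n_t, shape = cfg$alpha)
  rho <- rho / sum(rho)
  pmf_len <- stats::dnorm(seq_len(cfg$max_frag_len), cfg$fld_mean, cfg$fld_sd)
  pmf_len[seq_len(min(rl - 1L, cfg$max_frag_len))] <- 0
  pmf_len <- pmf_len / sum(pmf_len)
  true_fld <- .fld_set(.fld_new(cfg$max_frag_len), pmf_len)
  eff <- .eff_lengths(ti$lens, true_fld)
  cumF <- cumsum(pmf_len)

  # 5' start-site bias weights per target position; the joint generative
  # draw is P(t, p, l) proportional to rho_t * pfld(l) * w_t(p)^strength,
  # so sequence bias distorts target-level sampling exactly the way the
  # quantifier's bias weights model it
  bias_chain <- NULL
  wlist <- NULL
  if (cfg$bias_strength > 0) {
    bias_chain <- .random_bias_chain(emcfg)
    lw <- log(bias_chain$p) - log(0.25)
    wlist <- lapply(seq_len(n_t), function(tt) {
      m <- .chain_slot_idx(bias_chain, ti$codes[[tt]], 0:(ti$lens[tt] - 1L))
      v <- matrix(0, nrow(m), ncol(m))
      v[!is.na(m)] <- lw[m[!is.na(m)]]
      exp(cfg$bias_strength * rowSums(v))
    })
    # per-target start-site weights including the length mass fitting there
    pw <- lapply(seq_len(n_t), function(tt) {
      L <- ti$lens[tt]
      wlist[[tt]] * cumF[pmax(pmin(L - 0:(L - 1L), cfg$max_frag_len), 1L)]
    })
    A <- vapply(pw, sum, numeric(1))        # bias-weighted effective length
  } else {
    A <- eff
  }
  tau <- rho * A
  tau <- tau / sum(tau)

  origin <- sample.int(n_t, cfg$n_fragments, replace = TRUE, prob = tau)
  counts_true <- tabulate(origin, nbins = n_t)

  # fragment start sites and lengths
  lens_t <- ti$lens[origin]
  if (is.null(wlist)) {
    fl <- .rtrunc_len(cfg$n_fragments, cfg$fld_mean, cfg$fld_sd,
                      rl, pmin(cfg$max_frag_len, lens_t))
    start0 <- as.integer(floor(stats::runif(cfg$n_fragments) * (lens_t - fl + 1L)))
  } else {
    start0 <- integer(cfg$n_fragments)
    fl <- integer(cfg$n_fragments)
    for (i in seq_len(cfg$n_fragments)) {
      tt <- origin[i]
      start0[i] <- sample.int(ti$lens[tt], 1L, prob = pw[[tt]]) - 1L
      lmax <- min(ti$lens[tt] - start0[i], cfg$max_frag_len)
      fl[i] <- sample.int(lmax, 1L, prob = pmf_len[seq_len(lmax)])
    }
  }

  # read sequences (left = first rl bases, right = last rl bases, both on
  # the forward strand), with i.i.d. substitution errors
  n_reads <- if (cfg$paired) 2L * cfg$n_fragments else cfg$n_fragments
  gl <- ti$off[origin] + start0                     # global 0-based frag start
  left_idx <- outer(gl, 1:rl, `+`)
  R <- matrix(ti$G[left_idx], nrow = cfg$n_fragments)
  if (cfg$paired) {
    gr <- gl + fl - rl
    right_idx <- outer(gr, 1:rl, `+`)
    R <- rbind(R, matrix(ti$G[right_idx], nrow = cfg$n_fragments))
    # rows: 1..n left reads, n+1..2n right reads
  }
  if (cfg$error_rate > 0) {
    ne <- length(R)
    hit <- stats::runif(ne) < cfg$error_rate
    if (any(hit)) {
      R[hit] <- (R[hit] + sample.int(3L, sum(hit), replace = TRUE)) %% 4L
    }
  }

  # exhaustive alignment of all reads
  al <- .align_batch(R, ti, cfg$max_mismatches)
  pl <- al$placements

  if (cfg$paired) {
    is_left <- pl$read <= cfg$n_fragments
    frag_of <- ifelse(is_left, pl$read, pl$read - cfg$n_fragments)
    dl <- data.frame(frag = frag_of[is_left], tgt = pl$tgt[is_left],
                     s = pl$start0[is_left], k = which(is_left))
    dr <- data.frame(frag = frag_of[!is_left], tgt = pl$tgt[!is_left],
                     s = pl$start0[!is_left], k = which(!is_left))
    pairs <- merge(dl, dr, by = c("frag", "tgt"), suffixes = c("_l", "_r"))
    implied <- pairs$s_r + rl - pairs$s_l
    pairs <- pairs[pairs$s_r >= pairs$s_l & implied <= cfg$max_frag_len, , drop = FALSE]
    pairs <- pairs[order(pairs$frag, pairs$tgt, pairs$s_l, pairs$s_r), , drop = FALSE]
    frag_ids <- pairs$frag
  } else {
    pairs <- data.frame(frag = pl$read, tgt = pl$tgt, s_l = pl$start0,
                        k_l = seq_len(nrow(pl)))
    frag_ids <- pairs$frag
  }

  # build fragment records
  kept <- sort(unique(frag_ids))
  n_dropped <- cfg$n_fragments - length(kept)
  split_rows <- split(seq_len(nrow(pairs)), frag_ids)
  fragments <- vector("list", length(kept))
  for (q in seq_along(kept)) {
    f <- kept[q]
    rows <- split_rows[[q]]
    alns <- lapply(rows, function(rr) {
      if (cfg$paired) {
        kl <- pairs$k_l[rr]; kr <- pairs$k_r[rr]
        structure(list(
          target_id = pairs$tgt[rr] - 1L,
          read_l = .fast_read_aln(TRUE, pairs$s_l[rr], pairs$s_l[rr] + rl - 1L,
                                  al$mm_idx[[kl]], al$mm_nuc[[kl]]),
          read_r = .fast_read_aln(FALSE, pairs$s_r[rr], pairs$s_r[rr] + rl - 1L,
                                  al$mm_idx[[kr]], al$mm_nuc[[kr]])),
          class = "fragment_alignment")
      } else {
        kl <- pairs$k_l[rr]
        structure(list(
          target_id = pairs$tgt[rr] - 1L,
          read_l = .fast_read_aln(TRUE, pairs$s_l[rr], pairs$s_l[rr] + rl - 1L,
                                  al$mm_idx[[kl]], al$mm_nuc[[kl]]),
          read_r = NULL),
          class = "fragment_alignment")
      }
    })
    fragments[[q]] <- structure(list(name = sprintf("F%07d", f),
                                     paired = cfg$paired, alignments = alns),
                                class = "fragment_record")
  }

  truth <- structure(list(tau = tau, counts = counts_true, rho = rho,
                          fld_pmf = pmf_len,
                          bias_chain = bias_chain,
                          n_dropped = n_dropped,
                          origin = origin),
                     class = "sim_truth")

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(fasta = file.path(out_dir, "targets.fa"),
                  sam = file.path(out_dir, "fragments.sam"),
                  targets_pb64 = file.path(out_dir, "targets.pb64"),
                  frags_pb64 = file.path(out_dir, "fragments.pb64"),
                  truth = file.path(out_dir, "truth.tsv"))
    write_targets_fasta(targets, paths$fasta)
    write_fragments_sam(fragments, targets, paths$sam)
    write_record_file(targets, paths$targets_pb64)
    write_record_file(fragments, paths$frags_pb64)
    utils::write.table(
      data.frame(target = ti$names, length = ti$lens,
                 true_tau = tau, true_count = counts_true),
      paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(fragments = fragments, truth = truth, paths = paths)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth: %d targets, %d fragments (%d dropped), %s>\n",
              length(x$tau), sum(x$counts), x$n_dropped,
              if (is.null(x$bias_chain)) "unbiased" else "5'-biased"))
  invisible(x)
}
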
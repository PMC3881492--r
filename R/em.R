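# Batch EM engine: E-step posterior assignment, M-step re-estimation with
# Laplace smoothing, auxiliary-parameter freezing, bias-weight updates and
# convergence detection.
#
# The hot path works on a "compiled" representation of a block of fragment
# records: flat integer index vectors that turn every E-step into a handful
# of vectorized gathers and grouped sums. The reference (record-at-a-time)
# path lives in e_step_fragment()/alignment_loglik() and is used to
# cross-check the compiled path in the tests.

#' EM configuration
#'
#' @param pseudocount Laplace smoothing constant added to the auxiliary
#'   count banks (fragment length, error, bias) before normalization.
#' @param abundance_pseudocount Smoothing added to the per-target expected
#'   counts; `NULL` (default) uses `1e-8 * n_fragments` so that small
#'   datasets are not distorted by a full pseudo-fragment per target.
#' @param min_prob Convergence floor: targets with sampling probability
#'   below this are ignored by the convergence check (default `1e-7`).
#' @param max_rel_change Convergence threshold on the relative abundance
#'   change between consecutive iterations (default `1e-2`).
#' @param aux_full_iters,aux_period,aux_freeze_at Auxiliary update
#'   schedule: updated every iteration for the first `aux_full_iters`
#'   (default 20), then every `aux_period` (default 100) iterations until
#'   `aux_freeze_at` (default 1000), after which they are frozen.
#' @param max_iters Iteration cap.
#' @param bias_enabled Enable sequence-specific bias correction.
#' @param max_frag_len Fragment length support.
#' @param max_read_len Modeled read positions in the error model.
#' @param bias_up,bias_down,bias_order Bias window geometry and Markov order.
#' @param partition_size Fragments per partition for the parallel executor.
#' @param target_partition_size Targets per partition for the distributed
#'   bias-expectation step.
#' @param seed Integer seed recorded with the run (the EM itself is
#'   deterministic; the seed is used by consumers that simulate).
#' @return An object of class `"em_config"`.
#' @export
em_config <- function(pseudocount = 1.0,
                      abundance_pseudocount = NULL,
                      min_prob = 1e-7,
                      max_rel_change = 1e-2,
                      aux_full_iters = 20L,
                      aux_period = 100L,
                      aux_freeze_at = 1000L,
                      max_iters = 1000L,
                      bias_enabled = TRUE,
                      max_frag_len = 800L,
                      max_read_len = 150L,
                      bias_up = 8L, bias_down = 12L, bias_order = 0L,
                      partition_size = 10000L,
                      target_partition_size = 50L,
                      seed = 1L) {
  stopifnot(pseudocount > 0, min_prob > 0, max_rel_change > 0,
            aux_full_iters >= 0L, aux_period >= 1L,
            aux_full_iters <= aux_freeze_at, max_iters >= 1L,
            partition_size >= 1L, target_partition_size >= 1L)
  structure(list(pseudocount = pseudocount,
                 abundance_pseudocount = abundance_pseudocount,
                 min_prob = min_prob, max_rel_change = max_rel_change,
                 aux_full_iters = as.integer(aux_full_iters),
                 aux_period = as.integer(aux_period),
                 aux_freeze_at = as.integer(aux_freeze_at),
                 max_iters = as.integer(max_iters),
                 bias_enabled = isTRUE(bias_enabled),
                 max_frag_len = as.integer(max_frag_len),
                 max_read_len = as.integer(max_read_len),
                 bias_up = as.integer(bias_up),
                 bias_down = as.integer(bias_down),
                 bias_order = as.integer(bias_order),
                 partition_size = as.integer(partition_size),
                 target_partition_size = as.integer(target_partition_size),
                 seed = as.integer(seed)),
            class = "em_config")
}

#' Is an auxiliary-parameter update due at this iteration?
#'
#' Auxiliary parameters (error model, fragment length distribution, bias
#' chains) are updated at every iteration for the first `aux_full_iters`,
#' then only at multiples of `aux_period` up to `aux_freeze_at`, after
#' which they are frozen. Iterations are 1-based.
#'
#' @param iteration 1-based iteration counter.
#' @param cfg An [em_config()].
#' @return Logical.
#' @export
aux_update_due <- function(iteration, cfg) {
  stopifnot(iteration >= 1L)
  iteration <- as.integer(iteration)
  iteration <= cfg$aux_full_iters ||
    (iteration <= cfg$aux_freeze_at && iteration %% cfg$aux_period == 0L)
}

#' Normalize counts into a smoothed probability vector
#'
#' Laplace smoothing followed by normalization:
#' `(counts + pseudocount) / sum(counts + pseudocount)`.
#'
#' @param counts Nonnegative numeric vector.
#' @param pseudocount Positive smoothing constant.
#' @return Strictly positive probability vector summing to 1.
#' @export
m_step_normalize <- function(counts, pseudocount) {
  stopifnot(is.numeric(counts), pseudocount > 0)
  if (any(counts < 0)) stop("negative count in M-step", call. = FALSE)
  x <- counts + pseudocount
  x / sum(x)
}

#' Convergence check on the abundance vector
#'
#' The abundances are converged when every target whose current sampling
#' probability is at least `min_prob` has changed by no more than
#' `max_rel_change` relative to its previous value.
#'
#' @param prev_tau,curr_tau Abundance vectors from consecutive iterations
#'   (equal length, each summing to 1).
#' @param cfg An [em_config()].
#' @return Logical.
#' @export
check_convergence <- function(prev_tau, curr_tau, cfg) {
  if (length(prev_tau) != length(curr_tau)) {
    stop("abundance vectors differ in length", call. = FALSE)
  }
  sel <- curr_tau >= cfg$min_prob
  if (!any(sel)) return(TRUE)
  all(abs(curr_tau[sel] - prev_tau[sel]) / prev_tau[sel] <= cfg$max_rel_change)
}

# --- accumulators -------------------------------------------------------

.acc_shape <- function(n_targets, cfg) {
  chain <- .chain_uniform(cfg$bias_up, cfg$bias_down, cfg$bias_order)
  list(n_targets = as.integer(n_targets),
       max_frag_len = cfg$max_frag_len,
       err_n = 2L * cfg$max_read_len * 16L,
       chain_n = chain$n)
}

#' Create an all-zero accumulator
#'
#' Accumulators are the additive empirical-count structures E-steps
#' produce: expected per-target counts, fragment-length counts, error
#' substitution counts, bias window counts, plus the total assigned mass
#' and the data log-likelihood.
#'
#' @param shape Shape descriptor (internal; taken from an existing
#'   accumulator's `shape` field or built by the engine).
#' @return An object of class `"em_accumulator"`.
#' @export
zero_accumulator <- function(shape) {
  structure(list(shape = shape,
                 counts = numeric(shape$n_targets),
                 fld_counts = numeric(shape$max_frag_len),
                 err_counts = numeric(shape$err_n),
                 b5_counts = numeric(shape$chain_n),
                 b3_counts = numeric(shape$chain_n),
                 mass = 0.0,
                 loglik = 0.0),
            class = "em_accumulator")
}

.acc_add <- function(a, b) {
  stopifnot(identical(a$shape, b$shape))
  a$counts <- a$counts + b$counts
  a$fld_counts <- a$fld_counts + b$fld_counts
  a$err_counts <- a$err_counts + b$err_counts
  a$b5_counts <- a$b5_counts + b$b5_counts
  a$b3_counts <- a$b3_counts + b$b3_counts
  a$mass <- a$mass + b$mass
  a$loglik <- a$loglik + b$loglik
  a
}

# --- compiled representation -------------------------------------------

# target-side structures shared by all chunks
.target_info <- function(targets, cfg) {
  n <- length(targets)
  ids <- vapply(targets, `[[`, integer(1), "id")
  if (!identical(sort(ids), 0:(n - 1L))) {
    stop("target ids must be unique and dense (0..n_targets-1)", call. = FALSE)
  }
  targets <- targets[order(ids)]
  codes <- lapply(targets, function(t) .unpack_codes(t$seq, t$length))
  lens <- vapply(targets, `[[`, integer(1), "length")
  off <- c(0L, cumsum(lens))[seq_len(n)]
  list(n = n, codes = codes, G = unlist(codes, use.names = FALSE),
       off = off, lens = lens,
       names = vapply(targets, `[[`, character(1), "name"))
}

# compile a block of fragment records into flat index vectors
.compile_chunk <- function(fragments, ti, cfg) {
  n_frag <- length(fragments)
  if (n_frag == 0L) {
    return(list(n_frag = 0L, n_aln = 0L))
  }
  n_aln_per <- vapply(fragments, function(f) length(f$alignments), integer(1))
  if (any(n_aln_per == 0L)) {
    stop(sprintf("fragment '%s' has no alignments",
                 fragments[[which(n_aln_per == 0L)[1L]]]$name), call. = FALSE)
  }
  alns <- unlist(lapply(fragments, `[[`, "alignments"), recursive = FALSE)
  n_aln <- length(alns)
  frag_of_aln <- rep(seq_len(n_frag), n_aln_per)
  tgt <- vapply(alns, `[[`, integer(1), "target_id") + 1L
  if (any(tgt < 1L | tgt > ti$n)) stop("alignment to unknown target", call. = FALSE)

  grab <- function(get) lapply(alns, get)
  rl <- grab(function(a) a$read_l)
  rr <- grab(function(a) a$read_r)
  has_l <- !vapply(rl, is.null, logical(1))
  has_r <- !vapply(rr, is.null, logical(1))

  rfield <- function(lst, sel, fld, default = NA_integer_) {
    out <- rep(default, n_aln)
    out[sel] <- vapply(lst[sel], `[[`, integer(1), fld)
    out
  }
  l_left <- rfield(rl, has_l, "left_pos")
  l_right <- rfield(rl, has_l, "right_pos")
  r_left <- rfield(rr, has_r, "left_pos")
  r_right <- rfield(rr, has_r, "right_pos")
  tlen_aln <- ti$lens[tgt]
  rmax <- pmax(ifelse(has_l, l_right, -1L), ifelse(has_r, r_right, -1L))
  if (any(rmax >= tlen_aln)) stop("alignment beyond target end", call. = FALSE)

  implied <- ifelse(has_l & has_r, r_right - l_left + 1L, NA_integer_)

  # --- read expansion for the error model -------------------------------
  read_rows <- list()
  add_reads <- function(sel, reads, left, right) {
    if (!any(sel)) return()
    first <- vapply(reads[sel], function(r) isTRUE(r$first), logical(1))
    mm_idx <- lapply(reads[sel], `[[`, "mismatch_indices")
    mm_nuc <- lapply(reads[sel], function(r) {
      .unpack_codes(r$mismatch_nucs, length(r$mismatch_indices))
    })
    read_rows[[length(read_rows) + 1L]] <<- list(
      aln = which(sel), left = left[sel], len = right[sel] - left[sel] + 1L,
      bank = ifelse(first, 1L, 2L), mm_idx = mm_idx, mm_nuc = mm_nuc)
  }
  add_reads(has_l, rl, l_left, l_right)
  add_reads(has_r, rr, r_left, r_right)
  rt <- list(aln = unlist(lapply(read_rows, `[[`, "aln")),
             left = unlist(lapply(read_rows, `[[`, "left")),
             len = unlist(lapply(read_rows, `[[`, "len")),
             bank = unlist(lapply(read_rows, `[[`, "bank")),
             mm_idx = do.call(c, lapply(read_rows, `[[`, "mm_idx")),
             mm_nuc = do.call(c, lapply(read_rows, `[[`, "mm_nuc")))

  pos_seq <- sequence(rt$len)                       # 1-based read positions
  aln_exp <- rep(rt$aln, rt$len)
  gidx <- rep(ti$off[tgt[rt$aln]] + rt$left, rt$len) + pos_seq
  ref <- ti$G[gidx]
  obs <- ref
  mm_len <- lengths(rt$mm_idx)
  if (sum(mm_len) > 0L) {
    read_start <- c(0L, cumsum(rt$len))[seq_along(rt$len)]
    mm_global <- rep(read_start, mm_len) + unlist(rt$mm_idx) + 1L
    obs[mm_global] <- unlist(rt$mm_nuc)
  }
  err_idx <- .err_flat_idx(rep(rt$bank, rt$len), pos_seq, ref, obs, cfg$max_read_len)

  # --- bias slot indices -------------------------------------------------
  b5 <- b3 <- list(idx = integer(0), aln = integer(0))
  if (cfg$bias_enabled) {
    tmpl <- .chain_uniform(cfg$bias_up, cfg$bias_down, cfg$bias_order)
    collect <- function(anchors0, rows) {
      idx_all <- integer(0); aln_all <- integer(0)
      for (tt in unique(tgt[rows])) {
        rsel <- rows[tgt[rows] == tt]
        m <- .chain_slot_idx(tmpl, ti$codes[[tt]], anchors0[match(rsel, rows)])
        keep <- !is.na(m)
        idx_all <- c(idx_all, m[keep])
        aln_all <- c(aln_all, rep(rsel, times = ncol(m))[keep])
      }
      list(idx = idx_all, aln = aln_all)
    }
    rows5 <- which(has_l)
    if (length(rows5)) b5 <- collect(l_left[rows5], rows5)
    rows3 <- which(has_r)
    if (length(rows3)) b3 <- collect(r_right[rows3], rows3)
  }

  # --- fragment grouping (padded index matrix for grouped max/sum) ------
  K <- max(n_aln_per)
  pad <- matrix(n_aln + 1L, nrow = n_frag, ncol = K)   # sentinel row
  first_aln <- c(0L, cumsum(n_aln_per))[seq_len(n_frag)]
  for (k in seq_len(K)) {
    sel <- n_aln_per >= k
    pad[sel, k] <- first_aln[sel] + k
  }

  list(n_frag = n_frag, n_aln = n_aln,
       frag_of_aln = frag_of_aln, tgt = tgt,
       implied = implied, has_l = has_l, has_r = has_r,
       l_left = l_left, r_right = r_right,
       err_idx = err_idx, err_aln = aln_exp,
       b5_idx = b5$idx, b5_aln = b5$aln,
       b3_idx = b3$idx, b3_aln = b3$aln,
       pad = pad)
}

# recompute the chunk-cached per-alignment auxiliary log-likelihood terms
.chunk_aux_cache <- function(chunk, params, cfg) {
  if (chunk$n_frag == 0L) return(chunk)
  ll_fld <- numeric(chunk$n_aln)
  sel <- !is.na(chunk$implied)
  if (any(sel)) {
    l <- chunk$implied[sel]
    v <- ifelse(l > params$fld$max_len, .FLD_FLOOR_LOG, params$fld$log_pmf[pmin(l, params$fld$max_len)])
    ll_fld[sel] <- v
  }
  ef <- .err_flat(params$err)
  ll_err <- numeric(chunk$n_aln)
  if (length(chunk$err_idx)) {
    rs <- rowsum(ef[chunk$err_idx], chunk$err_aln)
    ll_err[as.integer(rownames(rs))] <- rs[, 1L]
  }
  ll_bias <- numeric(chunk$n_aln)
  if (cfg$bias_enabled && isTRUE(params$bias$enabled)) {
    if (length(chunk$b5_idx)) {
      d <- log(params$bias$obs5$p[chunk$b5_idx]) - log(params$bias$exp5$p[chunk$b5_idx])
      rs <- rowsum(d, chunk$b5_aln)
      ll_bias[as.integer(rownames(rs))] <- ll_bias[as.integer(rownames(rs))] + rs[, 1L]
    }
    if (length(chunk$b3_idx)) {
      d <- log(params$bias$obs3$p[chunk$b3_idx]) - log(params$bias$exp3$p[chunk$b3_idx])
      rs <- rowsum(d, chunk$b3_aln)
      ll_bias[as.integer(rownames(rs))] <- ll_bias[as.integer(rownames(rs))] + rs[, 1L]
    }
  }
  chunk$ll_fld <- ll_fld
  chunk$ll_err <- ll_err
  chunk$ll_bias <- ll_bias
  chunk
}

# one E-step over a compiled chunk under the broadcast parameter snapshot
.estep_chunk <- function(chunk, bc) {
  acc <- zero_accumulator(bc$shape)
  if (chunk$n_frag == 0L) return(acc)
  ll <- bc$log_tau[chunk$tgt] - bc$log_eff[chunk$tgt] +
    chunk$ll_fld + chunk$ll_err + chunk$ll_bias
  V <- matrix(c(ll, -Inf)[chunk$pad], nrow = chunk$n_frag)
  m <- V[, 1L]
  if (ncol(V) > 1L) for (k in 2:ncol(V)) m <- pmax(m, V[, k])
  denom <- rowSums(exp(V - m))
  logZ <- m + log(denom)
  post <- exp(ll - logZ[chunk$frag_of_aln])
  acc$loglik <- sum(logZ)
  acc$mass <- sum(post)

  rs <- rowsum(post, chunk$tgt)
  acc$counts[as.integer(rownames(rs))] <- rs[, 1L]

  if (bc$want_aux) {
    sel <- !is.na(chunk$implied) & chunk$implied <= bc$shape$max_frag_len
    if (any(sel)) {
      rs <- rowsum(post[sel], chunk$implied[sel])
      acc$fld_counts[as.integer(rownames(rs))] <- rs[, 1L]
    }
    if (length(chunk$err_idx)) {
      rs <- rowsum(post[chunk$err_aln], chunk$err_idx)
      acc$err_counts[as.integer(rownames(rs))] <- rs[, 1L]
    }
    if (bc$bias_on) {
      if (length(chunk$b5_idx)) {
        rs <- rowsum(post[chunk$b5_aln], chunk$b5_idx)
        acc$b5_counts[as.integer(rownames(rs))] <- rs[, 1L]
      }
      if (length(chunk$b3_idx)) {
        rs <- rowsum(post[chunk$b3_aln], chunk$b3_idx)
        acc$b3_counts[as.integer(rownames(rs))] <- rs[, 1L]
      }
    }
  }
  acc
}

# --- bias expected frequencies -----------------------------------------

# lazily built sliding-window cache over all target positions
.slide_cache <- function(ti, cfg) {
  tmpl <- .chain_uniform(cfg$bias_up, cfg$bias_down, cfg$bias_order)
  build <- function(anchor_offset_is_5p) {
    idx_all <- vector("list", ti$n); anch_all <- vector("list", ti$n)
    for (tt in seq_len(ti$n)) {
      anchors <- 0:(ti$lens[tt] - 1L)
      m <- .chain_slot_idx(tmpl, ti$codes[[tt]], anchors)
      keep <- !is.na(m)
      idx_all[[tt]] <- m[keep]
      anch_all[[tt]] <- (ti$off[tt] + rep(anchors, times = ncol(m)))[keep] + 1L
    }
    list(idx = unlist(idx_all), anchor = unlist(anch_all))
  }
  s <- build(TRUE)   # slot geometry identical for both ends
  t_of_anchor <- rep(seq_len(ti$n), ti$lens)
  p_of_anchor <- sequence(ti$lens) - 1L
  list(idx = s$idx, anchor = s$anchor,
       t_of_anchor = t_of_anchor, p_of_anchor = p_of_anchor,
       chain_n = tmpl$n)
}

# expected window counts for a set of targets given current tau and fld.
# Each anchor position is weighted by the target's per-start-site sampling
# weight tau/efflen times the probability (under the fld) that a fragment
# end actually falls there.
.bias_expected_counts <- function(slide, tau, eff, fld, lens) {
  cumF <- cumsum(fld$pmf)
  F <- function(x) {
    out <- cumF[pmax(pmin(x, fld$max_len), 1L)]
    out[x <= 0L] <- 0
    out
  }
  base_w <- tau[slide$t_of_anchor] / eff[slide$t_of_anchor]
  L <- lens[slide$t_of_anchor]
  w5 <- base_w * F(L - slide$p_of_anchor)       # lengths fitting a 5' start
  w3 <- base_w * F(slide$p_of_anchor + 1L)      # lengths fitting a 3' end
  c5 <- numeric(slide$chain_n)
  rs <- rowsum(w5[slide$anchor], slide$idx)
  c5[as.integer(rownames(rs))] <- rs[, 1L]
  c3 <- numeric(slide$chain_n)
  rs <- rowsum(w3[slide$anchor], slide$idx)
  c3[as.integer(rownames(rs))] <- rs[, 1L]
  list(c5 = c5, c3 = c3)
}

.rescale_mass <- function(counts, target_mass) {
  s <- sum(counts)
  if (s <= 0 || target_mass <= 0) return(counts)
  counts * (target_mass / s)
}

# Bias-adjusted effective lengths: the per-target normalizer of the
# bias-weighted position distribution, so tau stays a proper sampling
# probability and the length-normalized abundance de-distorts the
# sequence bias. Product of the marginal 5' and 3' adjustments over the
# base effective length; equals eff_base when all weights are 1.
.bias_adjusted_eff <- function(slide, bias, fld, lens, eff_base) {
  lw5 <- log(bias$obs5$p) - log(bias$exp5$p)
  lw3 <- log(bias$obs3$p) - log(bias$exp3$p)
  n_anchor <- length(slide$t_of_anchor)
  s5 <- numeric(n_anchor); s3 <- numeric(n_anchor)
  rs <- rowsum(lw5[slide$idx], slide$anchor)
  s5[as.integer(rownames(rs))] <- rs[, 1L]
  rs <- rowsum(lw3[slide$idx], slide$anchor)
  s3[as.integer(rownames(rs))] <- rs[, 1L]
  cumF <- cumsum(fld$pmf)
  F <- function(x) {
    out <- cumF[pmax(pmin(x, fld$max_len), 1L)]
    out[x <= 0L] <- 0
    out
  }
  L <- lens[slide$t_of_anchor]
  e5 <- rowsum(exp(s5) * F(L - slide$p_of_anchor), slide$t_of_anchor)[, 1L]
  e3 <- rowsum(exp(s3) * F(slide$p_of_anchor + 1L), slide$t_of_anchor)[, 1L]
  pmax(e5 * e3 / pmax(eff_base, .Machine$double.xmin), .Machine$double.xmin)
}

#' Recompute the expected-frequency bias chains
#'
#' Slides windows along every target position, counting window
#' sub-sequences weighted by the target's current per-start-site sampling
#' weight (`tau/efflen`) and by the probability under the fragment length
#' distribution that a fragment end falls at that position; counts are
#' smoothed and normalized into the expected 5'/3' chains.
#'
#' @param targets List of [target_record()]s.
#' @param params A [new_model_params()] snapshot (bias enabled).
#' @param cfg An [em_config()].
#' @param obs_mass Optional total observed window mass; when given, the
#'   raw expected counts are rescaled to it before smoothing so that the
#'   shared pseudocount acts equally on both chains.
#' @return `params` with updated `bias$exp5`/`bias$exp3`.
#' @export
update_bias_expected <- function(targets, params, cfg = em_config(),
                                 obs_mass = NULL) {
  stopifnot(isTRUE(params$bias$enabled))
  ti <- .target_info(targets, cfg)
  slide <- .slide_cache(ti, cfg)
  eff <- .eff_lengths(ti$lens, params$fld)
  ec <- .bias_expected_counts(slide, params$tau, eff, params$fld, ti$lens)
  if (!is.null(obs_mass)) {
    ec$c5 <- .rescale_mass(ec$c5, obs_mass)
    ec$c3 <- .rescale_mass(ec$c3, obs_mass)
  }
  params$bias$exp5 <- .chain_normalize(params$bias$exp5, ec$c5, cfg$pseudocount)
  params$bias$exp3 <- .chain_normalize(params$bias$exp3, ec$c3, cfg$pseudocount)
  params
}

# --- reference (record-at-a-time) E-step --------------------------------

#' E-step for a single fragment
#'
#' Computes the posterior probability of each candidate alignment
#' (likelihoods normalized over the fragment's alignments via
#' log-sum-exp) and the fragment's additive contribution to the
#' accumulator: posterior-weighted target counts, fragment length counts,
#' error substitution counts, and observed bias window counts.
#'
#' This is the record-at-a-time reference implementation; [run_em()] uses
#' an equivalent vectorized path.
#'
#' @param frag A [fragment_record()].
#' @param params A [new_model_params()] snapshot.
#' @param targets List of [target_record()]s.
#' @param cfg An [em_config()].
#' @return List with `posteriors` (numeric, one per alignment, summing to
#'   1) and `contribution` (an `em_accumulator`).
#' @export
e_step_fragment <- function(frag, params, targets, cfg = em_config()) {
  if (!inherits(frag, "fragment_record") || length(frag$alignments) == 0L) {
    stop("fragment with zero alignments", call. = FALSE)
  }
  ll <- vapply(frag$alignments, function(a) alignment_loglik(frag, a, params, targets),
               numeric(1))
  m <- max(ll)
  w <- exp(ll - m)
  post <- w / sum(w)
  acc <- zero_accumulator(.acc_shape(length(targets), cfg))
  acc$loglik <- m + log(sum(w))
  acc$mass <- sum(post)
  tmpl <- .chain_uniform(cfg$bias_up, cfg$bias_down, cfg$bias_order)
  for (i in seq_along(frag$alignments)) {
    a <- frag$alignments[[i]]
    t1 <- a$target_id + 1L
    acc$counts[t1] <- acc$counts[t1] + post[i]
    if (!is.null(a$read_l) && !is.null(a$read_r)) {
      l <- a$read_r$right_pos - a$read_l$left_pos + 1L
      if (l <= cfg$max_frag_len) acc$fld_counts[l] <- acc$fld_counts[l] + post[i]
    }
    tcodes <- .unpack_codes(targets[[t1]]$seq, targets[[t1]]$length)
    for (r in list(a$read_l, a$read_r)) {
      if (is.null(r)) next
      len <- r$right_pos - r$left_pos + 1L
      ref <- tcodes[(r$left_pos + 1L):(r$right_pos + 1L)]
      obs <- ref
      n_mm <- length(r$mismatch_indices)
      if (n_mm > 0L) obs[r$mismatch_indices + 1L] <- .unpack_codes(r$mismatch_nucs, n_mm)
      bank <- if (isTRUE(r$first)) 1L else 2L
      idx <- .err_flat_idx(bank, seq_len(len), ref, obs, cfg$max_read_len)
      acc$err_counts[idx] <- acc$err_counts[idx] + post[i]
    }
    if (cfg$bias_enabled && isTRUE(params$bias$enabled)) {
      if (!is.null(a$read_l)) {
        s <- .chain_slot_idx(tmpl, tcodes, a$read_l$left_pos)
        s <- s[!is.na(s)]
        acc$b5_counts[s] <- acc$b5_counts[s] + post[i]
      }
      if (!is.null(a$read_r)) {
        s <- .chain_slot_idx(tmpl, tcodes, a$read_r$right_pos)
        s <- s[!is.na(s)]
        acc$b3_counts[s] <- acc$b3_counts[s] + post[i]
      }
    }
  }
  list(posteriors = post, contribution = acc)
}

# --- M-step and main loop ----------------------------------------------

.m_step <- function(params, acc, cfg, ti, slide, n_fragments, update_aux) {
  ap <- cfg$abundance_pseudocount
  if (is.null(ap)) ap <- 1e-8 * n_fragments
  params <- .params_set_tau(params, m_step_normalize(acc$counts, ap))
  if (update_aux) {
    params$fld <- .fld_set(params$fld,
                           m_step_normalize(acc$fld_counts, cfg$pseudocount))
    ec <- acc$err_counts + cfg$pseudocount
    grp <- rep(seq_len(length(ec) %/% 4L), each = 4L)
    tot <- rowsum(ec, grp)
    pflat <- ec / tot[grp]
    # invert the flat layout back into the [bank, pos, ref, obs] array
    p <- aperm(array(pflat, dim = c(4L, 4L, cfg$max_read_len, 2L)), c(4L, 3L, 2L, 1L))
    params$err <- .err_set(params$err, p)
    if (cfg$bias_enabled) {
      params$bias$obs5 <- .chain_normalize(params$bias$obs5, acc$b5_counts, cfg$pseudocount)
      params$bias$obs3 <- .chain_normalize(params$bias$obs3, acc$b3_counts, cfg$pseudocount)
      eff <- .eff_lengths(ti$lens, params$fld)
      ec2 <- .bias_expected_counts(slide, params$tau, eff, params$fld, ti$lens)
      # expected counts are rescaled to the observed mass so the shared
      # Laplace pseudocount smooths both chains equally
      params$bias$exp5 <- .chain_normalize(params$bias$exp5,
                                           .rescale_mass(ec2$c5, sum(acc$b5_counts)),
                                           cfg$pseudocount)
      params$bias$exp3 <- .chain_normalize(params$bias$exp3,
                                           .rescale_mass(ec2$c3, sum(acc$b3_counts)),
                                           cfg$pseudocount)
    }
  }
  params
}

.init_params <- function(n_targets, cfg, init_tau = NULL) {
  params <- new_model_params(n_targets,
                             max_frag_len = cfg$max_frag_len,
                             max_read_len = cfg$max_read_len,
                             bias_enabled = cfg$bias_enabled,
                             bias_up = cfg$bias_up, bias_down = cfg$bias_down,
                             bias_order = cfg$bias_order)
  if (!is.null(init_tau)) {
    stopifnot(length(init_tau) == n_targets, all(init_tau > 0))
    params <- .params_set_tau(params, init_tau / sum(init_tau))
  }
  params
}

# shared driver for the serial and parallel executors. `estep` is a
# function(bc, want_aux) -> combined accumulator for the full data.
.run_em_loop <- function(estep, n_targets, n_fragments, ti, cfg,
                         init_tau = NULL, n_iters = NULL) {
  params <- .init_params(n_targets, cfg, init_tau)
  slide <- if (cfg$bias_enabled) .slide_cache(ti, cfg) else NULL
  shape <- .acc_shape(n_targets, cfg)
  loglik_trace <- numeric(0)
  relchg_trace <- numeric(0)
  mass_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  last_acc <- NULL
  max_iters <- if (is.null(n_iters)) cfg$max_iters else as.integer(n_iters)
  aux_version <- 0L
  eff <- .eff_lengths(ti$lens, params$fld)   # initial chains are equal: no adjustment
  while (iter < max_iters) {
    iter <- iter + 1L
    want_aux <- aux_update_due(iter, cfg)
    bc <- list(shape = shape, log_tau = params$log_tau, log_eff = log(eff),
               want_aux = want_aux, bias_on = cfg$bias_enabled,
               params = params, aux_version = aux_version)
    acc <- estep(bc)
    last_acc <- acc
    loglik_trace <- c(loglik_trace, acc$loglik)
    mass_trace <- c(mass_trace, acc$mass)
    prev_tau <- params$tau
    params <- .m_step(params, acc, cfg, ti, slide, n_fragments, want_aux)
    if (want_aux) {
      aux_version <- aux_version + 1L
      eff <- .eff_lengths(ti$lens, params$fld)
      if (cfg$bias_enabled) {
        eff <- .bias_adjusted_eff(slide, params$bias, params$fld, ti$lens, eff)
      }
    }
    sel <- params$tau >= cfg$min_prob
    relchg_trace <- c(relchg_trace,
                      if (any(sel)) max(abs(params$tau[sel] - prev_tau[sel]) / prev_tau[sel]) else 0)
    if (is.null(n_iters) && check_convergence(prev_tau, params$tau, cfg)) {
      converged <- TRUE
      break
    }
  }
  structure(list(params = params,
                 counts = last_acc$counts,
                 tau = params$tau,
                 eff_lengths = eff,
                 target_names = ti$names,
                 target_lengths = ti$lens,
                 n_fragments = n_fragments,
                 iterations = iter,
                 converged = converged,
                 loglik_trace = loglik_trace,
                 max_rel_change_trace = relchg_trace,
                 mass_trace = mass_trace),
            class = "em_result")
}

#' Run the serial batch EM
#'
#' Alternates a full-data E-step (posterior assignment of every fragment
#' over its candidate alignments) with an M-step (Laplace-smoothed
#' re-estimation). Abundances are updated every iteration; auxiliary
#' parameters (error model, fragment length distribution, bias chains)
#' follow the freezing schedule of [aux_update_due()]. The loop stops when
#' [check_convergence()] fires or at `max_iters`.
#'
#' @param fragments List of [fragment_record()]s.
#' @param targets List of [target_record()]s.
#' @param cfg An [em_config()].
#' @param init_tau Optional initial abundance vector (defaults to uniform).
#' @param n_iters If given, run exactly this many iterations with no
#'   convergence check.
#' @return An object of class `"em_result"`: final parameters, per-target
#'   expected counts, iteration count, convergence flag and the
#'   log-likelihood trace.
#' @export
run_em <- function(fragments, targets, cfg = em_config(), init_tau = NULL,
                   n_iters = NULL) {
  stopifnot(length(fragments) >= 1L, length(targets) >= 1L)
  ti <- .target_info(targets, cfg)
  chunk <- .compile_chunk(fragments, ti, cfg)
  cache_version <- -1L
  estep <- function(bc) {
    if (cache_version != bc$aux_version) {
      chunk <<- .chunk_aux_cache(chunk, bc$params, cfg)
      cache_version <<- bc$aux_version
    }
    .estep_chunk(chunk, bc)
  }
  .run_em_loop(estep, ti$n, length(fragments), ti, cfg, init_tau, n_iters)
}

#' The rescue method
#'
#' The classical heuristic for ambiguous fragments: count the fragments
#' that are unique to a single target, then split each ambiguous fragment
#' across the distinct targets it aligns to proportionally to those unique
#' counts (uniformly when all are zero). Equivalent to a single E-step of
#' the EM algorithm initialized at the unique-count abundance estimate.
#'
#' @param fragments List of [fragment_record()]s.
#' @param targets List of [target_record()]s.
#' @return Numeric vector of per-target counts (sums to the number of
#'   fragments).
#' @export
run_rescue <- function(fragments, targets) {
  stopifnot(length(fragments) >= 1L, length(targets) >= 1L)
  n_t <- length(targets)
  tsets <- lapply(fragments, function(f) {
    unique(vapply(f$alignments, `[[`, integer(1), "target_id")) + 1L
  })
  uniq <- numeric(n_t)
  for (s in tsets) if (length(s) == 1L) uniq[s] <- uniq[s] + 1
  total <- uniq
  for (s in tsets) {
    if (length(s) > 1L) {
      w <- uniq[s]
      if (sum(w) == 0) w <- rep(1, length(s))
      total[s] <- total[s] + w / sum(w)
    }
  }
  total
}

#' @export
print.em_result <- function(x, ...) {
  cat(sprintf("<em_result: %d targets, %s fragments, %d iteration(s), %s>\n",
              length(x$tau), format(x$n_fragments, big.mark = ","),
              x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}
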
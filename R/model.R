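# The generative likelihood. A fragment aligned to target t at a given
# position with length l contributes
#
#   tau_t / efflen_t * P_fld(l) * P_err(read_l) * P_err(read_r) * w5 * w3
#
# where tau_t is the target sampling probability (the probability that a
# random sequenced fragment originates from t), efflen_t the effective
# length (valid start sites averaged over the fragment length
# distribution), P_fld the fragment length pmf, P_err positional
# substitution error terms, and w5/w3 sequence-specific bias weights
# (observed/expected Markov-chain probabilities of the windows around the
# fragment ends). All terms are handled in log space.

# --- fragment length distribution --------------------------------------

.fld_new <- function(max_len = 800L) {
  pmf <- rep(1 / max_len, max_len)
  list(pmf = pmf, log_pmf = log(pmf), max_len = as.integer(max_len))
}

.fld_set <- function(fld, pmf) {
  stopifnot(length(pmf) == fld$max_len)
  fld$pmf <- pmf
  fld$log_pmf <- log(pmf)
  fld
}

.FLD_FLOOR_LOG <- log(1e-12)

#' Log-probability of a fragment length
#'
#' @param len Fragment length (positive integer).
#' @param fld Fragment length distribution (component `fld` of a model
#'   parameter set), a pmf over `1..max_len`.
#' @return Log pmf value; lengths beyond `max_len` get the smoothing floor.
#' @export
fraglen_logprob <- function(len, fld) {
  stopifnot(is.numeric(len), length(len) == 1L)
  if (len <= 0) stop("fragment length must be positive", call. = FALSE)
  len <- as.integer(len)
  if (len > fld$max_len) return(.FLD_FLOOR_LOG)
  fld$log_pmf[[len]]
}

#' Effective length of a target
#'
#' The number of valid fragment start positions averaged over the fragment
#' length distribution: `sum_l pmf(l) * max(target_len - l + 1, 0)`. Used
#' to normalize the target sampling probability to a per-start-site weight.
#'
#' @param target_len Target length in nucleotides (>= 1).
#' @param fld Fragment length distribution.
#' @return A real number `<= target_len`.
#' @export
effective_length <- function(target_len, fld) {
  stopifnot(is.numeric(target_len), length(target_len) == 1L, target_len >= 1)
  .eff_lengths(as.integer(target_len), fld)
}

# vectorized over target lengths; (L+1) F(L) - sum_{l<=L} l pmf(l)
.eff_lengths <- function(tlens, fld) {
  cum_p <- cumsum(fld$pmf)
  cum_lp <- cumsum(seq_len(fld$max_len) * fld$pmf)
  i <- pmin(tlens, fld$max_len)
  (tlens + 1) * cum_p[i] - cum_lp[i]
}

# --- error model --------------------------------------------------------

# p[bank, pos, ref+1, obs+1]; bank 1 = first-sequenced end, bank 2 = the
# other. Positions beyond max_read_len reuse the last position's matrix.
.err_new <- function(max_read_len = 150L) {
  p <- array(0.25, dim = c(2L, max_read_len, 4L, 4L))
  list(p = p, log_p = log(p), max_read_len = as.integer(max_read_len))
}

.err_set <- function(err, p) {
  err$p <- p
  err$log_p <- log(p)
  err
}

# flat index into aperm(p, c(4,3,2,1)) laid out as
# ((bank-1)*L + (pos-1))*16 + ref*4 + obs + 1
.err_flat <- function(err) {
  as.vector(aperm(err$log_p, c(4L, 3L, 2L, 1L)))
}

.err_flat_idx <- function(bank, pos, ref, obs, max_read_len) {
  pos <- pmin(pos, max_read_len)
  ((bank - 1L) * max_read_len + (pos - 1L)) * 16L + ref * 4L + obs + 1L
}

#' Log-likelihood of the substitution errors of one read alignment
#'
#' Sums, over read positions, the log conditional probability of the
#' observed nucleotide given the reference nucleotide and the read
#' position. Positions absent from `mismatch_indices` observed the
#' reference base. Read positions beyond the modeled read length reuse
#' the last position's matrix.
#'
#' @param readaln A [read_alignment()] record.
#' @param ref_window Reference nucleotides spanned by the alignment
#'   (string of length `right_pos - left_pos + 1`).
#' @param err Error model (component `err` of a model parameter set).
#' @return Log probability.
#' @export
error_loglik <- function(readaln, ref_window, err) {
  len <- readaln$right_pos - readaln$left_pos + 1L
  if (nchar(ref_window) != len) {
    stop("ref_window must cover the alignment span", call. = FALSE)
  }
  ref <- nuc_codes(ref_window)
  obs <- ref
  n_mm <- length(readaln$mismatch_indices)
  if (n_mm > 0L) {
    obs[readaln$mismatch_indices + 1L] <- .unpack_codes(readaln$mismatch_nucs, n_mm)
  }
  bank <- if (isTRUE(readaln$first)) 1L else 2L
  idx <- .err_flat_idx(bank, seq_len(len), ref, obs, err$max_read_len)
  sum(.err_flat(err)[idx])
}

# --- bias model ---------------------------------------------------------

# A bias chain scores the W = up + 1 + down window anchored on a fragment
# end; window position j has a conditional table over the base given the
# min(j-1, order) preceding window slots. Stored flat: probability of
# (j, context, nuc) at off[j] + context*4 + nuc + 1.
.chain_uniform <- function(up = 8L, down = 12L, order = 3L) {
  W <- up + 1L + down
  o <- pmin(seq_len(W) - 1L, order)
  sizes <- 4L^o * 4L
  off <- c(0L, cumsum(sizes))[seq_len(W)]
  list(up = as.integer(up), down = as.integer(down), order = as.integer(order),
       W = W, ord = o, off = off, n = sum(sizes),
       p = rep(0.25, sum(sizes)))
}

.chain_set <- function(chain, p) { chain$p <- p; chain }

# normalize flat counts into conditional probabilities per (j, context)
.chain_normalize <- function(chain, counts, pseudocount = 1.0) {
  stopifnot(length(counts) == chain$n, all(counts >= 0))
  counts <- counts + pseudocount
  grp <- rep(seq_len(chain$n %/% 4L), each = 4L)
  tot <- rowsum(counts, grp)
  chain$p <- counts / tot[grp]
  chain
}

# flat chain indices for window slots of anchors on a coded sequence.
# codes: integer codes of the target; anchors: 0-based end positions.
# Returns (per anchor) up to W flat indices; clipped slots (slot or any
# context position outside the target) are dropped.
.chain_slot_idx <- function(chain, codes, anchors0) {
  L <- length(codes)
  n <- length(anchors0)
  W <- chain$W
  # matrix of absolute 0-based slot positions: n x W
  offs <- seq_len(W) - chain$up - 1L
  pos <- outer(anchors0, offs, `+`)
  ok <- pos >= 0L & pos <= L - 1L
  ctx <- matrix(0L, n, W)
  for (k in seq_len(chain$order)) {
    # context position k slots back, only for window slots with ord >= k
    jmin <- k + 1L
    cols <- jmin:W
    cpos <- pos[, cols, drop = FALSE] - k
    cok <- cpos >= 0L
    ok[, cols] <- ok[, cols, drop = FALSE] & cok
    cc <- matrix(0L, n, length(cols))
    cc[cok] <- codes[cpos[cok] + 1L]
    # accumulate base-4 context id: earlier bases more significant
    ctx[, cols] <- ctx[, cols, drop = FALSE] +
      cc * rep(4L^(pmin(cols - 1L, chain$order) - k), each = n)
  }
  nuc <- matrix(0L, n, W)
  nuc[ok] <- codes[pos[ok] + 1L]
  idx <- rep(chain$off, each = n) + ctx * 4L + nuc + 1L
  idx[!ok] <- NA_integer_
  idx  # n x W integer matrix, NA where clipped
}

#' Sequence-specific bias weight at a fragment end
#'
#' The ratio of the observed to the expected Markov-chain probability of
#' the sequence window surrounding a fragment end (8 nt upstream through
#' 12 nt downstream of the end base, order-3 conditionals). Windows
#' clipped at target boundaries use shortened products. Returns exactly 1
#' when the bias model is disabled.
#'
#' @param target_seq Target nucleotide string.
#' @param end_pos 0-based position of the fragment end base on the target.
#' @param end `"five_prime"` or `"three_prime"`.
#' @param bias Bias model (component `bias` of a model parameter set).
#' @return A positive real weight.
#' @export
bias_weight <- function(target_seq, end_pos, end = c("five_prime", "three_prime"),
                        bias) {
  end <- match.arg(end)
  if (!isTRUE(bias$enabled)) return(1.0)
  codes <- nuc_codes(target_seq)
  obs <- if (end == "five_prime") bias$obs5 else bias$obs3
  expd <- if (end == "five_prime") bias$exp5 else bias$exp3
  idx <- .chain_slot_idx(obs, codes, as.integer(end_pos))
  idx <- idx[!is.na(idx)]
  w <- exp(sum(log(obs$p[idx])) - sum(log(expd$p[idx])))
  stopifnot(is.finite(w), w > 0)
  w
}

.bias_new <- function(enabled = TRUE, up = 8L, down = 12L, order = 3L) {
  list(enabled = enabled,
       obs5 = .chain_uniform(up, down, order),
       exp5 = .chain_uniform(up, down, order),
       obs3 = .chain_uniform(up, down, order),
       exp3 = .chain_uniform(up, down, order))
}

# --- model parameter snapshot ------------------------------------------

#' Create an initial model parameter snapshot
#'
#' Abundances, fragment length distribution and error matrices start
#' uniform; bias chains start equal (all weights 1). The snapshot is the
#' unit that gets broadcast to workers and must never be mutated by them.
#'
#' @param n_targets Number of targets.
#' @param max_frag_len Fragment length support (default 800).
#' @param max_read_len Number of modeled read positions.
#' @param bias_enabled Is sequence-specific bias correction on?
#' @param bias_up,bias_down,bias_order Window extent (upstream/downstream
#'   of the end base) and Markov order of the bias chains.
#' @return An object of class `"model_params"`.
#' @export
new_model_params <- function(n_targets, max_frag_len = 800L, max_read_len = 150L,
                             bias_enabled = TRUE, bias_up = 8L, bias_down = 12L,
                             bias_order = 3L) {
  stopifnot(n_targets >= 1L)
  structure(list(
    tau = rep(1 / n_targets, n_targets),
    log_tau = rep(-log(n_targets), n_targets),
    fld = .fld_new(max_frag_len),
    err = .err_new(max_read_len),
    bias = .bias_new(bias_enabled, bias_up, bias_down, bias_order)
  ), class = "model_params")
}

.params_set_tau <- function(params, tau) {
  params$tau <- tau
  params$log_tau <- log(tau)
  params
}

#' Log-likelihood contribution of one alignment
#'
#' Assembles, in log space, the full per-alignment likelihood term:
#' `log(tau_t) - log(efflen_t)` plus the fragment-length term (when both
#' ends are present, using the implied length; omitted for single-end
#' fragments whose length is unobserved), the substitution-error terms
#' for each sequenced end, and the log bias weights of the observed ends.
#'
#' @param frag The [fragment_record()] the alignment belongs to.
#' @param aln One of `frag$alignments`.
#' @param params A [new_model_params()] snapshot.
#' @param targets List of [target_record()]s indexed by `id + 1`.
#' @return Log-likelihood value.
#' @export
alignment_loglik <- function(frag, aln, params, targets) {
  if (aln$target_id < 0L || aln$target_id >= length(targets)) {
    stop(sprintf("alignment references unknown target id %d", aln$target_id),
         call. = FALSE)
  }
  t <- targets[[aln$target_id + 1L]]
  tseq <- unpack_nucleotides(t$seq, t$length)
  ll <- log(params$tau[[aln$target_id + 1L]]) -
    log(effective_length(t$length, params$fld))
  if (!is.null(aln$read_l) && !is.null(aln$read_r)) {
    implied <- aln$read_r$right_pos - aln$read_l$left_pos + 1L
    ll <- ll + fraglen_logprob(implied, params$fld)
  }
  for (r in list(aln$read_l, aln$read_r)) {
    if (is.null(r)) next
    refw <- substr(tseq, r$left_pos + 1L, r$right_pos + 1L)
    ll <- ll + error_loglik(r, refw, params$err)
  }
  if (isTRUE(params$bias$enabled)) {
    if (!is.null(aln$read_l)) {
      ll <- ll + log(bias_weight(tseq, aln$read_l$left_pos, "five_prime", params$bias))
    }
    if (!is.null(aln$read_r)) {
      ll <- ll + log(bias_weight(tseq, aln$read_r$right_pos, "three_prime", params$bias))
    }
  }
  ll
}
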
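# Idealized exhaustive aligner: reports every ungapped placement of a
# read with at most max_mismatches substitutions, on any target. Works by
# the pigeonhole principle: a read split into (max_mismatches + 1)
# disjoint chunks must have at least one chunk matching exactly, so exact
# chunk hits (found with vectorized rolling hashes) enumerate every
# candidate diagonal, which is then verified by direct comparison.

# per-position w-mer hashes of an integer code vector (exact in doubles:
# 4^w < 2^53 for w <= 26)
.kmer_hashes <- function(codes, w) {
  if (length(codes) < w) return(numeric(0))
  # filter: y_t = sum_i coef_i * x_{t-i+1}; coef = 4^(0:(w-1)) makes y_t the
  # hash of the window starting at t-w+1 with its first base most significant
  h <- stats::filter(as.numeric(codes), 4^(0:(w - 1L)), sides = 1L)
  as.numeric(h[w:length(codes)])   # hash of window starting at p = 1..L-w+1
}

# All placements of equal-length reads on the target set with at most
# max_mismatches substitutions. reads: integer code matrix (n x len).
# Returns a list with a placement table (read, tgt, start0, nmm) and the
# per-placement mismatch positions/codes.
.align_batch <- function(read_codes, ti, max_mismatches) {
  n_reads <- nrow(read_codes)
  len <- ncol(read_codes)
  mm <- as.integer(max_mismatches)
  w <- len %/% (mm + 1L)
  stopifnot(w >= 1L)

  # target k-mer hash table (global positions, boundary-safe per target)
  tpos <- vector("list", ti$n)
  thash <- vector("list", ti$n)
  for (tt in seq_len(ti$n)) {
    h <- .kmer_hashes(ti$codes[[tt]], w)
    thash[[tt]] <- h
    tpos[[tt]] <- if (length(h)) ti$off[tt] + seq_along(h) else integer(0)
  }
  tH <- unlist(thash); tP <- unlist(tpos)   # tP: global 1-based start of w-mer
  ord <- order(tH, method = "radix")
  tHs <- tH[ord]; tPs <- tP[ord]

  # chunk hashes for every read at offsets 0, w, 2w, ...
  pw <- 4^((w - 1L):0)
  cand_key <- numeric(0)
  Gtot <- sum(ti$lens)
  for (k in 0:mm) {
    o <- k * w
    qh <- as.numeric(read_codes[, (o + 1L):(o + w), drop = FALSE] %*% pw)
    lo <- findInterval(qh - 0.5, tHs) + 1L
    hi <- findInterval(qh + 0.5, tHs)
    nh <- pmax(hi - lo + 1L, 0L)
    if (sum(nh) == 0) next
    rd <- rep(seq_len(n_reads), nh)
    gp <- tPs[sequence(nh, from = lo)]          # global 1-based w-mer start
    st0g <- gp - 1L - o                          # global 0-based read start
    pos_ok <- st0g >= 0L
    cand_key <- c(cand_key, (rd[pos_ok] - 1) * as.numeric(Gtot) + st0g[pos_ok])
  }
  if (length(cand_key) == 0L) {
    return(list(placements = data.frame(read = integer(0), tgt = integer(0),
                                        start0 = integer(0), nmm = integer(0)),
                mm_idx = list(), mm_nuc = list()))
  }
  cand_key <- unique(cand_key)
  rd <- as.integer(cand_key %/% Gtot) + 1L
  g0 <- as.integer(cand_key %% Gtot)             # global 0-based read start
  # map back to target + local start; drop starts crossing a target boundary
  tt <- findInterval(g0, ti$off)                 # off is 0-based cumulative
  st0 <- g0 - ti$off[tt]
  ok <- st0 >= 0L & st0 + len <= ti$lens[tt]
  rd <- rd[ok]; tt <- tt[ok]; st0 <- st0[ok]
  if (length(rd) == 0L) {
    return(list(placements = data.frame(read = integer(0), tgt = integer(0),
                                        start0 = integer(0), nmm = integer(0)),
                mm_idx = list(), mm_nuc = list()))
  }

  # verify candidates in blocks
  keep_rd <- integer(0); keep_tt <- integer(0); keep_st <- integer(0)
  keep_nmm <- integer(0); keep_mi <- list(); keep_mn <- list()
  block <- 400000L
  for (b0 in seq(1L, length(rd), by = block)) {
    b1 <- min(b0 + block - 1L, length(rd))
    i <- b0:b1
    gidx <- outer(ti$off[tt[i]] + st0[i], 1:len, `+`)
    D <- matrix(ti$G[gidx], nrow = length(i)) != read_codes[rd[i], , drop = FALSE]
    nm <- rowSums(D)
    sel <- which(nm <= mm)
    if (length(sel) == 0L) next
    keep_rd <- c(keep_rd, rd[i][sel])
    keep_tt <- c(keep_tt, tt[i][sel])
    keep_st <- c(keep_st, st0[i][sel])
    keep_nmm <- c(keep_nmm, as.integer(nm[sel]))
    Dk <- D[sel, , drop = FALSE]
    wh <- which(Dk, arr.ind = TRUE)
    mi <- rep(list(integer(0)), length(sel))
    mn <- rep(list(integer(0)), length(sel))
    if (nrow(wh) > 0L) {
      o2 <- order(wh[, 1L], wh[, 2L])
      rows <- wh[o2, 1L]; cols <- wh[o2, 2L]
      sp <- split(cols, rows)
      ridx <- as.integer(names(sp))
      for (q in seq_along(sp)) {
        r <- ridx[q]
        mi[[r]] <- as.integer(sp[[q]] - 1L)                    # 0-based read pos
        mn[[r]] <- read_codes[keep_rd[length(keep_rd) - length(sel) + r],
                              sp[[q]], drop = TRUE]
      }
    }
    keep_mi <- c(keep_mi, mi)
    keep_mn <- c(keep_mn, mn)
  }
  o3 <- order(keep_rd, keep_tt, keep_st)
  list(placements = data.frame(read = keep_rd[o3], tgt = keep_tt[o3],
                               start0 = keep_st[o3], nmm = keep_nmm[o3]),
       mm_idx = keep_mi[o3], mm_nuc = keep_mn[o3])
}

# fast record constructors for simulator/aligner-built (already valid) data
.fast_read_aln <- function(first, left, right, mi, mn) {
  structure(list(first = first, left_pos = left, right_pos = right,
                 mismatch_indices = mi,
                 mismatch_nucs = if (length(mi)) pack_nucleotides(codes_to_string(mn)) else raw(0)),
            class = "read_alignment")
}

#' Enumerate all placements of a fragment's reads (idealized aligner)
#'
#' An exhaustive substitution-only aligner: reports every (target,
#' position) placement of the read(s) with at most `max_mismatches`
#' mismatches, as alignment records. For a read pair, end placements on
#' the same target are combined when the implied fragment length is
#' between the read length and `max_frag_len`. Fragments with no
#' placement yield an empty list.
#'
#' @param reads Character vector of read sequences: one element
#'   (single-end) or two (`c(left, right)`, both given on the forward
#'   strand of the originating target).
#' @param targets List of [target_record()]s.
#' @param max_mismatches Mismatch threshold (default 3).
#' @param max_frag_len Largest admissible implied fragment length for
#'   pairing.
#' @return List of [fragment_alignment()] records (possibly empty).
#' @export
emulate_aligner <- function(reads, targets, max_mismatches = 3L,
                            max_frag_len = 800L) {
  stopifnot(is.character(reads), length(reads) %in% c(1L, 2L))
  cfg <- em_config(bias_enabled = FALSE)
  ti <- .target_info(targets, cfg)
  out <- list()
  lens <- nchar(reads)
  al <- lapply(seq_along(reads), function(i) {
    rc <- matrix(nuc_codes(reads[[i]]), nrow = 1L)
    .align_batch(rc, ti, max_mismatches)
  })
  if (length(reads) == 1L) {
    pl <- al[[1L]]$placements
    return(lapply(seq_len(nrow(pl)), function(k) {
      fragment_alignment(pl$tgt[k] - 1L,
                         read_l = .fast_read_aln(TRUE, pl$start0[k],
                                                 pl$start0[k] + lens[1L] - 1L,
                                                 al[[1L]]$mm_idx[[k]],
                                                 al[[1L]]$mm_nuc[[k]]))
    }))
  }
  pl <- al[[1L]]$placements; pr <- al[[2L]]$placements
  if (nrow(pl) == 0L || nrow(pr) == 0L) return(list())
  for (kl in seq_len(nrow(pl))) {
    for (kr in which(pr$tgt == pl$tgt[kl])) {
      implied <- pr$start0[kr] + lens[2L] - pl$start0[kl]
      if (pr$start0[kr] >= pl$start0[kl] && implied <= max_frag_len) {
        out[[length(out) + 1L]] <- fragment_alignment(
          pl$tgt[kl] - 1L,
          read_l = .fast_read_aln(TRUE, pl$start0[kl],
                                  pl$start0[kl] + lens[1L] - 1L,
                                  al[[1L]]$mm_idx[[kl]], al[[1L]]$mm_nuc[[kl]]),
          read_r = .fast_read_aln(FALSE, pr$start0[kr],
                                  pr$start0[kr] + lens[2L] - 1L,
                                  al[[2L]]$mm_idx[[kr]], al[[2L]]$mm_nuc[[kr]]))
      }
    }
  }
  out
}
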
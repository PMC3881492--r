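# SAM/FASTA preprocessing into the compact record format, plus the
# writers the simulator uses to emit its SAM/FASTA mirror.

#' Convert a FASTA file to target records
#'
#' Reads target sequences (via Biostrings) and assigns each the integer id
#' given by its position in `header_order` — the reference order of the SAM
#' header the alignments will be parsed against. Sequences are uppercased;
#' characters outside `A/C/G/T` are rejected because the packed
#' representation has a 2-bit alphabet.
#'
#' @param fasta Path to a (possibly line-wrapped) FASTA file.
#' @param header_order Character vector of target names in SAM header
#'   order; defaults to the FASTA's own order.
#' @return List of [target_record()]s, ordered by id (`0..n-1`).
#' @export
fasta_to_target_records <- function(fasta, header_order = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  nms <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nms)) {
    stop(sprintf("duplicate target name in FASTA: '%s'", nms[duplicated(nms)][1L]),
         call. = FALSE)
  }
  if (is.null(header_order)) header_order <- nms
  missing <- setdiff(header_order, nms)
  if (length(missing) > 0L) {
    stop(sprintf("target '%s' in header order but missing from FASTA", missing[1L]),
         call. = FALSE)
  }
  chr <- toupper(as.character(seqs))
  names(chr) <- nms
  lapply(seq_along(header_order), function(i) {
    target_record(name = header_order[[i]], id = i - 1L, seq = chr[[header_order[[i]]]])
  })
}

# Parse a SAM text file into a data frame of mapped alignment lines.
# Uses Rsamtools (SAM -> BAM -> scanBam) so the standard parser does the
# format work; indexDestination = FALSE keeps the original record order.
.scan_sam <- function(sam) {
  bam <- tempfile(fileext = ".bam")
  on.exit(unlink(c(bam, paste0(bam, ".bai")), force = TRUE), add = TRUE)
  Rsamtools::asBam(sam, destination = sub("\\.bam$", "", bam),
                   overwrite = TRUE, indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "mpos", "cigar", "seq"))
  res <- Rsamtools::scanBam(bam, param = p)[[1L]]
  data.frame(qname = res$qname,
             flag = res$flag,
             rname = as.character(res$rname),
             pos = res$pos,
             mpos = res$mpos,
             cigar = res$cigar,
             seq = as.character(res$seq),
             stringsAsFactors = FALSE)
}

#' Convert name-grouped SAM alignments to fragment records
#'
#' Aggregates all alignment lines of each query into one fragment record.
#' The SAM must be grouped by query name (all lines of a fragment
#' adjacent); this keeps preprocessing streaming-friendly and is checked —
#' a query reappearing after a different one is an error. 1-based SAM
#' positions become 0-based endpoints; mismatches are recovered by
#' comparing the read sequence against the packed reference. Alignments
#' whose CIGAR contains indels or clipping (`I/D/N/S/H/P`) are skipped
#' with a warning: the record format encodes substitutions only.
#'
#' For paired alignments the two ends of each placement are matched via
#' their mate positions; the leftmost end becomes `read_l`.
#'
#' @param sam Path to a SAM text file.
#' @param targets List of [target_record()]s covering every reference name.
#' @return List of [fragment_record()]s in order of first appearance.
#' @export
sam_to_fragment_records <- function(sam, targets) {
  df <- .scan_sam(sam)
  df <- df[bitwAnd(df$flag, 4L) == 0L, , drop = FALSE]   # mapped only
  if (nrow(df) == 0L) return(list())

  tnames <- vapply(targets, `[[`, character(1), "name")
  tmap <- match(df$rname, tnames)
  if (anyNA(tmap)) {
    stop(sprintf("reference '%s' absent from target set", df$rname[is.na(tmap)][1L]),
         call. = FALSE)
  }
  unknown <- grepl("[IDNSHP]", df$cigar)
  if (any(unknown)) {
    warning(sprintf("skipping %d alignment line(s) with indel/clip CIGAR operations",
                    sum(unknown)), call. = FALSE)
    df <- df[!unknown, , drop = FALSE]
    tmap <- tmap[!unknown]
  }
  if (nrow(df) == 0L) return(list())

  grp <- rle(df$qname)
  if (anyDuplicated(grp$values)) {
    stop("SAM is not grouped by query name; sort/group alignments by name first",
         call. = FALSE)
  }
  tseqs <- lapply(targets, function(t) unpack_nucleotides(t$seq, t$length))
  names(tseqs) <- tnames

  ends <- cumsum(grp$lengths)
  starts <- ends - grp$lengths + 1L
  out <- vector("list", length(grp$values))
  for (g in seq_along(grp$values)) {
    rows <- starts[g]:ends[g]
    sub <- df[rows, , drop = FALSE]
    tid <- tmap[rows] - 1L
    paired <- any(bitwAnd(sub$flag, 1L) != 0L)
    mk_read <- function(i) {
      rseq <- toupper(sub$seq[i])
      len <- nchar(rseq)
      lp <- sub$pos[i] - 1L
      rp <- lp + len - 1L
      tname <- sub$rname[i]
      tlen <- nchar(tseqs[[tname]])
      if (rp >= tlen) {
        stop(sprintf("alignment of '%s' extends beyond target '%s'",
                     sub$qname[i], tname), call. = FALSE)
      }
      ref <- substr(tseqs[[tname]], lp + 1L, rp + 1L)
      rc <- nuc_codes(rseq); fc <- nuc_codes(ref)
      mm <- which(rc != fc) - 1L
      first <- if (paired) bitwAnd(sub$flag[i], 64L) != 0L else TRUE
      read_alignment(first = first, left_pos = lp, right_pos = rp,
                     mismatch_indices = mm,
                     mismatch_nucs = pack_nucleotides(codes_to_string(rc[mm + 1L])))
    }
    if (!paired) {
      alns <- lapply(seq_len(nrow(sub)), function(i) {
        fragment_alignment(tid[i], read_l = mk_read(i))
      })
    } else {
      # pair the two ends of each placement: line i mates with the line of
      # the same target whose pos equals i's mate pos and vice versa;
      # occurrence counters disambiguate repeated identical placements
      key <- paste(sub$rname, sub$pos, sub$mpos)
      mate_key <- paste(sub$rname, sub$mpos, sub$pos)
      idx <- seq_len(nrow(sub))
      occ <- stats::ave(idx, key, FUN = seq_along)
      mate <- integer(length(idx))
      self <- key == mate_key  # both ends at the same span: pair consecutively
      if (any(self)) {
        for (kk in unique(key[self])) {
          ii <- idx[self & key == kk]
          if (length(ii) %% 2L != 0L) {
            stop(sprintf("unpaired mate in alignments of '%s'", sub$qname[1L]),
                 call. = FALSE)
          }
          sw <- matrix(ii, nrow = 2L)[2:1, ]
          mate[ii] <- as.integer(sw)
        }
      }
      if (any(!self)) {
        m <- match(paste(mate_key[!self], occ[!self]), paste(key, occ))
        if (anyNA(m)) {
          stop(sprintf("unpaired mate in alignments of '%s'", sub$qname[1L]),
               call. = FALSE)
        }
        mate[!self] <- m
      }
      take <- which(idx < mate)
      alns <- lapply(take, function(i) {
        j <- mate[i]
        ri <- mk_read(i); rj <- mk_read(j)
        if (ri$left_pos <= rj$left_pos) {
          fragment_alignment(tid[i], read_l = ri, read_r = rj)
        } else {
          fragment_alignment(tid[i], read_l = rj, read_r = ri)
        }
      })
    }
    out[[g]] <- fragment_record(name = grp$values[g], paired = paired, alignments = alns)
  }
  out
}

#' Preprocess SAM + FASTA into the compact record files
#'
#' The end-to-end preprocessing step: reads a name-grouped SAM and the
#' target FASTA, and writes the two newline-delimited base64 record files
#' (fragments and targets) that the quantifier and the partitioned
#' executor consume.
#'
#' @param sam,fasta Input paths.
#' @param out_frags,out_targets Output paths for the record files.
#' @return Invisibly, a list with the parsed records.
#' @export
preprocess_sam_fasta <- function(sam, fasta, out_frags, out_targets) {
  sam_names <- .sam_header_order(sam)
  targets <- fasta_to_target_records(fasta, header_order = sam_names)
  frags <- sam_to_fragment_records(sam, targets)
  write_record_file(targets, out_targets)
  write_record_file(frags, out_frags)
  invisible(list(fragments = frags, targets = targets))
}

.sam_header_order <- function(sam) {
  hdr <- readLines(sam, n = 10000L)
  sq <- grep("^@SQ\t", hdr, value = TRUE)
  if (length(sq) == 0L) stop("SAM has no @SQ header lines", call. = FALSE)
  sub("^.*\tSN:([^\t]+).*$", "\\1", sq)
}

# --- writers (simulator mirror) ----------------------------------------

#' Write target records as FASTA
#' @param targets List of [target_record()]s.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly `path`.
#' @export
write_targets_fasta <- function(targets, path, width = 70L) {
  seqs <- Biostrings::DNAStringSet(vapply(targets, function(t) {
    unpack_nucleotides(t$seq, t$length)
  }, character(1)))
  names(seqs) <- vapply(targets, `[[`, character(1), "name")
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(path)
}

# Write fragment records as SAM text. Needs the target set to reconstruct
# read sequences from the reference plus mismatch fields.
#' Write fragment records as a SAM text file
#'
#' Reconstructs each read sequence from the reference window and the
#' stored mismatches, and emits minimal name-grouped SAM lines
#' (FLAG/RNAME/POS/CIGAR/SEQ). Used by the simulator to mirror its native
#' records in the standard format.
#'
#' @param fragments List of [fragment_record()]s.
#' @param targets List of [target_record()]s.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_fragments_sam <- function(fragments, targets, path) {
  tseqs <- lapply(targets, function(t) unpack_nucleotides(t$seq, t$length))
  tnames <- vapply(targets, `[[`, character(1), "name")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tGO:query", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", tnames,
                     vapply(targets, `[[`, integer(1), "length")), con)
  read_seq <- function(tid, r) {
    ref <- substr(tseqs[[tid + 1L]], r$left_pos + 1L, r$right_pos + 1L)
    if (length(r$mismatch_indices) == 0L) return(ref)
    codes <- nuc_codes(ref)
    codes[r$mismatch_indices + 1L] <-
      .unpack_codes(r$mismatch_nucs, length(r$mismatch_indices))
    codes_to_string(codes)
  }
  for (fr in fragments) {
    n_aln <- length(fr$alignments)
    for (k in seq_len(n_aln)) {
      a <- fr$alignments[[k]]
      sec <- if (k > 1L) 256L else 0L
      if (!fr$paired) {
        r <- if (!is.null(a$read_l)) a$read_l else a$read_r
        s <- read_seq(a$target_id, r)
        writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                           fr$name, sec, tnames[a$target_id + 1L],
                           r$left_pos + 1L, nchar(s), s), con)
      } else {
        rl <- a$read_l; rr <- a$read_r
        sl <- read_seq(a$target_id, rl); sr <- read_seq(a$target_id, rr)
        fl_l <- 1L + 2L + sec + (if (rl$first) 64L else 128L)
        fl_r <- 1L + 2L + sec + (if (rr$first) 64L else 128L)
        tlen <- rr$right_pos - rl$left_pos + 1L
        writeLines(c(
          sprintf("%s\t%d\t%s\t%d\t255\t%dM\t=\t%d\t%d\t%s\t*",
                  fr$name, fl_l, tnames[a$target_id + 1L], rl$left_pos + 1L,
                  nchar(sl), rr$left_pos + 1L, tlen, sl),
          sprintf("%s\t%d\t%s\t%d\t255\t%dM\t=\t%d\t%d\t%s\t*",
                  fr$name, fl_r, tnames[a$target_id + 1L], rr$left_pos + 1L,
                  nchar(sr), rl$left_pos + 1L, -tlen, sr)), con)
      }
    }
  }
  invisible(path)
}
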
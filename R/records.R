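# Record types for the compact alignment/target interchange format.
# A dataset is two newline-delimited files: one record per line, each line
# the base64 of a binary (protobuf wire format) serialization. Field layout:
#
#   Fragment:           name (1, string), paired (2, bool),
#                       alignments (3, repeated FragmentAlignment)
#   FragmentAlignment:  target_id (1, uint32), read_l (2, ReadAlignment),
#                       read_r (3, ReadAlignment)
#   ReadAlignment:      first (1, bool), left_pos (2, uint32),
#                       right_pos (3, uint32), mismatch_indices (4, bytes),
#                       mismatch_nucs (5, bytes)
#   Target:             name (1, string), id (2, uint32),
#                       length (3, uint32), seq (4, bytes)
#
# Positions are 0-based; right_pos is the inclusive right endpoint.
# mismatch_indices holds one byte per 0-based read position (read length is
# bounded at 255); mismatch_nucs packs the observed bases at 2 bits each.

#' Construct a target record
#'
#' A target is one reference sequence fragments may originate from (for
#' RNA-Seq, a transcript). The nucleotide sequence is stored 2-bit packed.
#'
#' @param name Unique identifier string.
#' @param id Non-negative integer index (position in SAM header order).
#' @param seq Nucleotide string over `{A,C,G,T}`, or `NULL` if `packed` and
#'   `length` are given directly.
#' @param packed,length Alternative to `seq`: a packed raw vector and the
#'   nucleotide count.
#' @return An object of class `"target_record"`.
#' @export
target_record <- function(name, id, seq = NULL, packed = NULL, length = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  id <- as.integer(id)
  stopifnot(length(id) == 1L, !is.na(id), id >= 0L)
  if (!is.null(seq)) {
    seq <- toupper(seq)
    packed <- pack_nucleotides(seq)
    length <- nchar(seq)
  } else {
    stopifnot(is.raw(packed), is.numeric(length))
    length <- as.integer(length)
    if (base::length(packed) != (length + 3L) %/% 4L) {
      stop("packed byte count must equal ceiling(length/4)", call. = FALSE)
    }
  }
  structure(list(name = name, id = id, length = as.integer(length), seq = packed),
            class = "target_record")
}

#' Construct a read alignment record
#'
#' Describes the placement of one sequenced end on a target, storing only
#' the 0-based endpoints and the substitution differences from the
#' reference (indices within the read and the observed bases, 2-bit
#' packed). Gapped alignments are not representable.
#'
#' @param first Logical: was this end sequenced first?
#' @param left_pos,right_pos 0-based left/right endpoints on the target
#'   (`right_pos` inclusive).
#' @param mismatch_indices Integer vector of 0-based read positions that
#'   differ from the reference, strictly increasing.
#' @param mismatch_nucs Observed nucleotides at those positions: either a
#'   string or an already-packed raw vector.
#' @return An object of class `"read_alignment"`.
#' @export
read_alignment <- function(first, left_pos, right_pos,
                           mismatch_indices = integer(0),
                           mismatch_nucs = raw(0)) {
  stopifnot(is.logical(first), length(first) == 1L)
  left_pos <- as.integer(left_pos); right_pos <- as.integer(right_pos)
  stopifnot(left_pos >= 0L, right_pos >= left_pos)
  mismatch_indices <- as.integer(mismatch_indices)
  if (is.character(mismatch_nucs)) mismatch_nucs <- pack_nucleotides(mismatch_nucs)
  stopifnot(is.raw(mismatch_nucs))
  n_mm <- length(mismatch_indices)
  if (length(mismatch_nucs) != (n_mm + 3L) %/% 4L) {
    stop("mismatch_nucs must pack exactly length(mismatch_indices) bases", call. = FALSE)
  }
  if (n_mm > 0L) {
    if (any(diff(mismatch_indices) <= 0L)) {
      stop("mismatch_indices must be strictly increasing", call. = FALSE)
    }
    if (mismatch_indices[1L] < 0L) stop("mismatch_indices must be >= 0", call. = FALSE)
    read_len <- right_pos - left_pos + 1L
    if (any(mismatch_indices >= read_len)) {
      stop("mismatch index beyond read length", call. = FALSE)
    }
    if (any(mismatch_indices > 255L)) {
      stop("read positions above 255 cannot be stored (one byte per index)", call. = FALSE)
    }
  }
  structure(list(first = first, left_pos = left_pos, right_pos = right_pos,
                 mismatch_indices = mismatch_indices, mismatch_nucs = mismatch_nucs),
            class = "read_alignment")
}

#' Construct a fragment alignment record
#'
#' One candidate origin of a fragment: the target index plus the read
#' placements for the 5' (left) and/or 3' (right) ends.
#'
#' @param target_id Integer index of the aligned target.
#' @param read_l,read_r [read_alignment()] records or `NULL`; at least one
#'   must be present. `read_l` is the leftmost end.
#' @return An object of class `"fragment_alignment"`.
#' @export
fragment_alignment <- function(target_id, read_l = NULL, read_r = NULL) {
  target_id <- as.integer(target_id)
  stopifnot(length(target_id) == 1L, !is.na(target_id), target_id >= 0L)
  if (is.null(read_l) && is.null(read_r)) {
    stop("a fragment alignment needs at least one aligned end", call. = FALSE)
  }
  for (r in list(read_l, read_r)) {
    if (!is.null(r) && !inherits(r, "read_alignment")) {
      stop("read_l/read_r must be read_alignment records", call. = FALSE)
    }
  }
  structure(list(target_id = target_id, read_l = read_l, read_r = read_r),
            class = "fragment_alignment")
}

#' Construct a fragment record
#'
#' One sequenced fragment together with all its candidate alignments.
#'
#' @param name Unique query name.
#' @param paired Logical: were both ends sequenced? If so every alignment
#'   must carry both ends.
#' @param alignments Nonempty list of [fragment_alignment()] records.
#' @return An object of class `"fragment_record"`.
#' @export
fragment_record <- function(name, paired, alignments) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.logical(paired), length(paired) == 1L, is.list(alignments))
  if (length(alignments) == 0L) {
    stop(sprintf("fragment '%s' has no alignments", name), call. = FALSE)
  }
  for (a in alignments) {
    if (!inherits(a, "fragment_alignment")) {
      stop("alignments must be fragment_alignment records", call. = FALSE)
    }
    if (paired && (is.null(a$read_l) || is.null(a$read_r))) {
      stop(sprintf("paired fragment '%s' has an alignment missing one end", name),
           call. = FALSE)
    }
  }
  structure(list(name = name, paired = paired, alignments = alignments),
            class = "fragment_record")
}

#' Validate a record against a target set
#'
#' Checks the record invariants that need the target sequences: position
#' bounds and target-id existence. Target-set ids must be dense `0..n-1`.
#'
#' @param record A `fragment_record` or `target_record`.
#' @param targets List of `target_record`s indexed by `id + 1`.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_record <- function(record, targets) {
  if (inherits(record, "target_record")) {
    if (length(record$seq) != (record$length + 3L) %/% 4L) {
      stop("target packed byte count must equal ceiling(length/4)", call. = FALSE)
    }
    return(invisible(TRUE))
  }
  stopifnot(inherits(record, "fragment_record"))
  n_t <- length(targets)
  for (a in record$alignments) {
    if (a$target_id < 0L || a$target_id >= n_t) {
      stop(sprintf("fragment '%s' aligned to unknown target id %d",
                   record$name, a$target_id), call. = FALSE)
    }
    tlen <- targets[[a$target_id + 1L]]$length
    for (r in list(a$read_l, a$read_r)) {
      if (is.null(r)) next
      if (r$right_pos >= tlen) {
        stop(sprintf("fragment '%s': alignment right endpoint %d beyond target length %d",
                     record$name, r$right_pos, tlen), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.target_record <- function(x, ...) {
  cat(sprintf("<target %s id=%d length=%d>\n", x$name, x$id, x$length))
  invisible(x)
}

#' @export
print.fragment_record <- function(x, ...) {
  cat(sprintf("<fragment %s %s, %d alignment(s)>\n", x$name,
              if (x$paired) "paired" else "single-end", length(x$alignments)))
  invisible(x)
}
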
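# 2-bit nucleotide packing. Encoding: A=00, C=01, G=10, T=11, first
# nucleotide occupies the most significant bit pair of each byte; trailing
# pad bits are zero. Only the unambiguous DNA alphabet is representable.

.NUC_CODE <- {
  x <- rep(NA_integer_, 128L)
  x[utf8ToInt("A") + 1L] <- 0L
  x[utf8ToInt("C") + 1L] <- 1L
  x[utf8ToInt("G") + 1L] <- 2L
  x[utf8ToInt("T") + 1L] <- 3L
  x
}
.NUC_CHAR <- c("A", "C", "G", "T")

#' Convert a nucleotide string to integer codes
#'
#' Maps `A,C,G,T` to `0,1,2,3`. Internal workhorse shared by the packing,
#' likelihood and simulator code.
#'
#' @param seq A single character string over `{A,C,G,T}`.
#' @return Integer vector of codes in `0:3`.
#' @keywords internal
nuc_codes <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return(integer(0))
  ints <- utf8ToInt(seq)
  bad <- ints > 127L
  codes <- rep(NA_integer_, length(ints))
  codes[!bad] <- .NUC_CODE[ints[!bad] + 1L]
  if (anyNA(codes)) {
    pos <- which(is.na(codes))[1L]
    stop(sprintf("unsupported nucleotide '%s' at position %d (only A/C/G/T can be 2-bit packed)",
                 substr(seq, pos, pos), pos), call. = FALSE)
  }
  codes
}

#' Pack nucleotides at 2 bits per base
#'
#' Encodes a DNA string into a raw vector at exactly 2 bits per nucleotide:
#' `ceiling(nchar(seq)/4)` bytes, first base in the most significant bit
#' pair, pad bits zero. Characters outside `A/C/G/T` (including `N` and
#' other IUPAC codes) are rejected — a 2-bit alphabet cannot represent them.
#'
#' @param seq A character string over `{A,C,G,T}` (may be empty).
#' @return A raw vector of length `ceiling(nchar(seq)/4)`.
#' @seealso [unpack_nucleotides()]
#' @examples
#' pack_nucleotides("ACGT")  # one byte: 0b00011011
#' @export
pack_nucleotides <- function(seq) {
  codes <- nuc_codes(seq)
  n <- length(codes)
  if (n == 0L) return(raw(0))
  nbytes <- (n + 3L) %/% 4L
  pad <- nbytes * 4L - n
  if (pad > 0L) codes <- c(codes, integer(pad))
  m <- matrix(codes, nrow = 4L)
  as.raw(m[1L, ] * 64L + m[2L, ] * 16L + m[3L, ] * 4L + m[4L, ])
}

#' Unpack 2-bit packed nucleotides
#'
#' Inverse of [pack_nucleotides()]: recovers the first `n` nucleotides from
#' a packed raw vector. Pad bits beyond `n` are ignored.
#'
#' @param packed Raw vector holding at least `ceiling(n/4)` bytes.
#' @param n Number of nucleotides to recover.
#' @return A character string of length `n`.
#' @export
unpack_nucleotides <- function(packed, n) {
  stopifnot(is.raw(packed), is.numeric(n), length(n) == 1L, n >= 0)
  n <- as.integer(n)
  if (n == 0L) return("")
  need <- (n + 3L) %/% 4L
  if (length(packed) < need) {
    stop(sprintf("packed sequence too short: need %d bytes for %d nucleotides, have %d",
                 need, n, length(packed)), call. = FALSE)
  }
  codes_to_string(.unpack_codes(packed, n))
}

# integer codes (0..3) for the first n bases of a packed raw vector
.unpack_codes <- function(packed, n) {
  b <- as.integer(packed[seq_len((n + 3L) %/% 4L)])
  codes <- rbind(b %/% 64L, (b %/% 16L) %% 4L, (b %/% 4L) %% 4L, b %% 4L)
  as.integer(codes)[seq_len(n)]
}

.code_ints <- function(codes) {
  # map 0..3 -> utf8 ints of A,C,G,T
  c(65L, 67L, 71L, 84L)[codes + 1L]
}

#' Convert integer codes back to a nucleotide string
#' @param codes Integer vector over `0:3`.
#' @return A character string.
#' @keywords internal
codes_to_string <- function(codes) {
  if (length(codes) == 0L) return("")
  intToUtf8(.code_ints(codes))
}
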
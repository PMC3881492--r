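# Minimal Protocol-Buffers wire-format codec for the record schemas.
# Only two wire types are needed: varint (0) for bool/uint32 and
# length-delimited (2) for strings, byte arrays and nested messages.
# Field numbers follow the schema comment in records.R.

.enc_varint <- function(x) {
  x <- as.integer(x)
  stopifnot(x >= 0L)
  if (x < 128L) return(as.raw(x))
  out <- raw(0)
  while (x >= 128L) {
    out <- c(out, as.raw(bitwOr(bitwAnd(x, 127L), 128L)))
    x <- bitwShiftR(x, 7L)
  }
  c(out, as.raw(x))
}

.enc_key <- function(field, wire) .enc_varint(field * 8L + wire)

.enc_ld <- function(field, payload) {
  c(.enc_key(field, 2L), .enc_varint(length(payload)), payload)
}

.enc_uint <- function(field, x) c(.enc_key(field, 0L), .enc_varint(x))

.serialize_read_alignment <- function(r) {
  c(.enc_uint(1L, as.integer(r$first)),
    .enc_uint(2L, r$left_pos),
    .enc_uint(3L, r$right_pos),
    .enc_ld(4L, as.raw(r$mismatch_indices)),
    .enc_ld(5L, r$mismatch_nucs))
}

.serialize_fragment_alignment <- function(a) {
  out <- .enc_uint(1L, a$target_id)
  if (!is.null(a$read_l)) out <- c(out, .enc_ld(2L, .serialize_read_alignment(a$read_l)))
  if (!is.null(a$read_r)) out <- c(out, .enc_ld(3L, .serialize_read_alignment(a$read_r)))
  out
}

.serialize_record <- function(record) {
  if (inherits(record, "target_record")) {
    c(.enc_ld(1L, charToRaw(record$name)),
      .enc_uint(2L, record$id),
      .enc_uint(3L, record$length),
      .enc_ld(4L, record$seq))
  } else if (inherits(record, "fragment_record")) {
    out <- c(.enc_ld(1L, charToRaw(record$name)),
             .enc_uint(2L, as.integer(record$paired)))
    alns <- lapply(record$alignments, function(a) .enc_ld(3L, .serialize_fragment_alignment(a)))
    c(out, unlist(alns, use.names = FALSE))
  } else {
    stop("record must be a fragment_record or target_record", call. = FALSE)
  }
}

# --- decoding -----------------------------------------------------------

.dec_varint <- function(buf, pos) {
  x <- 0L; shift <- 0L
  repeat {
    if (pos > length(buf)) stop("truncated varint", call. = FALSE)
    b <- as.integer(buf[pos]); pos <- pos + 1L
    x <- bitwOr(x, bitwShiftL(bitwAnd(b, 127L), shift))
    if (b < 128L) break
    shift <- shift + 7L
    if (shift > 28L) stop("varint too large", call. = FALSE)
  }
  list(value = x, pos = pos)
}

# Parse one message level into a list: fields[[n]] is a list of payloads
# (raw vectors for wire type 2, integers for wire type 0), in order.
.dec_fields <- function(buf) {
  fields <- list()
  pos <- 1L
  n <- length(buf)
  while (pos <= n) {
    k <- .dec_varint(buf, pos); pos <- k$pos
    field <- bitwShiftR(k$value, 3L)
    wire <- bitwAnd(k$value, 7L)
    if (field < 1L) stop("invalid field number", call. = FALSE)
    if (wire == 0L) {
      v <- .dec_varint(buf, pos); pos <- v$pos
      val <- v$value
    } else if (wire == 2L) {
      l <- .dec_varint(buf, pos); pos <- l$pos
      if (pos + l$value - 1L > n) stop("truncated length-delimited field", call. = FALSE)
      val <- if (l$value > 0L) buf[pos:(pos + l$value - 1L)] else raw(0)
      pos <- pos + l$value
    } else {
      stop(sprintf("unsupported wire type %d", wire), call. = FALSE)
    }
    fi <- as.character(field)
    fields[[fi]] <- c(fields[[fi]], list(val))
  }
  fields
}

.field1 <- function(fields, n, what) {
  v <- fields[[as.character(n)]]
  if (is.null(v)) stop(sprintf("missing required field %d (%s)", n, what), call. = FALSE)
  v[[length(v)]]
}

.deserialize_read_alignment <- function(buf) {
  f <- .dec_fields(buf)
  mm_idx <- as.integer(.field1(f, 4L, "mismatch_indices"))
  read_alignment(first = .field1(f, 1L, "first") != 0L,
                 left_pos = .field1(f, 2L, "left_pos"),
                 right_pos = .field1(f, 3L, "right_pos"),
                 mismatch_indices = mm_idx,
                 mismatch_nucs = .field1(f, 5L, "mismatch_nucs"))
}

.deserialize_fragment_alignment <- function(buf) {
  f <- .dec_fields(buf)
  rl <- f[["2"]]; rr <- f[["3"]]
  fragment_alignment(
    target_id = .field1(f, 1L, "target_id"),
    read_l = if (!is.null(rl)) .deserialize_read_alignment(rl[[1L]]),
    read_r = if (!is.null(rr)) .deserialize_read_alignment(rr[[1L]]))
}

.deserialize_record <- function(buf, kind) {
  f <- .dec_fields(buf)
  if (kind == "target") {
    seq <- .field1(f, 4L, "seq")
    target_record(name = rawToChar(.field1(f, 1L, "name")),
                  id = .field1(f, 2L, "id"),
                  packed = seq, length = .field1(f, 3L, "length"))
  } else if (kind == "fragment") {
    alns <- lapply(f[["3"]], .deserialize_fragment_alignment)
    if (length(alns) == 0L) stop("fragment record with no alignments", call. = FALSE)
    fragment_record(name = rawToChar(.field1(f, 1L, "name")),
                    paired = .field1(f, 2L, "paired") != 0L,
                    alignments = alns)
  } else {
    stop("kind must be 'fragment' or 'target'", call. = FALSE)
  }
}

# --- line codec ---------------------------------------------------------

#' Encode a record as one base64 text line
#'
#' Serializes a fragment or target record to the binary wire format and
#' base64-encodes it so the result contains no newline: every record is a
#' self-contained line, which is what makes the files partitionable by
#' line ranges.
#'
#' @param record A `fragment_record` or `target_record`.
#' @return A single character string (no newline).
#' @seealso [decode_record_line()]
#' @export
encode_record_line <- function(record) {
  line <- jsonlite::base64_enc(.serialize_record(record))
  line <- gsub("[\r\n]", "", line)
  line
}

#' Decode one base64 record line
#'
#' @param line A character string produced by [encode_record_line()].
#' @param kind `"fragment"` or `"target"`.
#' @return The decoded record.
#' @export
decode_record_line <- function(line, kind = c("fragment", "target")) {
  kind <- match.arg(kind)
  stopifnot(is.character(line), length(line) == 1L)
  if (!grepl("^[A-Za-z0-9+/]*={0,2}$", line) || nchar(line) %% 4L != 0L) {
    stop("malformed base64 record line", call. = FALSE)
  }
  buf <- jsonlite::base64_dec(line)
  .deserialize_record(buf, kind)
}

#' Write records to a newline-delimited base64 file
#'
#' @param records List of records (all fragments or all targets).
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
write_record_file <- function(records, path) {
  lines <- vapply(records, encode_record_line, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a newline-delimited base64 record file
#'
#' Each line is decoded independently; a malformed line is reported with
#' its line number.
#'
#' @param path Input file path.
#' @param kind `"fragment"` or `"target"`.
#' @return List of decoded records.
#' @export
read_record_file <- function(path, kind = c("fragment", "target")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    out[[i]] <- tryCatch(decode_record_line(lines[[i]], kind),
                         error = function(e) {
                           stop(sprintf("line %d of %s: %s", i, path, conditionMessage(e)),
                                call. = FALSE)
                         })
  }
  out
}
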
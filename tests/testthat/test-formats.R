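# Record format: 2-bit packing, wire serialization, base64 line codec,
# and the SAM/FASTA preprocessing path.

test_that("packing encodes at exactly 2 bits per nucleotide with the stated bit layout", {
  p <- pack_nucleotides("ACGT")
  expect_identical(p, as.raw(0x1b))           # 00 01 10 11, high bits first
  expect_identical(pack_nucleotides(""), raw(0))
  s <- random_seq(4096, seed = 1)
  expect_identical(length(pack_nucleotides(s)), 1024L)
  # partial final byte, pad bits zero
  expect_identical(pack_nucleotides("AAA"), as.raw(0x00))
  expect_identical(pack_nucleotides("TTT"), as.raw(0xfc))
})

test_that("pack/unpack round-trips and rejects unsupported characters", {
  for (seed in 1:5) {
    n <- sample(0:200, 1L)
    s <- random_seq(max(n, 1), seed = seed)
    s <- substr(s, 1, n)
    expect_identical(unpack_nucleotides(pack_nucleotides(s), nchar(s)), s)
  }
  expect_error(pack_nucleotides("ACGNT"), "position 4")
  expect_error(pack_nucleotides("acgt"), "position 1")  # case is the caller's job
  expect_error(unpack_nucleotides(raw(1), 5), "too short")
})

test_that("record lines are newline-free base64 and decode to identical records", {
  set.seed(42)
  rand_read <- function(first, left, len) {
    n_mm <- sample(0:3, 1L)
    mm <- if (n_mm > 0) sort(sample(0:(len - 1L), n_mm)) else integer(0)
    read_alignment(first, left, left + len - 1L, mm,
                   if (n_mm > 0) substr(random_seq(n_mm), 1, n_mm) else raw(0))
  }
  for (i in 1:20) {
    paired <- runif(1) < 0.5
    alns <- lapply(seq_len(sample(1:4, 1L)), function(j) {
      l <- rand_read(TRUE, sample(0:50, 1L), 20L)
      if (paired) {
        r <- rand_read(FALSE, l$left_pos + sample(0:30, 1L), 20L)
        fragment_alignment(sample(0:5, 1L), read_l = l, read_r = r)
      } else {
        fragment_alignment(sample(0:5, 1L), read_l = l)
      }
    })
    fr <- fragment_record(sprintf("frag%03d", i), paired, alns)
    line <- encode_record_line(fr)
    expect_false(grepl("\n", line, fixed = TRUE))
    expect_identical(decode_record_line(line, "fragment"), fr)
  }
  tr <- target_record("tX", 3L, seq = random_seq(137, seed = 9))
  expect_identical(decode_record_line(encode_record_line(tr), "target"), tr)
  # distinct records give distinct lines
  tr2 <- target_record("tY", 4L, seq = random_seq(137, seed = 10))
  expect_false(encode_record_line(tr) == encode_record_line(tr2))
})

test_that("malformed or truncated lines raise parse errors, not partial records", {
  expect_error(decode_record_line("not-base64!", "fragment"), "base64")
  tr <- target_record("t", 0L, seq = "ACGTACGT")
  line <- encode_record_line(tr)
  truncated <- substr(line, 1, nchar(line) - 8)
  expect_error(decode_record_line(truncated, "target"))
  expect_error(read_record_file(
    withr::local_tempfile(lines = c(line, "####")), "target"), "line 2")
})

test_that("record files are line-independent and smaller than the SAM mirror", {
  sm <- small_sim(seed = 21, n_fragments = 800L)
  dir <- withr::local_tempdir()
  sim <- simulate_experiment(sm$targets, sm$cfg, out_dir = dir)
  frag_lines <- readLines(file.path(dir, "fragments.pb64"))
  # every line parses on its own, in any order
  idx <- sample(seq_along(frag_lines), 25L)
  for (i in idx) expect_s3_class(decode_record_line(frag_lines[i], "fragment"),
                                 "fragment_record")
  expect_lt(file.size(file.path(dir, "fragments.pb64")),
            file.size(file.path(dir, "fragments.sam")))
  # record stream round-trips through the file
  back <- read_record_file(file.path(dir, "fragments.pb64"), "fragment")
  expect_identical(back, sim$fragments)
})

test_that("record validation enforces target bounds and id existence", {
  tg <- toy_targets(2L, len = 50L)
  ok <- toy_fragment("f", 0L, read_len = 10L, pos = 40L)
  expect_true(validate_record(ok, tg))
  expect_true(validate_record(tg[[1]], tg))
  beyond <- toy_fragment("g", 0L, read_len = 12L, pos = 40L)
  expect_error(validate_record(beyond, tg), "beyond target length")
  unknown <- toy_fragment("h", 5L, read_len = 10L)
  expect_error(validate_record(unknown, tg), "unknown target id")
})

test_that("FASTA conversion assigns header-order ids and normalizes case", {
  fa <- withr::local_tempfile(lines = c(">b", "acgtacgta", ">a", "ACGT", "ACGT"))
  tg <- fasta_to_target_records(fa, header_order = c("a", "b"))
  expect_identical(vapply(tg, `[[`, character(1), "name"), c("a", "b"))
  expect_identical(vapply(tg, `[[`, integer(1), "id"), 0:1)
  expect_identical(vapply(tg, `[[`, integer(1), "length"), c(8L, 9L))
  expect_identical(unpack_nucleotides(tg[[2]]$seq, 9), "ACGTACGTA")
  expect_error(fasta_to_target_records(fa, header_order = c("a", "zz")), "missing")
  dup <- withr::local_tempfile(lines = c(">a", "ACGT", ">a", "GGGG"))
  expect_error(fasta_to_target_records(dup), "duplicate")
})

test_that("SAM conversion recovers mismatches, pairs mates and enforces grouping", {
  tg <- list(target_record("tA", 0L, seq = "ACGTACGTACGTACGTACGT"),
             target_record("tB", 1L, seq = "ACGTACGTACGTACGTACGT"))
  sam <- withr::local_tempfile(lines = c(
    "@HD\tVN:1.6",
    "@SQ\tSN:tA\tLN:20", "@SQ\tSN:tB\tLN:20",
    "f1\t0\ttA\t1\t255\t4M\t*\t0\t0\tAGGT\t*",
    "f1\t256\ttB\t5\t255\t4M\t*\t0\t0\tAGGT\t*",
    "f2\t67\ttA\t1\t255\t5M\t=\t10\t14\tACGTA\t*",
    "f2\t131\ttA\t10\t255\t5M\t=\t1\t-14\tTACGT\t*"))
  fr <- sam_to_fragment_records(sam, tg)
  expect_length(fr, 2L)
  expect_false(fr[[1]]$paired)
  expect_length(fr[[1]]$alignments, 2L)
  r <- fr[[1]]$alignments[[1]]$read_l
  expect_identical(r$left_pos, 0L)
  expect_identical(r$mismatch_indices, 1L)
  expect_identical(unpack_nucleotides(r$mismatch_nucs, 1), "G")
  expect_true(fr[[2]]$paired)
  a <- fr[[2]]$alignments[[1]]
  expect_identical(a$read_l$left_pos, 0L)
  expect_identical(a$read_r$left_pos, 9L)
  expect_true(a$read_l$first)

  ungrouped <- withr::local_tempfile(lines = c(
    "@HD\tVN:1.6", "@SQ\tSN:tA\tLN:20",
    "f1\t0\ttA\t1\t255\t4M\t*\t0\t0\tACGT\t*",
    "f2\t0\ttA\t1\t255\t4M\t*\t0\t0\tACGT\t*",
    "f1\t256\ttA\t5\t255\t4M\t*\t0\t0\tACGT\t*"))
  expect_error(sam_to_fragment_records(ungrouped, tg), "grouped")

  indel <- withr::local_tempfile(lines = c(
    "@HD\tVN:1.6", "@SQ\tSN:tA\tLN:20",
    "f1\t0\ttA\t1\t255\t2M1I2M\t*\t0\t0\tACGTA\t*",
    "f1\t256\ttA\t1\t255\t4M\t*\t0\t0\tACGT\t*"))
  expect_warning(fr2 <- sam_to_fragment_records(indel, tg), "indel")
  expect_length(fr2[[1]]$alignments, 1L)

  badref <- withr::local_tempfile(lines = c(
    "@HD\tVN:1.6", "@SQ\tSN:tZ\tLN:20",
    "f1\t0\ttZ\t1\t255\t4M\t*\t0\t0\tACGT\t*"))
  expect_error(sam_to_fragment_records(badref, tg), "absent")
})

test_that("simulator records survive the SAM round trip", {
  sm <- small_sim(seed = 31, n_fragments = 400L)
  dir <- withr::local_tempdir()
  simulate_experiment(sm$targets, sm$cfg, out_dir = dir)
  back <- sam_to_fragment_records(file.path(dir, "fragments.sam"), sm$targets)
  orig <- read_record_file(file.path(dir, "fragments.pb64"), "fragment")
  expect_identical(back, orig)
})
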
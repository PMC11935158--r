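test_that("modulation is cyclic keystream addition and demodulation inverts it", {
  expect_identical(modulate("ACGT", "AAAA"), "ACGT")  # A = 0 keystream
  expect_identical(modulate("AAAA", "ACGT"), "ACGT")  # 0+0,0+1,0+2,0+3
  expect_error(modulate("ACGN", "ACGT"), "outside")
  withr::with_seed(5, {
    for (i in 1:200) {
      s <- paste(sample(c("A", "C", "G", "T"), sample(1:40, 1), TRUE),
                 collapse = "")
      p <- paste(sample(c("A", "C", "G", "T"), 4, TRUE), collapse = "")
      expect_identical(demodulate(modulate(s, p), p), s)
    }
  })
})

test_that("modulating twice composes as keystream addition (group action)", {
  withr::with_seed(6, {
    for (i in 1:50) {
      s <- paste(sample(c("A", "C", "G", "T"), 24, TRUE), collapse = "")
      p <- paste(sample(c("A", "C", "G", "T"), 4, TRUE), collapse = "")
      q <- paste(sample(c("A", "C", "G", "T"), 4, TRUE), collapse = "")
      pq <- modulate(p, q)  # position-wise sum of the two keystreams
      expect_identical(modulate(modulate(s, p), q), modulate(s, pq))
    }
  })
})

test_that("build_core emits constraint-compliant 124-nt cores deterministically", {
  lay <- sequence_layout()
  chunk <- fixture_bytes(25, seed = 11)
  r1 <- withr::with_seed(1, build_core(chunk, 7L, lay))
  r2 <- withr::with_seed(1, build_core(chunk, 7L, lay))
  expect_identical(r1$core, r2$core)
  expect_gte(nchar(r1$core), 124L)
  expect_identical(nchar(r1$core) %% 4L, 0L)
  expect_true(passes_constraints(r1$core))
  expect_identical(r1$index, 7L)
  # an all-zero payload would be a >3 homopolymer under the identity
  # keystream, so a non-identity modulation primer must be chosen
  rz <- withr::with_seed(1, build_core(raw(25), 0L, lay))
  expect_false(rz$mod_primer_a == "AAAA")
  expect_true(passes_constraints(rz$core))
})

test_that("assembled strands carry primers and a verifying outer RS region", {
  lay <- sequence_layout()
  pp <- fixture_primer_pair()
  rec <- withr::with_seed(2, build_core(fixture_bytes(25), 3L, lay))
  rec <- assemble_strand(rec, pp, lay)
  expect_identical(nchar(rec$full), nchar(rec$core) + 48L)
  expect_identical(substr(rec$full, 1, 20), pp$forward)
  expect_identical(substr(rec$full, nchar(rec$full) - 19, nchar(rec$full)),
                   revcomp(pp$reverse))
  interior <- substr(rec$full, 21, nchar(rec$full) - 20)
  expect_true(rs_decode(as.integer(bases_to_bytes(interior)), 2L)$ok)
  d <- decode_strand(rec$full, pp, lay)
  expect_true(d$ok)
  expect_identical(d$index, 3L)
})

test_that("any single substituted core base is still decoded (RS sweep)", {
  lay <- sequence_layout()
  pp <- fixture_primer_pair()
  rec <- assemble_strand(withr::with_seed(3, build_core(fixture_bytes(25), 5L, lay)),
                         pp, lay)
  chunk <- decode_strand(rec$full, pp, lay)$chunk
  n <- nchar(rec$full)
  good <- 0L; total <- 0L
  for (pos in 21:(n - 20)) {
    ch <- substr(rec$full, pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), ch)) {
      bad <- paste0(substr(rec$full, 1, pos - 1), alt,
                    substr(rec$full, pos + 1, n))
      d <- decode_strand(bad, pp, lay)
      total <- total + 1L
      good <- good + (isTRUE(d$ok) && d$index == 5L &&
                        identical(d$chunk, chunk))
    }
  }
  expect_identical(good, total)
  expect_identical(total, 3L * (n - 40L))
})

test_that("decode_strand returns failures as values on malformed input", {
  lay <- sequence_layout()
  pp <- fixture_primer_pair()
  rec <- assemble_strand(withr::with_seed(4, build_core(fixture_bytes(25), 0L, lay)),
                         pp, lay)
  expect_false(decode_strand(substr(rec$full, 1, 100), pp, lay)$ok)
  other <- withr::with_seed(77, random_primer_pair(lay, avoid = c(pp$forward, pp$reverse)))
  d <- decode_strand(rec$full, other, lay)
  expect_false(d$ok)
  expect_match(d$reason, "primer")
})

test_that("encode_file chunks with a length prefix and decode_file inverts", {
  lay <- sequence_layout()
  pp <- fixture_primer_pair()
  # 1,999 bytes -> ceil((1999 + 2) / 25) = 81 strands
  strands <- encode_file(fixture_demo_bytes(), 1L, pp, lay, seed = 11)
  expect_length(strands, 81L)
  expect_identical(vapply(strands, function(r) r$index, integer(1)), 0:80)
  expect_true(all(vapply(strands, function(r) passes_constraints(r$core),
                         logical(1))))
  lens <- vapply(strands, function(r) nchar(r$core), integer(1))
  expect_true(all(lens %in% seq(124L, 140L, by = 4L)))
  expect_identical(decode_file(strands, pp, lay), fixture_demo_bytes())
  # empty file: one strand carrying length 0
  empty <- encode_file(raw(0), 0L, pp, lay, seed = 1)
  expect_length(empty, 1L)
  expect_identical(decode_file(empty, pp, lay), raw(0))
  expect_error(encode_file(raw(6399), 0L, pp, lay), "index space")
})

test_that("encode/decode round trips arbitrary payload sizes", {
  lay <- sequence_layout()
  pp <- fixture_primer_pair()
  withr::with_seed(8, {
    for (i in 1:10) {
      data <- as.raw(sample(0:255, sample(0:1200, 1), replace = TRUE))
      strands <- encode_file(data, i, pp, lay, seed = i)
      expect_identical(decode_file(strands, pp, lay), data)
    }
  })
})

test_that("encoding is deterministic under a fixed seed", {
  lay <- sequence_layout()
  pp <- fixture_primer_pair()
  data <- fixture_bytes(300, seed = 9)
  f1 <- vapply(encode_file(data, 1L, pp, lay, seed = 5),
               function(r) r$full, character(1))
  f2 <- vapply(encode_file(data, 1L, pp, lay, seed = 5),
               function(r) r$full, character(1))
  expect_identical(f1, f2)
})

test_that("sequence_error_rate pairs by assignment and penalizes misses", {
  expect_equal(sequence_error_rate(c("ACGT", "TTTT"), c("ACGT", "TTTT")), 0)
  expect_equal(sequence_error_rate(c("ACGT", "TTTT"), c("ACGA", "TTTT")),
               1 / 8)
  # one original of length 10 out of 20 nt missing: at least half wrong
  expect_gte(sequence_error_rate(c("ACGTACGTAC", "TGCATGCATG"),
                                 c("ACGTACGTAC")), 0.5)
  expect_equal(sequence_error_rate("ACGT", character(0)), 1.0)
  # index-based pairing when identities are known
  expect_equal(sequence_error_rate(c("AAAA", "CCCC"), c("CCCC", "AAAA"),
                                   original_indices = c(1, 2),
                                   recovered_indices = c(2, 1)), 0)
})
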
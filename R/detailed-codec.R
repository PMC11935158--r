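# Detailed-data codec: byte payloads -> constraint-compliant DNA strands.
#
# Core geometry (offsets within the core, defaults in nt):
#   [ mod primer A | M_A(index || payload) | M_B(inner RS parity) | mod primer B | seed ]
#          4                 4 + 100                  8                   4         >= 4
# The inner RS codeword protects (index, payload, primer A id, primer B id)
# with 2 parity bytes. The full strand wraps the core in 20-nt PCR primers
# and appends 2 outer RS parity bytes (8 nt) over the core's bytes:
#   [ fwd primer | core | outer RS | revcomp(rev primer) ]

#' Modulate a sequence with a cyclic keystream primer
#'
#' Modulation maps a sequence onto an alternative sequence by position-wise
#' addition modulo 4 of the primer's bases, repeated cyclically (a Vigenere
#' cipher over the 4-letter alphabet). Screening many modulation primers lets
#' the encoder find a representation that satisfies the GC-content and
#' homopolymer constraints without changing length.
#'
#' @param seq Nucleotide string.
#' @param primer Modulation primer (4 nt under the default layout).
#' @return The modulated sequence, same length as `seq`.
#' @examples
#' modulate("AAAA", "ACGT")  # "ACGT"
#' demodulate(modulate("GATTACA", "CGTA"), "CGTA")  # "GATTACA"
#' @export
modulate <- function(seq, primer) {
  if (nchar(seq) == 0L) return("")
  s <- seq_to_ints(seq)
  p <- seq_to_ints(primer)
  ints_to_seq((s + rep_len(p, length(s))) %% 4L)
}

#' @rdname modulate
#' @export
demodulate <- function(seq, primer) {
  if (nchar(seq) == 0L) return("")
  s <- seq_to_ints(seq)
  p <- seq_to_ints(primer)
  ints_to_seq((s - rep_len(p, length(s))) %% 4L)
}

#' Pool of admissible 4-nt modulation primers
#'
#' All 256 4-nt words, in byte order, filtered by [passes_constraints()]
#' under the layout's thresholds. The deterministic ordering makes the
#' encoder's first-success search reproducible.
#'
#' @param layout A [sequence_layout()].
#' @return Character vector of 4-nt words.
#' @export
mod_primer_pool <- function(layout = sequence_layout()) {
  words <- vapply(0:255, function(b) bytes_to_bases(as.raw(b)), character(1))
  keep <- vapply(words, passes_constraints, logical(1),
                 gc_min = layout$gc_min, gc_max = layout$gc_max,
                 max_homopolymer = layout$max_homopolymer)
  unname(words[keep])
}

core_offsets <- function(layout) {
  body_len <- layout$index_len + layout$payload_len
  a_end <- layout$mod_primer_len
  body_end <- a_end + body_len
  rs_end <- body_end + layout$rs_inner_len
  b_end <- rs_end + layout$mod_primer_len
  list(a = c(1L, a_end), body = c(a_end + 1L, body_end),
       rs = c(body_end + 1L, rs_end), b = c(rs_end + 1L, b_end),
       seed_start = b_end + 1L)
}

chunk_bytes <- function(layout) layout$payload_len %/% 4L

core_ints_pass <- function(ints, layout) {
  gc <- mean(ints == 1L | ints == 2L)
  if (gc < layout$gc_min || gc > layout$gc_max) return(FALSE)
  max(rle(ints)$lengths) <= layout$max_homopolymer
}

#' Build the core region of one strand
#'
#' Searches modulation primers (and, when needed, longer seeds) until the
#' assembled core satisfies the composition constraints. Primer pairs are
#' tried in pool order and the seed is redrawn/extended in `seed_step`
#' increments up to `seed_max_len`; the first success wins, so the result is
#' deterministic given the pool order and the RNG state.
#'
#' @param chunk Raw vector of exactly `payload_len/4` bytes (25 by default).
#' @param index Strand index within the file, 0..255.
#' @param layout A [sequence_layout()].
#' @param primer_pool Ordered candidate modulation primers.
#' @return A `strand_record` list with `index`, `mod_primer_a`,
#'   `mod_primer_b`, `seed` and `core` populated.
#' @export
build_core <- function(chunk, index, layout = sequence_layout(),
                       primer_pool = mod_primer_pool(layout)) {
  stopifnot(length(chunk) == chunk_bytes(layout), index >= 0L, index <= 255L,
            length(primer_pool) > 0L)
  body_bytes <- c(as.integer(index), as.integer(as.raw(chunk)))
  body_ints <- seq_to_ints(bytes_to_bases(body_bytes))
  pool_ints <- lapply(primer_pool, seq_to_ints)
  pool_bytes <- vapply(primer_pool, function(w) as.integer(bases_to_bytes(w)), integer(1))
  # RS is linear over GF(256): parity(body || idA || idB) splits into the
  # XOR of parity(body || 0 || 0) and per-id parities, precomputed once.
  par_body <- tail(rs_encode(c(body_bytes, 0L, 0L), 2L), 2L)
  par_a <- lapply(pool_bytes, function(v) tail(rs_encode(c(v, 0L), 2L), 2L))
  par_b <- lapply(pool_bytes, function(v) tail(rs_encode(v, 2L), 2L))
  seed_lens <- rep(seq(layout$seed_min_len, layout$seed_max_len,
                       by = layout$seed_step), each = 2L)
  for (seed_len in seed_lens) {
    seed_words <- sample(primer_pool, seed_len %/% layout$seed_step, replace = TRUE)
    seed_ints <- unlist(lapply(seed_words, seq_to_ints))
    for (ai in seq_along(pool_ints)) {
      a <- pool_ints[[ai]]
      body_mod <- (body_ints + rep_len(a, length(body_ints))) %% 4L
      if (max(rle(body_mod)$lengths) > layout$max_homopolymer) next
      for (bi in seq_along(pool_ints)) {
        b <- pool_ints[[bi]]
        parity <- bitwXor(bitwXor(par_body, par_a[[ai]]), par_b[[bi]])
        rs_ints <- (seq_to_ints(bytes_to_bases(parity)) +
                      rep_len(b, layout$rs_inner_len)) %% 4L
        core_ints <- c(a, body_mod, rs_ints, b, seed_ints)
        if (core_ints_pass(core_ints, layout)) {
          rec <- list(file_id = NA_integer_, index = as.integer(index),
                      mod_primer_a = primer_pool[ai], mod_primer_b = primer_pool[bi],
                      seed = ints_to_seq(seed_ints), core = ints_to_seq(core_ints),
                      full = NA_character_)
          class(rec) <- "strand_record"
          return(rec)
        }
      }
    }
  }
  stop(sprintf("constraint-unsatisfiable chunk (index %d): exhausted %d primer pairs and seeds up to %d nt",
               index, length(primer_pool)^2, layout$seed_max_len), call. = FALSE)
}

#' Append PCR primers and the outer Reed-Solomon region
#'
#' `full = forward || core || outer-RS || revcomp(reverse)`; the outer RS
#' parity (2 bytes = 8 nt) is computed over the core's bytes, so a full
#' strand is 48 nt longer than its core (172 nt for a minimal 124-nt core).
#'
#' @param record A `strand_record` from [build_core()].
#' @param primer_pair A [primer_pair()].
#' @param layout A [sequence_layout()].
#' @return The record with `full` populated.
#' @export
assemble_strand <- function(record, primer_pair, layout = sequence_layout()) {
  core_bytes <- as.integer(bases_to_bytes(record$core))
  parity <- tail(rs_encode(core_bytes, 2L), 2L)
  record$full <- paste0(primer_pair$forward, record$core,
                        bytes_to_bases(parity), revcomp(primer_pair$reverse))
  record
}

#' PCR primer pair
#'
#' @param forward,reverse 20-nt constraint-compliant sequences with mutual
#'   edit distance of at least 8 (cross-talk guard).
#' @return An object of class `primer_pair`.
#' @export
primer_pair <- function(forward, reverse) {
  stopifnot(nchar(forward) == 20L, nchar(reverse) == 20L, forward != reverse)
  check_alphabet(forward); check_alphabet(reverse)
  if (edit_distance(forward, reverse) < 8L)
    stop("primer pair too similar: edit distance < 8", call. = FALSE)
  structure(list(forward = forward, reverse = reverse), class = "primer_pair")
}

#' Draw a constraint-compliant primer pair
#'
#' Rejection-samples 20-nt primers until both satisfy the composition
#' constraints and sit at edit distance >= `min_dist` from each other and
#' from every primer in `avoid` (orthogonality across library units).
#'
#' @param layout A [sequence_layout()].
#' @param avoid Character vector of primers already in use.
#' @param min_dist Minimum pairwise edit distance.
#' @return A [primer_pair()].
#' @export
random_primer_pair <- function(layout = sequence_layout(), avoid = character(0),
                               min_dist = 8L) {
  draw_one <- function(taken) {
    repeat {
      cand <- ints_to_seq(sample(0:3, layout$pcr_primer_len, replace = TRUE))
      if (!passes_constraints(cand, layout$gc_min, layout$gc_max,
                              layout$max_homopolymer)) next
      if (length(taken) && any(edit_distance_matrix(cand, taken) < min_dist)) next
      return(cand)
    }
  }
  fwd <- draw_one(avoid)
  rev <- draw_one(c(avoid, fwd))
  primer_pair(fwd, rev)
}

#' Levenshtein edit distance
#' @param a,b Strings.
#' @return Integer edit distance.
#' @export
edit_distance <- function(a, b) cpp_edit_distance(a, b)

#' Pairwise edit-distance matrix
#' @param a,b Character vectors.
#' @return `length(a)` x `length(b)` integer matrix.
#' @export
edit_distance_matrix <- function(a, b) cpp_edit_distance_matrix(a, b)

#' Encode a byte payload into DNA strands
#'
#' The payload is prefixed with its 2-byte little-endian length, chunked into
#' `payload_len/4`-byte blocks (the last block zero-padded), and each block
#' becomes one strand with consecutive indices from 0. [decode_file()]
#' inverts the encoding exactly.
#'
#' @param data Raw vector; at most `256 * payload_len/4 - 2` bytes (the 4-nt
#'   index addresses 256 strands).
#' @param file_id Small integer identifier stored on each record.
#' @param primer_pair The file's [primer_pair()].
#' @param layout A [sequence_layout()].
#' @param seed Integer seed making the constraint search reproducible.
#' @return List of `strand_record`s with `full` populated.
#' @export
encode_file <- function(data, file_id = 0L, primer_pair, layout = sequence_layout(),
                        seed = NULL) {
  data <- as.raw(data)
  bs <- chunk_bytes(layout)
  if (length(data) > 256L * bs - 2L)
    stop(sprintf("payload of %d bytes exceeds the %d-byte index space",
                 length(data), 256L * bs - 2L), call. = FALSE)
  n <- length(data)
  prefixed <- c(as.raw(n %% 256L), as.raw(n %/% 256L), data)
  n_strands <- ceiling(length(prefixed) / bs)
  padded <- c(prefixed, raw(n_strands * bs - length(prefixed)))
  pool <- mod_primer_pool(layout)
  run <- function() {
    lapply(seq_len(n_strands), function(i) {
      chunk <- padded[((i - 1L) * bs + 1L):(i * bs)]
      rec <- build_core(chunk, i - 1L, layout, pool)
      rec$file_id <- as.integer(file_id)
      assemble_strand(rec, primer_pair, layout)
    })
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Shared interior decoder: takes core||outer-RS (primers already stripped,
# canonical orientation) and returns list(ok, index, chunk, corrected, reason).
decode_core <- function(interior, layout = sequence_layout()) {
  fail <- function(reason) list(ok = FALSE, index = NA_integer_, chunk = NULL,
                                reason = reason)
  len <- nchar(interior)
  core_len <- len - layout$rs_outer_len
  if (len %% 4L != 0L || core_len < layout$min_core_len ||
      core_len > layout$min_core_len + (layout$seed_max_len - layout$seed_min_len))
    return(fail("length outside core window"))
  if (grepl("[^ACGT]", interior)) return(fail("invalid alphabet"))
  outer <- rs_decode(as.integer(bases_to_bytes(interior)), 2L)
  if (!outer$ok) return(fail("outer RS failure"))
  core <- bytes_to_bases(as.raw(outer$message))
  off <- core_offsets(layout)
  primer_a <- substr(core, off$a[1], off$a[2])
  primer_b <- substr(core, off$b[1], off$b[2])
  body <- demodulate(substr(core, off$body[1], off$body[2]), primer_a)
  parity <- demodulate(substr(core, off$rs[1], off$rs[2]), primer_b)
  inner_cw <- as.integer(c(bases_to_bytes(body),
                           bases_to_bytes(primer_a), bases_to_bytes(primer_b),
                           bases_to_bytes(parity)))
  inner <- rs_decode(inner_cw, 2L)
  if (!inner$ok) return(fail("inner RS failure"))
  nb <- length(inner$message)
  id_a <- inner$message[nb - 1L]
  id_b <- inner$message[nb]
  if (id_a != as.integer(bases_to_bytes(primer_a)) ||
      id_b != as.integer(bases_to_bytes(primer_b))) {
    # a corrected primer id: re-demodulate with the corrected keystreams
    primer_a <- bytes_to_bases(as.raw(id_a))
    primer_b <- bytes_to_bases(as.raw(id_b))
    body <- demodulate(substr(core, off$body[1], off$body[2]), primer_a)
    parity <- demodulate(substr(core, off$rs[1], off$rs[2]), primer_b)
    inner <- rs_decode(as.integer(c(bases_to_bytes(body), id_a, id_b,
                                    bases_to_bytes(parity))), 2L)
    if (!inner$ok) return(fail("inner RS failure after primer correction"))
  }
  msg <- inner$message
  list(ok = TRUE, index = msg[1], chunk = as.raw(msg[2:(nb - 2L)]),
       corrected = outer$n_corrected + inner$n_corrected, reason = NULL)
}

#' Decode one full strand
#'
#' Verifies and strips the exact PCR primers (fuzzy primer matching for noisy
#' reads lives in [filter_and_trim()]), applies the outer then inner RS
#' layers, demodulates, and returns the strand's index and payload chunk.
#' Failures are returned as values, never raised.
#'
#' @param seq Full strand sequence.
#' @param primer_pair The file's [primer_pair()].
#' @param layout A [sequence_layout()].
#' @return List with `ok`, `index`, `chunk` (raw), and `reason` on failure.
#' @export
decode_strand <- function(seq, primer_pair, layout = sequence_layout()) {
  fail <- function(reason) list(ok = FALSE, index = NA_integer_, chunk = NULL,
                                reason = reason)
  p <- layout$pcr_primer_len
  lo <- layout$min_core_len + layout$rs_outer_len + 2L * p
  hi <- lo + (layout$seed_max_len - layout$seed_min_len)
  if (is.na(seq) || nchar(seq) < lo || nchar(seq) > hi)
    return(fail("length outside strand window"))
  if (substr(seq, 1L, p) != primer_pair$forward)
    return(fail("forward primer mismatch"))
  if (substr(seq, nchar(seq) - p + 1L, nchar(seq)) != revcomp(primer_pair$reverse))
    return(fail("reverse primer mismatch"))
  decode_core(substr(seq, p + 1L, nchar(seq) - p), layout)
}

#' Decode a file from its strands
#'
#' @param strands List of `strand_record`s (or full-strand character vector).
#' @param primer_pair The file's [primer_pair()].
#' @param layout A [sequence_layout()].
#' @return The original raw payload.
#' @export
decode_file <- function(strands, primer_pair, layout = sequence_layout()) {
  seqs <- if (is.character(strands)) strands
          else vapply(strands, function(r) r$full, character(1))
  decoded <- lapply(seqs, decode_strand, primer_pair = primer_pair, layout = layout)
  ok <- vapply(decoded, function(d) isTRUE(d$ok), logical(1))
  if (!any(ok)) stop("no strand decoded", call. = FALSE)
  assemble_chunks(decoded[ok], layout)
}

# Order decoded (index, chunk) records, strip the length prefix, return bytes.
assemble_chunks <- function(decoded, layout = sequence_layout()) {
  idx <- vapply(decoded, function(d) d$index, integer(1))
  keep <- !duplicated(idx)
  decoded <- decoded[keep]
  idx <- idx[keep]
  n_strands <- max(idx) + 1L
  bs <- chunk_bytes(layout)
  if (length(idx) < n_strands)
    warning(sprintf("missing strand indices: %s",
                    paste(setdiff(0:(n_strands - 1L), idx), collapse = ",")),
            call. = FALSE)
  buf <- raw(n_strands * bs)
  for (i in seq_along(decoded))
    buf[(idx[i] * bs + 1L):((idx[i] + 1L) * bs)] <- decoded[[i]]$chunk
  n <- as.integer(buf[1]) + 256L * as.integer(buf[2])
  if (n > length(buf) - 2L)
    stop("corrupt length prefix exceeds decoded payload", call. = FALSE)
  buf[seq_len(n) + 2L]
}

#' Sequence-level error rate between originals and recovered sequences
#'
#' Pairs recovered sequences with originals (by decoded index when supplied,
#' otherwise by minimum-cost one-to-one assignment on Levenshtein distance;
#' originals left unmatched count their full length) and reports total edit
#' distance divided by total original length.
#'
#' @param originals,recovered Character vectors of sequences.
#' @param original_indices,recovered_indices Optional integer identifiers;
#'   when both are given, pairing is by identity of the index.
#' @return Fraction in \[0, 1+\].
#' @examples
#' sequence_error_rate(c("ACGT", "TTTT"), c("ACGA", "TTTT"))  # 0.125
#' @export
sequence_error_rate <- function(originals, recovered,
                                original_indices = NULL, recovered_indices = NULL) {
  stopifnot(length(originals) > 0L)
  total_len <- sum(nchar(originals))
  if (length(recovered) == 0L) return(1.0)
  if (!is.null(original_indices) && !is.null(recovered_indices)) {
    m <- match(original_indices, recovered_indices)
    d <- ifelse(is.na(m), nchar(originals),
                mapply(function(o, r) if (is.na(r)) NA_integer_
                       else edit_distance(o, recovered[r]),
                       originals, m))
    return(sum(d) / total_len)
  }
  dmat <- edit_distance_matrix(originals, recovered)
  # dummy columns let any original stay unmatched at its full length
  cost <- cbind(dmat, matrix(nchar(originals), nrow = length(originals),
                             ncol = length(originals)))
  match_col <- cpp_hungarian(cost)
  total <- sum(cost[cbind(seq_along(originals), match_col)])
  total / total_len
}
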
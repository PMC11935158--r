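# Shared fixtures, all generated in code.

fixture_layout <- function() sequence_layout()

# A fixed constraint-compliant primer pair used across tests.
fixture_primer_pair <- function() {
  withr::with_seed(42, random_primer_pair(sequence_layout()))
}

fixture_bytes <- function(n, seed = 7) {
  withr::with_seed(seed, as.raw(sample(0:255, n, replace = TRUE)))
}

# The 1,999-byte demonstration payload: 404 bytes of text + 1,595 bytes of
# binary image data.
fixture_demo_bytes <- function(seed = 1) {
  p <- demo_payloads(seed)
  c(p$name, p$motto, p$anthem, p$ethos, p$seal)
}

# Brute-force greedy sphere clustering oracle (utils::adist Levenshtein),
# independent of the package's clustering path.
oracle_greedy_cluster <- function(reads, radius) {
  tab <- table(reads)
  uniq <- names(tab)
  mult <- as.integer(tab)
  ord <- order(-mult, uniq, method = "radix")
  uniq <- uniq[ord]; mult <- mult[ord]
  alive <- rep(TRUE, length(uniq))
  out <- list()
  while (any(alive)) {
    ci <- which(alive)[1]
    d <- as.integer(utils::adist(uniq[ci], uniq[alive]))
    members <- which(alive)[d <= radius]
    out[[length(out) + 1L]] <- list(centroid = uniq[ci],
                                    abundance = sum(mult[members]))
    alive[members] <- FALSE
  }
  ab <- vapply(out, function(x) x$abundance, numeric(1))
  ce <- vapply(out, function(x) x$centroid, character(1))
  out[order(-ab, ce, method = "radix")]
}

# Brute-force semi-global oracle: best edit distance of pattern against any
# substring of text, via utils::adist.
oracle_best_infix_edits <- function(pattern, text) {
  n <- nchar(text)
  best <- nchar(pattern)
  for (i in seq_len(n)) {
    for (j in (i - 1):n) {  # j = i-1 encodes the empty substring
      sub <- if (j < i) "" else substr(text, i, j)
      best <- min(best, as.integer(utils::adist(pattern, sub)))
    }
  }
  best
}

# Brute-force RS decode oracle for 2 parity bytes: try every single-byte
# correction (position x magnitude) and accept the first whose syndromes
# vanish. Uses its own GF(256) tables, independent of the package's
# Berlekamp-Massey decoder.
oracle_rs_decode1 <- function(codeword) {
  exp_t <- integer(510); log_t <- integer(256); x <- 1L
  for (i in 0:254) {
    exp_t[i + 1L] <- x; log_t[x + 1L] <- i
    x <- bitwShiftL(x, 1L)
    if (bitwAnd(x, 256L) != 0L) x <- bitwXor(x, 285L)
  }
  exp_t[256:510] <- exp_t[1:255]
  mul <- function(a, b) {
    out <- integer(max(length(a), length(b)))
    a <- rep_len(a, length(out)); b <- rep_len(b, length(out))
    nz <- a != 0L & b != 0L
    out[nz] <- exp_t[((log_t[a[nz] + 1L] + log_t[b[nz] + 1L]) %% 255L) + 1L]
    out
  }
  synd <- function(cw) {
    s0 <- 0L; s1 <- 0L
    for (b in cw) {
      s0 <- bitwXor(s0, b)
      s1 <- bitwXor(mul(s1, 2L), b)
    }
    c(s0, s1)
  }
  s <- synd(codeword)
  if (all(s == 0L)) return(list(ok = TRUE, cw = codeword))
  n <- length(codeword)
  v <- 1:255
  for (p in seq_len(n)) {
    # adding v at position p shifts the syndromes by (v, v * alpha^(n-p))
    hit <- which(bitwXor(s[1], v) == 0L &
                   bitwXor(s[2], mul(v, exp_t[((n - p) %% 255L) + 1L])) == 0L)
    if (length(hit)) {
      cand <- codeword
      cand[p] <- bitwXor(cand[p], v[hit[1]])
      return(list(ok = TRUE, cw = as.integer(cand)))
    }
  }
  list(ok = FALSE, cw = NULL)
}
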
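DNA_BASES <- c("A", "C", "G", "T")

#' Strand layout for the detailed-data DNA codec
#'
#' Collects every structural constant of the archival strand design in one
#' object: region lengths (modulation primers, index, payload, inner
#' Reed-Solomon redundancy, seed, PCR primers, outer Reed-Solomon parity) and
#' the composition constraints (GC-content window, homopolymer limit) that
#' every emitted core must satisfy.
#'
#' The default layout reproduces the reference strand geometry: a minimum
#' core of 124 nt made of two 4-nt modulation primers, a 4-nt index, a 100-nt
#' payload (25 bytes, comfortably above the 60 nt of information per strand
#' the design guarantees), 8 nt of inner RS redundancy and a seed of at least
#' 4 nt; 20-nt PCR primers and an 8-nt outer RS region are appended around
#' the core, so the shortest full strand is 172 nt.
#'
#' @param payload_len Payload region length in nt (multiple of 4).
#' @param gc_min,gc_max GC-content window applied to every core.
#' @param max_homopolymer Longest tolerated single-base run.
#' @param seed_max_len Maximum seed length in nt (multiple of `seed_step`).
#' @return An object of class `sequence_layout` (a named list).
#' @examples
#' layout <- sequence_layout()
#' layout$min_core_len  # 124
#' @export
sequence_layout <- function(payload_len = 100L, gc_min = 0.40, gc_max = 0.60,
                            max_homopolymer = 3L, seed_max_len = 16L) {
  layout <- list(
    mod_primer_len = 4L,
    index_len = 4L,
    payload_len = as.integer(payload_len),
    rs_inner_len = 8L,
    seed_min_len = 4L,
    seed_step = 4L,
    seed_max_len = as.integer(seed_max_len),
    pcr_primer_len = 20L,
    rs_outer_len = 8L,
    gc_min = gc_min,
    gc_max = gc_max,
    max_homopolymer = as.integer(max_homopolymer),
    base_map = stats::setNames(0:3, DNA_BASES)
  )
  layout$min_core_len <- with(layout, 2L * mod_primer_len + index_len +
                                payload_len + rs_inner_len + seed_min_len)
  class(layout) <- "sequence_layout"
  validate_layout(layout)
  layout
}

validate_layout <- function(layout) {
  stopifnot(
    layout$payload_len >= 60L,
    layout$payload_len %% 4L == 0L,
    layout$min_core_len %% 4L == 0L,
    layout$seed_step %% 4L == 0L,
    layout$seed_max_len >= layout$seed_min_len,
    layout$gc_min > 0, layout$gc_max < 1, layout$gc_min < layout$gc_max,
    layout$max_homopolymer >= 1L,
    all(vapply(layout[grep("_len$", names(layout))], function(x) x > 0, TRUE))
  )
  invisible(layout)
}

#' @export
print.sequence_layout <- function(x, ...) {
  cat("<sequence_layout>\n")
  cat(sprintf("  core: %d nt min = 2x%d (mod primers) + %d (index) + %d (payload) + %d (inner RS) + %d (seed min)\n",
              x$min_core_len, x$mod_primer_len, x$index_len, x$payload_len,
              x$rs_inner_len, x$seed_min_len))
  cat(sprintf("  appended: 2x%d nt PCR primers + %d nt outer RS\n",
              x$pcr_primer_len, x$rs_outer_len))
  cat(sprintf("  constraints: GC in [%.2f, %.2f], homopolymer <= %d\n",
              x$gc_min, x$gc_max, x$max_homopolymer))
  invisible(x)
}

check_alphabet <- function(seq) {
  if (any(!strsplit(seq, "", fixed = TRUE)[[1]] %in% DNA_BASES))
    stop("sequence contains characters outside {A,C,G,T}", call. = FALSE)
  invisible(seq)
}

seq_to_ints <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  ints <- match(chars, DNA_BASES) - 1L
  if (anyNA(ints)) stop("sequence contains characters outside {A,C,G,T}", call. = FALSE)
  ints
}

ints_to_seq <- function(ints) paste(DNA_BASES[ints + 1L], collapse = "")

#' Map bytes to nucleotides at 2 bits per base
#'
#' Each byte becomes four bases, most-significant bit pair first, under the
#' bijection A=00, C=01, G=10, T=11 (the default `base_map` of
#' [sequence_layout()]).
#'
#' @param data A raw vector (or integers in 0..255).
#' @return A nucleotide string of length `4 * length(data)`.
#' @examples
#' bytes_to_bases(as.raw(0x1B))  # "ACGT"
#' @seealso [bases_to_bytes()]
#' @export
bytes_to_bases <- function(data) {
  data <- as.integer(as.raw(data))
  if (length(data) == 0L) return("")
  quads <- rbind(
    data %/% 64L,
    (data %/% 16L) %% 4L,
    (data %/% 4L) %% 4L,
    data %% 4L
  )
  ints_to_seq(as.integer(quads))
}

#' Map nucleotides back to bytes
#'
#' Exact inverse of [bytes_to_bases()]; the sequence length must be a
#' multiple of 4.
#'
#' @param seq A nucleotide string over {A,C,G,T}.
#' @return A raw vector of length `nchar(seq) / 4`.
#' @export
bases_to_bytes <- function(seq) {
  if (nchar(seq) == 0L) return(raw(0))
  if (nchar(seq) %% 4L != 0L)
    stop("sequence length must be a multiple of 4 to form whole bytes", call. = FALSE)
  ints <- seq_to_ints(seq)
  quads <- matrix(ints, nrow = 4L)
  as.raw(quads[1, ] * 64L + quads[2, ] * 16L + quads[3, ] * 4L + quads[4, ])
}

#' GC fraction of a sequence
#' @param seq Nucleotide string.
#' @return Fraction of G and C bases.
#' @export
gc_fraction <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  mean(chars %in% c("G", "C"))
}

#' Longest homopolymer run
#' @param seq Nucleotide string.
#' @return Length of the longest run of identical consecutive bases.
#' @export
max_homopolymer_run <- function(seq) {
  if (nchar(seq) == 0L) return(0L)
  max(rle(strsplit(seq, "", fixed = TRUE)[[1]])$lengths)
}

#' Composition constraint screen
#'
#' A sequence is synthesizable/sequenceable under the codec's rules iff its
#' GC fraction lies in `[gc_min, gc_max]` and its longest homopolymer run does
#' not exceed `max_homopolymer`.
#'
#' @param seq Non-empty nucleotide string.
#' @param gc_min,gc_max GC window.
#' @param max_homopolymer Maximum run length.
#' @return `TRUE` or `FALSE`.
#' @examples
#' passes_constraints("ACGT")   # TRUE
#' passes_constraints("AAAA")   # FALSE (run of 4)
#' @export
passes_constraints <- function(seq, gc_min = 0.40, gc_max = 0.60,
                               max_homopolymer = 3L) {
  if (nchar(seq) == 0L) stop("empty sequence", call. = FALSE)
  check_alphabet(seq)
  gc <- gc_fraction(seq)
  gc >= gc_min && gc <= gc_max && max_homopolymer_run(seq) <= max_homopolymer
}

#' Reverse complement
#' @param seq Nucleotide string.
#' @return The reverse complement string.
#' @export
revcomp <- function(seq) {
  if (nchar(seq) == 0L) return("")
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "", fixed = TRUE)[[1]]),
        collapse = "")
}
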
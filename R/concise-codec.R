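# Concise-data codec: Unicode text <-> square 0/1 matrices (nanodot bitmaps).
# A 32-bit big-endian byte-count header precedes the UTF-8 payload bits; the
# matrix is filled row-major from the top-left and zero-padded to the
# smallest square.

#' Construct a bit matrix
#'
#' @param bits 0/1 matrix (square for encoded payloads).
#' @param pitch_nm Physical dot spacing metadata (may be `NA`).
#' @param payload_bit_count Number of meaningful bits (header + payload).
#' @return Object of class `bit_matrix`.
#' @export
bit_matrix <- function(bits, pitch_nm = NA_real_, payload_bit_count = length(bits)) {
  bits <- as.matrix(bits)
  storage.mode(bits) <- "integer"
  if (!all(bits %in% c(0L, 1L))) stop("bit matrix entries must be 0 or 1", call. = FALSE)
  structure(list(bits = bits, side = nrow(bits), pitch_nm = pitch_nm,
                 payload_bit_count = as.integer(payload_bit_count)),
            class = "bit_matrix")
}

#' @export
print.bit_matrix <- function(x, ...) {
  cat(sprintf("<bit_matrix> %dx%d, %d payload bits, pitch %s nm\n",
              nrow(x$bits), ncol(x$bits), x$payload_bit_count,
              format(x$pitch_nm)))
  invisible(x)
}

bytes_to_bits <- function(bytes) {
  if (length(bytes) == 0L) return(integer(0))
  m <- matrix(as.integer(rawToBits(bytes)), nrow = 8L)  # little-endian per byte
  as.integer(m[8:1, ])  # most-significant bit first
}

bits_to_bytes <- function(bits) {
  stopifnot(length(bits) %% 8L == 0L)
  if (length(bits) == 0L) return(raw(0))
  m <- matrix(as.integer(bits), nrow = 8L)
  packBits(as.raw(m[8:1, ]), "raw")
}

#' Encode text as a square bit matrix
#'
#' The text's UTF-8 bytes are preceded by a 32-bit big-endian byte-count
#' header; the bit stream fills the smallest possible square row-major
#' (top-left origin) and is zero-padded. [matrix_to_text()] inverts exactly.
#'
#' @param text A character scalar (any Unicode).
#' @param pitch_nm Physical pitch metadata to carry on the matrix.
#' @return A [bit_matrix()].
#' @examples
#' m <- text_to_matrix("A")
#' m$side  # 7: ceil(sqrt(32 + 8))
#' matrix_to_text(m)  # "A"
#' @export
text_to_matrix <- function(text, pitch_nm = NA_real_) {
  stopifnot(is.character(text), length(text) == 1L)
  bytes <- charToRaw(enc2utf8(text))
  n <- length(bytes)
  header <- bytes_to_bits(as.raw(c(n %/% 16777216L, (n %/% 65536L) %% 256L,
                                   (n %/% 256L) %% 256L, n %% 256L)))
  payload <- c(header, bytes_to_bits(bytes))
  side <- ceiling(sqrt(length(payload)))
  bits <- integer(side * side)
  bits[seq_along(payload)] <- payload
  bit_matrix(matrix(bits, nrow = side, byrow = TRUE), pitch_nm,
             payload_bit_count = length(payload))
}

#' Decode a bit matrix back to text
#'
#' Exact inverse of [text_to_matrix()]. Padding bits are ignored; a corrupted
#' header (declared length beyond capacity) or payload that is not valid
#' UTF-8 raises a decode-failure error.
#'
#' @param m A [bit_matrix()] (or plain 0/1 matrix).
#' @return The decoded character scalar.
#' @export
matrix_to_text <- function(m) {
  bits <- if (inherits(m, "bit_matrix")) m$bits else m
  stream <- as.integer(t(bits))  # row-major read-out
  if (length(stream) < 32L) stop("matrix too small for header", call. = FALSE)
  hdr <- as.numeric(bits_to_bytes(stream[1:32]))
  n <- ((hdr[1] * 256 + hdr[2]) * 256 + hdr[3]) * 256 + hdr[4]
  if (32 + 8 * n > length(stream))
    stop(sprintf("malformed header: %.0f bytes declared, capacity %d bits",
                 n, length(stream) - 32L), call. = FALSE)
  if (n == 0L) return("")
  bytes <- bits_to_bytes(stream[33:(32L + 8L * n)])
  out <- rawToChar(bytes)
  if (!validUTF8(out)) stop("decoded payload is not valid UTF-8", call. = FALSE)
  Encoding(out) <- "UTF-8"
  out
}

#' Catalog record
#'
#' One entry of the library catalog (concise file #0): which storage unit
#' holds a named file and where that unit sits on the chip grid.
#'
#' @param unit_id Non-negative integer.
#' @param file_name File name (must not contain `|` or newline).
#' @param row,col Unit grid coordinates.
#' @return Object of class `catalog_record`.
#' @export
catalog_record <- function(unit_id, file_name, row, col) {
  stopifnot(unit_id >= 0L, !grepl("[|\n]", file_name))
  structure(list(unit_id = as.integer(unit_id), file_name = file_name,
                 row = as.integer(row), col = as.integer(col)),
            class = "catalog_record")
}

#' Encode the catalog as a bit matrix
#'
#' Records are serialized one per line as `id|name|row|col` and passed
#' through [text_to_matrix()].
#'
#' @param records List of [catalog_record()]s with unique unit ids.
#' @return A [bit_matrix()].
#' @export
encode_catalog <- function(records) {
  ids <- vapply(records, function(r) r$unit_id, integer(1))
  if (anyDuplicated(ids)) stop("duplicate unit_id in catalog", call. = FALSE)
  lines <- vapply(records, function(r)
    sprintf("%d|%s|%d|%d", r$unit_id, r$file_name, r$row, r$col), character(1))
  text_to_matrix(paste(lines, collapse = "\n"))
}

#' Decode a catalog matrix
#'
#' @param m A [bit_matrix()] produced by [encode_catalog()].
#' @return A data.frame with columns `unit_id`, `file_name`, `row`, `col`.
#' @export
decode_catalog <- function(m) {
  text <- matrix_to_text(m)
  if (nchar(text) == 0L)
    return(data.frame(unit_id = integer(0), file_name = character(0),
                      row = integer(0), col = integer(0)))
  fields <- strsplit(strsplit(text, "\n", fixed = TRUE)[[1]], "|", fixed = TRUE)
  if (any(lengths(fields) != 4L)) stop("malformed catalog line", call. = FALSE)
  data.frame(
    unit_id = as.integer(vapply(fields, `[`, "", 1L)),
    file_name = vapply(fields, `[`, "", 2L),
    row = as.integer(vapply(fields, `[`, "", 3L)),
    col = as.integer(vapply(fields, `[`, "", 4L))
  )
}

escape_primer_lines <- function(body)
  gsub("(?m)^(\\\\*PRIMERS\\|)", "\\\\\\1", body, perl = TRUE)

unescape_primer_lines <- function(body)
  gsub("(?m)^\\\\(\\\\*PRIMERS\\|)", "\\1", body, perl = TRUE)

#' Encode a concise file (body text plus its detailed file's primers)
#'
#' The body is followed by a trailer line `PRIMERS|<fwd>|<rev>` carrying the
#' PCR primer pair of the paired detailed file, so reading the nanodot array
#' alone suffices to launch the in-situ amplification of the archival data.
#' Body lines that themselves start with `PRIMERS|` are escaped.
#'
#' @param body Character scalar (frequently accessed text).
#' @param primer_pair A [primer_pair()].
#' @return A [bit_matrix()].
#' @export
encode_concise_file <- function(body, primer_pair) {
  stopifnot(inherits(primer_pair, "primer_pair"))
  text_to_matrix(paste0(escape_primer_lines(body), "\n",
                        sprintf("PRIMERS|%s|%s",
                                primer_pair$forward, primer_pair$reverse)))
}

#' Decode a concise file
#'
#' @param m A [bit_matrix()] from [encode_concise_file()].
#' @return List with `body` (character) and `primer_pair` ([primer_pair()]).
#' @export
decode_concise_file <- function(m) {
  text <- matrix_to_text(m)
  cut <- regexpr("\nPRIMERS\\|[^\n]*$", text)
  if (cut < 0L) stop("concise file lacks a PRIMERS trailer", call. = FALSE)
  trailer <- substr(text, cut + 1L, nchar(text))
  parts <- strsplit(trailer, "|", fixed = TRUE)[[1]]
  if (length(parts) != 3L) stop("malformed PRIMERS trailer", call. = FALSE)
  list(body = unescape_primer_lines(substr(text, 1L, cut - 1L)),
       primer_pair = primer_pair(parts[2], parts[3]))
}
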
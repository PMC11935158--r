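# Dual-mode library: storage units pairing a concise nanodot bitmap with a
# detailed DNA file, a catalog unit for indirection, and fully in-silico
# random access through the AFM and sequencing channels.

#' Deterministic demonstration payloads
#'
#' Generates the demonstration library's detailed payloads at the
#' demonstrated byte sizes: one 1,595-byte binary file (a stand-in for the
#' stored seal image; content is seeded pseudo-random bytes) and four
#' 101-byte text files (404 bytes of text in total). Together: 1,999 bytes.
#'
#' @param seed Integer seed.
#' @return Named list of raw vectors: `seal`, `name`, `motto`, `anthem`,
#'   `ethos`.
#' @export
demo_payloads <- function(seed = 1L) {
  withr::with_seed(seed, {
    printable <- as.raw(32:126)
    list(
      seal = as.raw(sample(0:255, 1595, replace = TRUE)),
      name = sample(printable, 101, replace = TRUE),
      motto = sample(printable, 101, replace = TRUE),
      anthem = sample(printable, 101, replace = TRUE),
      ethos = sample(printable, 101, replace = TRUE)
    )
  })
}

#' Build the demonstration dual-mode library
#'
#' Six storage units on a 2x3 grid: unit 0 holds the catalog; units 1-5 each
#' pair a concise bitmap (a short description plus the unit's PCR primers)
#' with a detailed DNA file. Primer pairs are distinct across units with
#' pairwise edit distance >= 8. Deterministic under `seed`.
#'
#' @param seed Integer seed.
#' @param layout A [sequence_layout()].
#' @return Object of class `dual_mode_library`.
#' @export
build_demo_library <- function(seed = 1L, layout = sequence_layout()) {
  payloads <- demo_payloads(seed)
  withr::with_seed(seed + 1L, {
    grid_row <- c(0L, 0L, 0L, 1L, 1L, 1L)
    grid_col <- c(0L, 1L, 2L, 0L, 1L, 2L)
    taken <- character(0)
    units <- vector("list", length(payloads))
    records <- vector("list", length(payloads))
    for (i in seq_along(payloads)) {
      name <- names(payloads)[i]
      pp <- random_primer_pair(layout, avoid = taken)
      taken <- c(taken, pp$forward, pp$reverse)
      strands <- encode_file(payloads[[i]], file_id = i, pp, layout)
      body <- sprintf("unit %d\nfile %s\n%d bytes in %d strands",
                      i, name, length(payloads[[i]]), length(strands))
      units[[i]] <- structure(
        list(unit_id = i, row = grid_row[i + 1L], col = grid_col[i + 1L],
             name = name, concise_matrix = encode_concise_file(body, pp),
             strands = strands, primer_pair = pp,
             n_strands = length(strands), detailed_bytes = payloads[[i]]),
        class = "storage_unit")
      records[[i]] <- catalog_record(i, name, grid_row[i + 1L],
                                     grid_col[i + 1L])
    }
    structure(list(catalog = encode_catalog(records), units = units,
                   layout = layout),
              class = "dual_mode_library")
  })
}

#' @export
print.dual_mode_library <- function(x, ...) {
  cat(sprintf("<dual_mode_library> catalog + %d units\n", length(x$units)))
  for (u in x$units)
    cat(sprintf("  unit %d (%d,%d) %-7s %5d bytes, %3d strands, concise %dx%d\n",
                u$unit_id, u$row, u$col, u$name, length(u$detailed_bytes),
                u$n_strands, u$concise_matrix$side, u$concise_matrix$side))
  invisible(x)
}

# Read a bit matrix through the full AFM channel: render, flatten, detect,
# threshold (with square-placement disambiguation).
afm_round_trip <- function(m, dot = dot_model(), seed = NULL,
                           validate = matrix_to_text) {
  img <- synthesize_image(m, dot, seed = seed)
  read_matrix_auto(plane_flatten(img), validate = validate)
}

#' Random access to one detailed file of a library
#'
#' Executes the complete read path in silico: the catalog bitmap is read
#' through the AFM channel and decoded to locate the target unit; the unit's
#' concise bitmap is read the same way and yields the PCR primer pair; the
#' unit's strands then pass through the sequencing channel and
#' [recover_file()] reconstructs the payload. The primers driving the
#' sequencing stage are the ones recovered from the image, exercising the
#' concise-to-detailed indirection end to end.
#'
#' @param library A [build_demo_library()] result.
#' @param target_name File name listed in the catalog.
#' @param channel A [channel_params()].
#' @param dot A [dot_model()] for the AFM read-out.
#' @param seed Integer seed for the AFM noise and sequencing channel.
#' @return List with `bytes` and `report` (see [recover_file()]).
#' @export
random_access <- function(library, target_name, channel = channel_params(),
                          dot = dot_model(), seed = NULL) {
  run <- function() {
    catalog <- decode_catalog(afm_round_trip(library$catalog, dot,
                                             validate = decode_catalog))
    hit <- catalog[catalog$file_name == target_name, ]
    if (nrow(hit) == 0L)
      stop(sprintf("file '%s' not present in catalog", target_name),
           call. = FALSE)
    unit <- NULL
    for (u in library$units)
      if (u$row == hit$row && u$col == hit$col) unit <- u
    if (is.null(unit))
      stop(sprintf("catalog points to empty position (%d,%d)",
                   hit$row, hit$col), call. = FALSE)
    concise <- decode_concise_file(
      afm_round_trip(unit$concise_matrix, dot, validate = decode_concise_file))
    reads <- simulate_reads(unit$strands, channel)
    recover_file(reads, concise$primer_pair, unit$n_strands, library$layout)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Serialize a library to a directory
#'
#' Writes `manifest.json`, per-unit strand FASTA (`unit<k>.fasta`, record
#' ids `<file_id>:<index>`), and per-unit bitmap TSV (`unit<k>.tsv`,
#' catalog as `unit0.tsv`).
#'
#' @param library A [build_demo_library()] result.
#' @param dir Target directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_library <- function(library, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(units = lapply(library$units, function(u) list(
    unit_id = u$unit_id, name = u$name, row = u$row, col = u$col,
    n_strands = u$n_strands, n_bytes = length(u$detailed_bytes),
    forward = u$primer_pair$forward, reverse = u$primer_pair$reverse)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write_bit_matrix(library$catalog, file.path(dir, "unit0.tsv"))
  for (u in library$units) {
    write_bit_matrix(u$concise_matrix,
                     file.path(dir, sprintf("unit%d.tsv", u$unit_id)))
    seqs <- vapply(u$strands, function(r) r$full, character(1))
    names(seqs) <- vapply(u$strands,
                          function(r) sprintf("%d:%d", r$file_id, r$index),
                          character(1))
    write_fasta(seqs, file.path(dir, sprintf("unit%d.fasta", u$unit_id)))
  }
  invisible(dir)
}
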
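# Standard-format I/O: FASTA/FASTQ via Biostrings, bitmap/height-image TSV,
# plain PGM, key-value layout configs, JSON reports.

#' Read and write FASTA
#'
#' Thin wrappers over Biostrings; gzip-transparent on read, identical round
#' trips for ACGT sequences.
#'
#' @param seqs Named character vector of sequences.
#' @param path File path.
#' @return `read_fasta` returns a named character vector.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) names(x) <- seq_along(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Read and write FASTQ
#'
#' The simulated channel carries no quality concept, so writes use a
#' constant quality (`I`, Phred 40).
#'
#' @param reads Character vector of reads.
#' @param path File path (`.gz` accepted).
#' @param quality Constant quality character.
#' @return `read_fastq` returns a named character vector.
#' @export
write_fastq <- function(reads, path, quality = "I") {
  ids <- if (is.null(names(reads))) as.character(seq_along(reads))
         else make.unique(paste0("read_", names(reads)))
  x <- Biostrings::DNAStringSet(unname(reads))
  names(x) <- ids
  q <- Biostrings::BStringSet(vapply(nchar(reads),
                                     function(n) strrep(quality, n),
                                     character(1)))
  names(q) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L)
    stop(sprintf("truncated FASTQ: record starting at line %d is incomplete",
                 (length(lines) %/% 4L) * 4L + 1L), call. = FALSE)
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}

#' Write and read a bit matrix as TSV
#'
#' Tab-separated 0/1 rows; the physical pitch, when known, travels in a
#' `<path>.meta` key-value sidecar.
#'
#' @param m A [bit_matrix()].
#' @param path File path.
#' @return `read_bit_matrix` returns a [bit_matrix()].
#' @export
write_bit_matrix <- function(m, path) {
  utils::write.table(m$bits, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  if (!is.na(m$pitch_nm))
    writeLines(sprintf("pitch_nm=%g", m$pitch_nm), paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_bit_matrix
#' @export
read_bit_matrix <- function(path) {
  bits <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(bits) <- NULL
  pitch <- NA_real_
  meta <- paste0(path, ".meta")
  if (file.exists(meta)) {
    kv <- read_key_values(meta)
    if (!is.null(kv$pitch_nm)) pitch <- as.numeric(kv$pitch_nm)
  }
  bit_matrix(bits, pitch_nm = pitch)
}

#' Write and read a height image as TSV
#'
#' @param img A [height_image()].
#' @param path File path; pixel size goes to a `<path>.meta` sidecar.
#' @return `read_height_image` returns a [height_image()].
#' @export
write_height_image <- function(img, path) {
  utils::write.table(signif(img$heights, 8), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("pixel_size_nm=%g", img$pixel_size_nm),
             paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_height_image
#' @export
read_height_image <- function(path) {
  z <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(z) <- NULL
  pixel <- 5
  meta <- paste0(path, ".meta")
  if (file.exists(meta)) {
    kv <- read_key_values(meta)
    if (!is.null(kv$pixel_size_nm)) pixel <- as.numeric(kv$pixel_size_nm)
  }
  height_image(z, pixel)
}

#' Write a matrix or height image as a plain (ASCII) PGM
#'
#' Bit matrices map 0/1 to 0/255 (8-bit); height images are scaled by
#' `scale` (hundredths of a nm by default) into 16-bit values.
#'
#' @param x A [bit_matrix()] or [height_image()].
#' @param path File path.
#' @param scale Multiplier applied to heights before rounding.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(x, path, scale = 100) {
  if (inherits(x, "bit_matrix")) {
    vals <- x$bits * 255L
    maxval <- 255L
  } else {
    z <- x$heights
    vals <- round((z - min(z)) * scale)
    maxval <- max(vals, 1L)
    if (maxval > 65535L) stop("height range exceeds 16-bit PGM", call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(vals), nrow(vals)),
               sprintf("%d", maxval)), con)
  utils::write.table(vals, con, sep = " ", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

read_key_values <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop(sprintf("malformed key-value line %d in %s",
                             which(bad)[1], path), call. = FALSE)
  stats::setNames(lapply(parts, `[`, 2L), vapply(parts, `[`, "", 1L))
}

#' Write and read a strand layout as a key-value config
#'
#' Keys mirror the [sequence_layout()] fields; unknown keys are rejected on
#' read.
#'
#' @param layout A [sequence_layout()].
#' @param path File path.
#' @return `read_layout_config` returns a [sequence_layout()].
#' @export
write_layout_config <- function(layout, path) {
  keys <- c("payload_len", "gc_min", "gc_max", "max_homopolymer",
            "seed_max_len")
  writeLines(sprintf("%s=%g", keys, unlist(layout[keys])), path)
  invisible(path)
}

#' @rdname write_layout_config
#' @export
read_layout_config <- function(path) {
  kv <- read_key_values(path)
  known <- c("payload_len", "gc_min", "gc_max", "max_homopolymer",
             "seed_max_len")
  unknown <- setdiff(names(kv), known)
  if (length(unknown))
    stop(sprintf("unknown layout keys: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  args <- lapply(kv, function(v) as.numeric(v))
  do.call(sequence_layout, args)
}

#' Write a decode report as JSON
#'
#' @param report A `decode_report` from [recover_file()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_decode_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Load a library saved by [save_library()]
#'
#' Restores everything [random_access()] needs (catalog and concise
#' matrices, strand sequences, primer pairs, strand counts); the original
#' payload bytes are not part of the serialized form.
#'
#' @param dir Directory written by [save_library()].
#' @param layout A [sequence_layout()].
#' @return A `dual_mode_library`.
#' @export
load_library <- function(dir, layout = sequence_layout()) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  units <- lapply(manifest$units, function(u) {
    seqs <- read_fasta(file.path(dir, sprintf("unit%d.fasta", u$unit_id)))
    structure(list(unit_id = u$unit_id, row = u$row, col = u$col,
                   name = u$name,
                   concise_matrix = read_bit_matrix(
                     file.path(dir, sprintf("unit%d.tsv", u$unit_id))),
                   strands = unname(seqs),
                   primer_pair = primer_pair(u$forward, u$reverse),
                   n_strands = u$n_strands, detailed_bytes = raw(0)),
              class = "storage_unit")
  })
  structure(list(catalog = read_bit_matrix(file.path(dir, "unit0.tsv")),
                 units = units, layout = layout),
            class = "dual_mode_library")
}
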
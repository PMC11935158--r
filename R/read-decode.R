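# Read-decoding pipeline: two-end primer filtering/trimming, abundance-greedy
# edit-distance sphere clustering, top-n centroid selection, consensus
# polishing, strand decoding, and error-rate evaluation.

#' Locate a primer within a read by semi-global alignment
#'
#' Best infix (free ends in the read, whole primer consumed) alignment under
#' unit edit costs; a hit is reported iff its edit count is at most
#' `max_edits`. Ties are broken toward the smaller start.
#'
#' @param read Read sequence.
#' @param primer Primer sequence (>= 4 nt).
#' @param max_edits Maximum tolerated edits.
#' @return List with `found`, `start`, `end` (1-based, inclusive), `edits`.
#' @export
locate_primer <- function(read, primer, max_edits = 4L) {
  stopifnot(nchar(primer) >= 4L)
  hit <- cpp_best_infix(primer, read)
  if (hit$edits <= max_edits)
    list(found = TRUE, start = hit$start, end = hit$end, edits = hit$edits)
  else
    list(found = FALSE, start = NA_integer_, end = NA_integer_,
         edits = hit$edits)
}

#' Filter reads by two-end primers and trim to the interior
#'
#' Each read is tried as-is and reverse-complemented; it is kept iff the
#' forward primer is found near the 5' end and the reverse complement of the
#' reverse primer near the 3' end, and the trimmed interior length falls in
#' `length_window`. Output is the interior (core plus outer RS region) in
#' canonical orientation.
#'
#' @param reads Character vector of reads.
#' @param primer_pair A [primer_pair()].
#' @param max_edits Maximum edits per primer match.
#' @param length_window `c(lo, hi)` for the trimmed length; default derives
#'   from `layout` as the possible interior lengths +/- 12 nt.
#' @param layout A [sequence_layout()].
#' @return Character vector of trimmed interiors.
#' @export
filter_and_trim <- function(reads, primer_pair, max_edits = 4L,
                            length_window = NULL, layout = sequence_layout()) {
  if (is.null(length_window)) {
    lo <- layout$min_core_len + layout$rs_outer_len - 12L
    hi <- layout$min_core_len + layout$rs_outer_len +
      (layout$seed_max_len - layout$seed_min_len) + 12L
    length_window <- c(lo, hi)
  }
  p <- layout$pcr_primer_len
  fwd <- primer_pair$forward
  rc_rev <- revcomp(primer_pair$reverse)
  head_w <- p + max_edits + 8L
  trim_one <- function(read) {
    n <- nchar(read)
    if (n < length_window[1]) return(NA_character_)
    f <- locate_primer(substr(read, 1L, min(n, head_w)), fwd, max_edits)
    if (!f$found || f$start > 9L) return(NA_character_)
    tail_from <- max(1L, n - head_w + 1L)
    r <- locate_primer(substr(read, tail_from, n), rc_rev, max_edits)
    if (!r$found) return(NA_character_)
    r_start <- tail_from + r$start - 1L
    r_end <- tail_from + r$end - 1L
    if (n - r_end > 8L) return(NA_character_)
    interior <- substr(read, f$end + 1L, r_start - 1L)
    if (nchar(interior) < length_window[1] || nchar(interior) > length_window[2])
      return(NA_character_)
    interior
  }
  out <- character(0)
  for (read in reads) {
    t1 <- trim_one(read)
    if (!is.na(t1)) { out <- c(out, t1); next }
    t2 <- trim_one(revcomp(read))
    if (!is.na(t2)) out <- c(out, t2)
  }
  out
}

#' Greedy edit-distance sphere clustering of trimmed reads
#'
#' Unique sequences are sorted by multiplicity (descending, lexicographic
#' tiebreak); repeatedly, the most abundant unassigned sequence becomes a
#' centroid and absorbs every unassigned sequence within Levenshtein distance
#' `radius`. Clusters are returned in decreasing abundance (centroid
#' lexicographic tiebreak).
#'
#' @param trimmed_reads Character vector.
#' @param radius Cluster radius in edits.
#' @return List of `read_cluster` objects (`centroid`, `abundance`,
#'   `member_ids` indexing `trimmed_reads`).
#' @export
cluster_reads <- function(trimmed_reads, radius = 3L) {
  if (length(trimmed_reads) == 0L) return(list())
  ids_by_seq <- split(seq_along(trimmed_reads), trimmed_reads)
  uniq <- names(ids_by_seq)
  mult <- lengths(ids_by_seq)
  ord <- order(-mult, uniq, method = "radix")
  uniq <- uniq[ord]
  mult <- mult[ord]
  ids_by_seq <- ids_by_seq[ord]
  n <- length(uniq)
  alive <- rep(TRUE, n)
  clusters <- list()
  while (any(alive)) {
    ci <- which(alive)[1]
    cand <- which(alive)
    d <- cpp_bounded_edit_many(uniq[ci], uniq[cand], as.integer(radius))
    members <- cand[d <= radius]
    alive[members] <- FALSE
    clusters[[length(clusters) + 1L]] <- structure(
      list(centroid = uniq[ci],
           abundance = sum(mult[members]),
           member_ids = unlist(ids_by_seq[members], use.names = FALSE),
           member_seqs = uniq[members]),
      class = "read_cluster")
  }
  ab <- vapply(clusters, function(cl) cl$abundance, numeric(1))
  ce <- vapply(clusters, function(cl) cl$centroid, character(1))
  clusters[order(-ab, ce, method = "radix")]
}

#' Select the top-n cluster centroids
#'
#' @param clusters Output of [cluster_reads()] (abundance-descending).
#' @param n Number of centroids wanted (the number of strands of the file).
#' @return List with `centroids` (<= n sequences) and `shortfall` (`TRUE`
#'   when fewer than `n` clusters exist).
#' @export
select_top_n <- function(clusters, n) {
  stopifnot(n >= 1L)
  k <- min(n, length(clusters))
  list(centroids = vapply(clusters[seq_len(k)], function(cl) cl$centroid,
                          character(1)),
       shortfall = length(clusters) < n)
}

# Positional-majority consensus of a cluster: iteratively align members to
# the template and take the per-position majority (including indels).
polish_cluster <- function(cluster, max_members = 48L, rounds = 8L,
                           band = 40L) {
  members <- cluster$member_seqs
  if (length(members) > max_members) members <- members[seq_len(max_members)]
  tpl <- cluster$centroid
  for (r in seq_len(rounds)) {
    new_tpl <- cpp_consensus_round(tpl, members, as.integer(band))
    if (new_tpl == tpl) break
    tpl <- new_tpl
  }
  tpl
}

#' Recover a file from noisy reads
#'
#' Runs the full pipeline: [filter_and_trim()], [cluster_reads()] at a
#' channel-matched radius, [select_top_n()], consensus polishing of each
#' selected cluster, interior strand decoding, and payload reassembly. When
#' decoded indices are still missing after the top-n clusters, decoding
#' continues down the abundance-ordered cluster list (duplicate clusters of
#' one strand would otherwise displace rare strands).
#'
#' @param reads Character vector of reads.
#' @param primer_pair The file's [primer_pair()].
#' @param n_strands Expected number of strands (from the library manifest).
#' @param layout A [sequence_layout()].
#' @param cluster_radius Sphere-clustering radius for noisy reads.
#' @param polish Consensus-polish selected clusters before decoding.
#' @param max_edits Primer-matching tolerance for [filter_and_trim()].
#' @return List with `bytes` (raw vector, possibly partial) and `report`
#'   (a `decode_report`).
#' @export
recover_file <- function(reads, primer_pair, n_strands,
                         layout = sequence_layout(), cluster_radius = 30L,
                         polish = TRUE, max_edits = 4L) {
  report <- list(n_reads_in = length(reads), n_reads_passing_filter = 0L,
                 n_clusters = 0L, n_strands_expected = as.integer(n_strands),
                 n_strands_recovered = 0L, error_rate = 1.0,
                 per_strand_status = data.frame())
  class(report) <- "decode_report"
  if (length(reads) == 0L)
    return(list(bytes = raw(0), report = report))
  trimmed <- filter_and_trim(reads, primer_pair, max_edits = max_edits,
                             layout = layout)
  report$n_reads_passing_filter <- length(trimmed)
  if (length(trimmed) == 0L)
    return(list(bytes = raw(0), report = report))
  clusters <- cluster_reads(trimmed, radius = cluster_radius)
  report$n_clusters <- length(clusters)
  decoded <- list()
  seen_idx <- integer(0)
  status <- list()
  for (ci in seq_along(clusters)) {
    if (length(seen_idx) >= n_strands && ci > n_strands) break
    cl <- clusters[[ci]]
    seq_i <- if (polish) polish_cluster(cl, band = cluster_radius + 10L)
             else cl$centroid
    res <- decode_core(seq_i, layout)
    keep <- res$ok && !(res$index %in% seen_idx)
    if (keep) {
      decoded[[length(decoded) + 1L]] <- res
      seen_idx <- c(seen_idx, res$index)
    }
    status[[length(status) + 1L]] <- data.frame(
      cluster = ci, abundance = cl$abundance,
      decoded = res$ok, index = res$index,
      note = if (res$ok && !keep) "duplicate index"
             else if (res$ok) "ok" else res$reason)
  }
  report$per_strand_status <- do.call(rbind, status)
  report$n_strands_recovered <- length(decoded)
  report$error_rate <- 1 - length(decoded) / n_strands
  bytes <- if (length(decoded) == 0L) raw(0)
           else tryCatch(assemble_chunks(decoded, layout),
                         warning = function(w) suppressWarnings(
                           assemble_chunks(decoded, layout)),
                         error = function(e) raw(0))
  list(bytes = bytes, report = report)
}

#' @export
print.decode_report <- function(x, ...) {
  cat(sprintf(paste0("<decode_report> %d reads in, %d passed filter, ",
                     "%d clusters, %d/%d strands recovered (error rate %.3f)\n"),
              x$n_reads_in, x$n_reads_passing_filter, x$n_clusters,
              x$n_strands_recovered, x$n_strands_expected, x$error_rate))
  invisible(x)
}

#' Edit-distance error rate of recovered sequences against the originals
#'
#' Compares on the strands' interior regions (core plus outer RS), the same
#' sequences the clustering pipeline recovers.
#'
#' @param original_strands List of `strand_record`s (or character vector of
#'   interiors).
#' @param centroids Recovered sequences.
#' @param layout A [sequence_layout()].
#' @return Fraction: total edit distance over total original length.
#' @export
evaluate_against_originals <- function(original_strands, centroids,
                                       layout = sequence_layout()) {
  p <- layout$pcr_primer_len
  originals <- if (is.character(original_strands)) original_strands
    else vapply(original_strands,
                function(r) substr(r$full, p + 1L, nchar(r$full) - p),
                character(1))
  sequence_error_rate(originals, centroids)
}
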
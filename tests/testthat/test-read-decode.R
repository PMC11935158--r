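test_that("semi-global primer location matches a brute-force oracle", {
  primer <- "ACGTACGTACGTACGTACGT"
  hit <- locate_primer(paste0(primer, "TTTTTTTT"), primer, 2)
  expect_true(hit$found)
  expect_identical(c(hit$start, hit$end, hit$edits), c(1L, 20L, 0L))
  # one substitution mid-read
  read <- paste0("GGC", "ACGTACGTAAGTACGTACGT", "TTACG")
  hit2 <- locate_primer(read, primer, 2)
  expect_true(hit2$found)
  expect_identical(hit2$edits, 1L)
  expect_identical(oracle_best_infix_edits(primer, read), 1L)
  # random reads: reported edit count equals the oracle optimum
  withr::with_seed(20, {
    for (i in 1:10) {
      r <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
      p <- paste(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = "")
      got <- locate_primer(r, p, max_edits = 100)
      expect_identical(got$edits, oracle_best_infix_edits(p, r))
    }
  })
  # far-away primer is not found under a tight budget
  expect_false(locate_primer("AAAAAAAAAAAAAAAAAAAAAAAAAAAAAA",
                             "CGCGCGCGCGCGCGCGCGCG", 4)$found)
})

test_that("filter_and_trim keeps clean strands and rejects foreign primers", {
  lay <- sequence_layout()
  pp <- fixture_primer_pair()
  strands <- encode_file(fixture_bytes(120, seed = 21), 1L, pp, lay, seed = 1)
  fulls <- vapply(strands, function(r) r$full, character(1))
  interiors <- vapply(strands, function(r)
    substr(r$full, 21, nchar(r$full) - 20), character(1))
  trimmed <- filter_and_trim(fulls, pp, layout = lay)
  expect_identical(sort(trimmed), sort(interiors))
  # reverse-complemented reads trim to the same canonical interiors
  rc <- vapply(fulls, revcomp, character(1))
  expect_identical(sort(filter_and_trim(rc, pp, layout = lay)),
                   sort(interiors))
  # a different file's primers pass nothing (orthogonality filter)
  other <- withr::with_seed(99,
    random_primer_pair(lay, avoid = c(pp$forward, pp$reverse)))
  expect_length(filter_and_trim(fulls, other, layout = lay), 0L)
  # truncated reads fail the length window
  expect_length(filter_and_trim(substr(fulls, 1, 100), pp, layout = lay), 0L)
})

test_that("greedy sphere clustering equals the brute-force oracle", {
  reads <- c(rep("ACGT", 10), rep("ACGA", 2), rep("TTTT", 5))
  cl <- cluster_reads(reads, radius = 1)
  expect_identical(vapply(cl, function(x) x$centroid, character(1)),
                   c("ACGT", "TTTT"))
  expect_identical(vapply(cl, function(x) x$abundance, numeric(1)), c(12, 5))
  # radius 0: unique-sequence histogram
  cl0 <- cluster_reads(reads, radius = 0)
  expect_identical(length(cl0), 3L)
  # all identical: one cluster
  expect_length(cluster_reads(rep("GATTACA", 7), radius = 2), 1L)
  # randomized equivalence with the oracle, up to 200 unique sequences
  withr::with_seed(22, {
    for (trial in 1:8) {
      n <- sample(50:200, 1)
      radius <- sample(1:3, 1)
      pool <- vapply(1:40, function(i)
        paste(sample(c("A", "C", "G"), sample(6:12, 1), TRUE), collapse = ""),
        character(1))
      reads <- sample(pool, n, replace = TRUE)
      got <- cluster_reads(reads, radius)
      want <- oracle_greedy_cluster(reads, radius)
      expect_identical(length(got), length(want))
      expect_identical(vapply(got, function(x) x$centroid, character(1)),
                       vapply(want, function(x) x$centroid, character(1)))
      expect_identical(vapply(got, function(x) x$abundance, numeric(1)),
                       vapply(want, function(x) x$abundance, numeric(1)))
      # abundances account for every read
      expect_identical(sum(vapply(got, function(x) x$abundance, numeric(1))),
                       as.numeric(n))
    }
  })
})

test_that("top-n selection is abundance-ordered with lexicographic ties", {
  clusters <- cluster_reads(c(rep("AAAA", 3), rep("CCCC", 3), rep("GGGG", 5)),
                            radius = 0)
  sel <- select_top_n(clusters, 2)
  expect_identical(sel$centroids, c("GGGG", "AAAA"))  # tie at rank 2 -> lexicographic
  expect_false(sel$shortfall)
  sel_all <- select_top_n(clusters, 10)
  expect_length(sel_all$centroids, 3L)
  expect_true(sel_all$shortfall)
})

test_that("recover_file survives empty and hopeless inputs", {
  pp <- fixture_primer_pair()
  res0 <- recover_file(character(0), pp, 5)
  expect_identical(res0$bytes, raw(0))
  expect_identical(res0$report$n_reads_in, 0L)
  # coverage 2 with extreme noise: graceful partial result, no crash
  lay <- sequence_layout()
  strands <- encode_file(fixture_bytes(100, seed = 23), 1L, pp, lay, seed = 2)
  harsh <- channel_params(sub_rate = 0.2, ins_rate = 0.1, del_rate = 0.2,
                          coverage = 2)
  reads <- simulate_reads(strands, harsh, seed = 3)
  res <- recover_file(reads, pp, length(strands), lay)
  expect_true(is.raw(res$bytes))
  expect_lte(res$report$n_reads_passing_filter, res$report$n_reads_in)
  expect_gte(res$report$error_rate, 0)
})

test_that("pipeline counts are monotone and recovery is orientation-invariant", {
  lay <- sequence_layout()
  pp <- fixture_primer_pair()
  data <- fixture_bytes(200, seed = 24)
  strands <- encode_file(data, 1L, pp, lay, seed = 4)
  reads <- simulate_reads(strands, channel_params(coverage = 60), seed = 5)
  res <- recover_file(reads, pp, length(strands), lay)
  expect_identical(res$bytes, data)
  rep <- res$report
  expect_gte(rep$n_reads_in, rep$n_reads_passing_filter)
  expect_lte(rep$n_strands_recovered, rep$n_clusters)
  expect_identical(rep$error_rate, 0)
  # reverse-complementing an arbitrary subset of reads changes nothing
  flipped <- reads
  idx <- withr::with_seed(25, sample(length(reads), length(reads) %/% 3))
  flipped[idx] <- vapply(flipped[idx], revcomp, character(1))
  res2 <- recover_file(flipped, pp, length(strands), lay)
  expect_identical(res2$bytes, data)
})

test_that("evaluate_against_originals is zero for exact recovery", {
  lay <- sequence_layout()
  pp <- fixture_primer_pair()
  strands <- encode_file(fixture_bytes(75, seed = 26), 1L, pp, lay, seed = 6)
  interiors <- vapply(strands, function(r)
    substr(r$full, 21, nchar(r$full) - 20), character(1))
  expect_identical(evaluate_against_originals(strands, interiors, lay), 0)
  # one corrupted recovery contributes its edit distance
  first <- if (substr(interiors[1], 1, 1) == "A") "C" else "A"
  interiors[1] <- paste0(first, substr(interiors[1], 2, nchar(interiors[1])))
  rate <- evaluate_against_originals(strands, interiors, lay)
  expect_gt(rate, 0)
  expect_lte(rate, 1 / sum(nchar(interiors)) + 1e-12)
})
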
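test_that("a zero-error channel is the identity up to orientation", {
  strands <- c("ACGTACGTACGTACGTACGT", "TTGCATGCATGCATGCAAGG")
  clean <- channel_params(sub_rate = 0, ins_rate = 0, del_rate = 0,
                          coverage = 20, revcomp_prob = 0)
  reads <- simulate_reads(strands, clean, seed = 1)
  expect_true(all(reads %in% strands))
  flip <- channel_params(sub_rate = 0, ins_rate = 0, del_rate = 0,
                         coverage = 20, revcomp_prob = 1)
  reads2 <- simulate_reads(strands, flip, seed = 1)
  expect_true(all(reads2 %in% vapply(strands, revcomp, character(1))))
})

test_that("read counts are Poisson at the requested coverage", {
  strands <- withr::with_seed(16, vapply(1:135, function(i)
    paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = ""),
    character(1)))
  reads <- simulate_reads(strands, channel_params(coverage = 100), seed = 2)
  expect_lt(abs(length(reads) - 13500), 3 * sqrt(13500))
})

test_that("empirical substitution frequency matches the configured rate", {
  strand <- withr::with_seed(17,
    paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = ""))
  params <- channel_params(sub_rate = 0.03, ins_rate = 0, del_rate = 0,
                           coverage = 100, revcomp_prob = 0)
  reads <- simulate_reads(strand, params, seed = 3)
  orig <- strsplit(strand, "")[[1]]
  mism <- vapply(reads, function(r) sum(strsplit(r, "")[[1]] != orig),
                 numeric(1))
  n_bases <- 10000 * length(reads)
  p_hat <- sum(mism) / n_bases
  se <- sqrt(0.03 * 0.97 / n_bases)
  expect_lt(abs(p_hat - 0.03), 3 * se)
})

test_that("reads are deterministic under a fixed seed", {
  strands <- c("ACGTACGTACGTACGTACGTACGTACGT")
  r1 <- simulate_reads(strands, channel_params(coverage = 30), seed = 4)
  r2 <- simulate_reads(strands, channel_params(coverage = 30), seed = 4)
  expect_identical(r1, r2)
})

test_that("thermal aging follows first-order kinetics", {
  # t = 0 leaves counts untouched
  expect_identical(age_strands(c(10L, 20L), 100, 25, 300, 0, seed = 1),
                   c(10L, 20L))
  # after one half-life the surviving fraction is 1/2 within 3 binomial se
  Ea <- 100; T_K <- 330
  lnA <- Ea * 1000 / (8.314 * T_K) + log(log(2))  # k = ln 2 per year
  surv <- age_strands(1e5L, Ea, lnA, T_K, 1, seed = 5) / 1e5
  expect_lt(abs(surv - 0.5), 3 * sqrt(0.25 / 1e5))
  # log-survival is linear in t with slope -k (within 2%)
  k <- log(2)
  t <- c(0.5, 1, 1.5, 2, 2.5)
  s <- vapply(seq_along(t), function(i)
    age_strands(1e5L, Ea, lnA, T_K, t[i], seed = 10 + i) / 1e5, numeric(1))
  slope <- coef(lm(log(s) ~ t))[[2]]
  expect_lt(abs(-slope - k) / k, 0.02)
})

test_that("in-situ access preserves template counts exactly", {
  counts <- withr::with_seed(18, sample(50:200, 40, TRUE))
  traj <- simulate_repeated_access(counts, "in_situ",
                                   access_params(n_accesses = 25), seed = 6)
  expect_identical(nrow(traj), 26L)
  for (a in 1:26) expect_identical(traj[a, ], as.numeric(counts))
})

test_that("pooled access without bias is uniform, with bias accumulates", {
  counts <- rep(1000, 50)
  flat <- simulate_repeated_access(counts, "pooled",
                                   access_params(n_accesses = 10,
                                                 consumed_frac = 0,
                                                 efficiency_sd = 0),
                                   seed = 7)
  expect_true(all(abs(flat - 1000) < 1e-9))
  biased <- simulate_repeated_access(rep(1000, 1000), "pooled",
                                     access_params(n_accesses = 25,
                                                   consumed_frac = 0.01,
                                                   efficiency_sd = 0.05),
                                     seed = 8)
  cv <- apply(biased, 1, function(x) sd(x) / mean(x))
  expect_true(all(diff(cv) > 0))
})
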
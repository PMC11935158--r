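# Physical channels between written strands and observed data: nanopore-like
# sequencing, first-order thermal decay, and repeated random access.

#' Sequencing channel parameters
#'
#' Defaults emulate a nanopore-class long-read channel at the coverage used
#' for the demonstration library: mean 100 reads per strand with per-base
#' substitution/insertion/deletion rates of 3/2/3 percent, and reads observed
#' in either orientation with equal probability (in-situ amplification
#' releases the complementary strand).
#'
#' @param sub_rate,ins_rate,del_rate Per-base error probabilities.
#' @param coverage Mean reads per strand (Poisson).
#' @param revcomp_prob Probability a read is reverse-complemented.
#' @return Object of class `channel_params`.
#' @export
channel_params <- function(sub_rate = 0.03, ins_rate = 0.02, del_rate = 0.03,
                           coverage = 100, revcomp_prob = 0.5) {
  stopifnot(sub_rate >= 0, sub_rate < 1, ins_rate >= 0, ins_rate < 1,
            del_rate >= 0, del_rate < 1, coverage > 0,
            revcomp_prob >= 0, revcomp_prob <= 1)
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
                 coverage = coverage, revcomp_prob = revcomp_prob),
            class = "channel_params")
}

#' Simulate sequencing reads
#'
#' Each strand yields `Poisson(coverage)` reads; every read passes through
#' iid per-base substitution/insertion/deletion edits and is then
#' reverse-complemented with probability `revcomp_prob`. Deterministic under
#' `seed`.
#'
#' @param strands Character vector of strand sequences (or `strand_record`
#'   list from [encode_file()]).
#' @param params A [channel_params()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Character vector of reads, named by source strand position.
#' @export
simulate_reads <- function(strands, params = channel_params(), seed = NULL) {
  if (is.list(strands)) strands <- vapply(strands, function(r) r$full, character(1))
  stopifnot(length(strands) > 0L)
  run <- function() {
    n_reads <- stats::rpois(length(strands), params$coverage)
    templ <- rep(strands, n_reads)
    src <- rep(seq_along(strands), n_reads)
    reads <- cpp_mutate_reads(templ, params$sub_rate, params$ins_rate,
                              params$del_rate)
    flip <- stats::runif(length(reads)) < params$revcomp_prob
    reads[flip] <- vapply(reads[flip], revcomp, character(1))
    stats::setNames(reads, src)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Thermal aging of immobilized strands
#'
#' First-order decay with Arrhenius temperature dependence: the rate is
#' `k = exp(lnA - Ea / (R T))` per year and each copy survives an interval
#' `t` independently with probability `exp(-k t)`.
#'
#' @param counts Integer vector of per-strand copy numbers.
#' @param Ea_kJ_mol Activation energy in kJ/mol.
#' @param lnA_per_year Log pre-exponential factor (rate in 1/year).
#' @param T_K Storage temperature in kelvin.
#' @param t_years Storage time in years.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Integer vector of surviving copy numbers.
#' @export
age_strands <- function(counts, Ea_kJ_mol, lnA_per_year, T_K, t_years,
                        seed = NULL) {
  stopifnot(all(counts >= 0), T_K > 0, t_years >= 0)
  k <- exp(lnA_per_year - Ea_kJ_mol * 1000 / (GAS_CONSTANT * T_K))
  p <- exp(-k * t_years)
  run <- function() stats::rbinom(length(counts), as.integer(counts), p)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

GAS_CONSTANT <- 8.314  # J / (mol K)

#' Repeated-access parameters
#'
#' @param n_accesses Number of consecutive random accesses simulated.
#' @param consumed_frac Fraction of template molecules irreversibly consumed
#'   per pooled access (default 0.01; in-situ access consumes none).
#' @param efficiency_sd Spread of per-strand PCR efficiency around 0.9.
#' @param cycles Amplification cycles per pooled recovery.
#' @return Object of class `access_params`.
#' @export
access_params <- function(n_accesses = 25L, consumed_frac = 0.01,
                          efficiency_sd = 0.05, cycles = 20L) {
  stopifnot(consumed_frac >= 0, consumed_frac < 1, cycles >= 0, n_accesses >= 1)
  structure(list(n_accesses = as.integer(n_accesses),
                 consumed_frac = consumed_frac,
                 efficiency_sd = efficiency_sd, cycles = as.integer(cycles)),
            class = "access_params")
}

#' Simulate repeated random access
#'
#' In `in_situ` mode the surface-bound templates are copied, not consumed:
#' template counts stay exactly constant across accesses. In `pooled` mode
#' each access consumes a Binomial fraction of every strand, then the pool is
#' re-amplified with per-strand efficiencies `e_i ~ Normal(0.9,
#' efficiency_sd)` (truncated to \[0, 1\], drawn once per strand) over
#' `cycles` cycles and renormalized to the initial total, so amplification
#' bias accumulates access after access.
#'
#' @param initial_counts Positive per-strand copy numbers.
#' @param mode `"in_situ"` or `"pooled"`.
#' @param params An [access_params()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Numeric matrix of copy numbers, `(n_accesses + 1)` rows (access 0
#'   = initial state) by `length(initial_counts)` columns.
#' @export
simulate_repeated_access <- function(initial_counts, mode = c("in_situ", "pooled"),
                                     params = access_params(), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(initial_counts > 0))
  n <- length(initial_counts)
  run <- function() {
    traj <- matrix(0, nrow = params$n_accesses + 1L, ncol = n)
    traj[1, ] <- initial_counts
    if (mode == "in_situ") {
      for (a in seq_len(params$n_accesses)) traj[a + 1L, ] <- initial_counts
      return(traj)
    }
    eff <- pmin(pmax(stats::rnorm(n, 0.9, params$efficiency_sd), 0), 1)
    gain <- (1 + eff)^params$cycles
    total0 <- sum(initial_counts)
    counts <- as.numeric(initial_counts)
    for (a in seq_len(params$n_accesses)) {
      consumed <- stats::rbinom(n, round(counts), params$consumed_frac)
      counts <- pmax(counts - consumed, 0)
      counts <- counts * gain
      counts <- counts * (total0 / sum(counts))
      traj[a + 1L, ] <- counts
    }
    traj
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
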
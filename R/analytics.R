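# Density and stability analytics: areal storage density of the two modes,
# Arrhenius fitting of accelerated-aging data, half-life extrapolation.

#' Areal density of nanodot (concise) data
#'
#' One bit per dot at spacing `d`: `rho = d^-2`, reported in bit/mm^2 for
#' `d` in nm. At the demonstrated 50-nm dot size the density clears
#' 3e8 bit/mm^2; 10-nm dots reach about 1e10.
#'
#' @param d_nm Spacing between neighbouring nanodots in nm.
#' @return Density in bit/mm^2.
#' @examples
#' nanodot_density(50)  # 4e8
#' @export
nanodot_density <- function(d_nm) {
  stopifnot(all(d_nm > 0))
  (1e6 / d_nm)^2
}

#' Areal density of DNA (detailed) data
#'
#' `rho = L * d^-2` with `L` the data per molecule in bits and `d` the
#' intermolecular spacing in nm.
#'
#' @param L_bits Bits stored per DNA molecule (a 124-nt strand at 2 bits per
#'   base carries 248).
#' @param d_nm Spacing between molecules in nm.
#' @return Density in bit/mm^2.
#' @examples
#' dna_density(248, 10)  # 2.48e12
#' @export
dna_density <- function(L_bits, d_nm) {
  stopifnot(all(L_bits > 0), all(d_nm > 0))
  L_bits * (1e6 / d_nm)^2
}

#' First-order decay rate from a survival observation
#'
#' `k = -ln(survival) / t`.
#'
#' @param survival Surviving fraction in (0, 1\].
#' @param t_years Elapsed time in years.
#' @return Rate per year (0 with a warning when survival is exactly 1).
#' @export
rate_from_survival <- function(survival, t_years) {
  stopifnot(all(t_years > 0), all(survival > 0), all(survival <= 1))
  if (any(survival == 1))
    warning("survival of 1 gives a zero rate", call. = FALSE)
  -log(survival) / t_years
}

#' Fit the Arrhenius law to accelerated-aging observations
#'
#' Converts each observation to a first-order rate, then least-squares fits
#' `ln k` on `1/T`: the activation energy is `-slope * R` and `lnA` the
#' intercept.
#'
#' @param observations Data frame with columns `T_K`, `t_years`, `survival`
#'   (at least two distinct temperatures).
#' @return Object of class `arrhenius_fit`: `Ea_kJ_mol`, `lnA`, `r_squared`.
#' @export
arrhenius_fit <- function(observations) {
  stopifnot(all(c("T_K", "t_years", "survival") %in% names(observations)))
  if (length(unique(observations$T_K)) < 2L)
    stop("Arrhenius fit needs at least two distinct temperatures", call. = FALSE)
  k <- rate_from_survival(observations$survival, observations$t_years)
  if (any(k <= 0)) stop("non-positive rate: survival must be < 1", call. = FALSE)
  inv_T <- 1 / observations$T_K
  fit <- stats::lm(log(k) ~ inv_T)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((log(k) - mean(log(k)))^2)
  structure(list(Ea_kJ_mol = -coef(fit)[[2]] * GAS_CONSTANT / 1000,
                 lnA = coef(fit)[[1]],
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("<arrhenius_fit> Ea = %.2f kJ/mol, lnA = %.3f (per year), r^2 = %.4f\n",
              x$Ea_kJ_mol, x$lnA, x$r_squared))
  invisible(x)
}

#' Extrapolated half-life at a storage temperature
#'
#' `t_half = ln 2 / k(T)` with `k(T) = exp(lnA - Ea / (R T))`; increases
#' monotonically as the temperature drops.
#'
#' @param fit An [arrhenius_fit()] (or list with `Ea_kJ_mol` and `lnA`).
#' @param T_K Temperature in kelvin.
#' @return Half-life in years.
#' @export
half_life <- function(fit, T_K) {
  stopifnot(all(T_K > 0))
  k <- exp(fit$lnA - fit$Ea_kJ_mol * 1000 / (GAS_CONSTANT * T_K))
  log(2) / k
}

#' Simulate aging observations on the copy-number channel
#'
#' Convenience wrapper around [age_strands()]: exposes `n_copies` molecules
#' per condition to the first-order thermal channel and records the surviving
#' fraction, yielding a data frame that [arrhenius_fit()] accepts.
#'
#' @param Ea_kJ_mol,lnA_per_year Generating Arrhenius parameters.
#' @param T_K Vector of aging temperatures (K).
#' @param t_years Aging time per condition (recycled).
#' @param n_copies Copies per condition.
#' @param seed Integer seed.
#' @return Data frame with `T_K`, `t_years`, `survival`.
#' @export
simulate_aging_series <- function(Ea_kJ_mol, lnA_per_year, T_K, t_years,
                                  n_copies = 1e5, seed = NULL) {
  t_years <- rep_len(t_years, length(T_K))
  run <- function() {
    surv <- vapply(seq_along(T_K), function(i)
      age_strands(n_copies, Ea_kJ_mol, lnA_per_year, T_K[i], t_years[i]) /
        n_copies,
      numeric(1))
    data.frame(T_K = T_K, t_years = t_years, survival = surv)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
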
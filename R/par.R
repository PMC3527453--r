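#' Population attributable risk: Levin's formula
#'
#' `PAR = f (RR - 1) / (1 + f (RR - 1))`, the proportion of cases
#' attributable to a risk factor with prevalence `f` in the population (in
#' case-control data, prevalence among controls) and relative risk `RR`
#' (approximated by the odds ratio). Appropriate for crude relative risks.
#'
#' @param f exposure prevalence in the population, in `[0, 1]`.
#' @param rr relative risk, `> 0`.
#' @return PAR, vectorized over both arguments.
#' @examples
#' par_levin(315 / 1723, 3.21)  # about 0.29
#' @export
par_levin <- function(f, rr) {
  if (anyNA(f) || any(f < 0 | f > 1)) stop("f must lie in [0, 1]")
  if (anyNA(rr) || any(rr <= 0)) stop("rr must be > 0")
  f * (rr - 1) / (1 + f * (rr - 1))
}

#' Population attributable risk: case-based (Miettinen) formula
#'
#' `PAR = p_c (RR - 1) / RR` with `p_c` the exposure prevalence among
#' cases. Unlike Levin's formula this form remains valid when `RR` is a
#' confounder-adjusted relative risk, and is therefore the default for
#' PARs based on adjusted odds ratios.
#'
#' @param p_c exposure prevalence among cases, in `[0, 1]`.
#' @param rr (adjusted) relative risk, `> 0`.
#' @return PAR, vectorized.
#' @examples
#' par_case_based(0.5, 2)  # 0.25
#' @export
par_case_based <- function(p_c, rr) {
  if (anyNA(p_c) || any(p_c < 0 | p_c > 1)) stop("p_c must lie in [0, 1]")
  if (anyNA(rr) || any(rr <= 0)) stop("rr must be > 0")
  p_c * (rr - 1) / rr
}

#' Population attributable risk for a multi-level exposure
#'
#' Case-based PAR summed over the non-reference levels of a polytomous
#' exposure (e.g. heterozygous and homozygous genotypes against the
#' reference genotype): `PAR = sum_i p_c,i (RR_i - 1) / RR_i`.
#'
#' @param p_c_by_level case prevalences of the non-reference levels.
#' @param rr_by_level matching (adjusted) relative risks.
#' @return PAR.
#' @examples
#' par_multilevel(c(0.3, 0.2), c(2, 1.5))  # 0.15 + 0.0667
#' @export
par_multilevel <- function(p_c_by_level, rr_by_level) {
  if (length(p_c_by_level) != length(rr_by_level))
    stop("level vectors must have equal length")
  sum(par_case_based(p_c_by_level, rr_by_level))
}

#' Combined PAR of independent risk factors
#'
#' `PAR = 1 - prod_i (1 - PAR_i)`: the fraction of cases attributable to
#' at least one of several independent risk factors. Symmetric, monotone
#' in each argument and bounded by 1; an empty list gives 0.
#'
#' @param pars vector of individual PARs, each in `[0, 1)`.
#' @return Combined PAR.
#' @examples
#' combined_par(c(0.3, 0.3))  # 0.51
#' @export
combined_par <- function(pars) {
  if (length(pars) == 0L) return(0)
  if (anyNA(pars) || any(pars < 0 | pars >= 1))
    stop("each PAR must lie in [0, 1)")
  1 - prod(1 - pars)
}

#' Relative risk required for a target PAR at a given exposure frequency
#'
#' Exact inverse of [par_levin()]: `RR = 1 + PAR / (f (1 - PAR))`. Used to
#' ask how strong a risk factor of frequency `f` must be to account for a
#' given attributable fraction - e.g. a PAR of 30% requires RR 5.3 at
#' 10% frequency but only 2.1 at 40%, with the curve bottoming out at
#' `1 + PAR/(1 - PAR)` (1.43 for PAR 30%) as the factor approaches being
#' present in the entire population.
#'
#' @param par target attributable fraction, in `[0, 1)`.
#' @param f risk-factor frequency in the population, in `(0, 1]`
#'   (`f = 0` is only admissible for `par = 0`).
#' @return Relative risk, vectorized.
#' @examples
#' rr_given_par(0.30, 0.10)  # 5.3
#' rr_given_par(0.30, 1.0)   # 1.43
#' @export
rr_given_par <- function(par, f) {
  if (anyNA(par) || any(par < 0 | par >= 1))
    stop("par must lie in [0, 1)")
  if (anyNA(f) || any(f < 0 | f > 1)) stop("f must lie in [0, 1]")
  bad <- f == 0 & par > 0
  if (any(bad)) stop("par > 0 is unattainable at frequency f = 0")
  out <- 1 + par / (f * (1 - par))
  out[par == 0] <- 1
  out
}

#' PAR curve: required relative risk across exposure frequencies
#'
#' Evaluates [rr_given_par()] on a frequency grid, producing the curve of
#' the relative risk needed to sustain a fixed attributable fraction.
#'
#' @param par target PAR.
#' @param f frequency grid in `(0, 1]`.
#' @return data.frame with columns `f` and `rr`.
#' @export
par_curve <- function(par, f = seq(0.01, 1, by = 0.01)) {
  data.frame(f = f, rr = rr_given_par(par, f))
}
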
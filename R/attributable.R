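#' Population attributable risk of a single risk allele
#'
#' `PAR = p (OR - 1) / (p (OR - 1) + 1)` with `p` the risk-allele prevalence
#' in controls (the population proxy) and `OR` the per-allele odds ratio.
#' An OR of exactly 1 gives PAR 0; an OR below 1 returns a negative PAR
#' with a warning (protective allele).
#'
#' @param p Risk-allele frequency in controls, in (0, 1).
#' @param or_per_allele Per-allele odds ratio (> 0).
#' @return PAR, a single number below 1.
#' @examples
#' par_locus(0.36, 1.43)
#' @export
par_locus <- function(p, or_per_allele) {
  if (!(p > 0 && p < 1)) stop("p must be in (0,1)", call. = FALSE)
  if (or_per_allele <= 0) stop("or_per_allele must be positive",
                               call. = FALSE)
  if (or_per_allele < 1)
    warning("odds ratio below 1: returning a negative PAR ",
            "(protective allele)", call. = FALSE)
  x <- p * (or_per_allele - 1)
  x / (x + 1)
}

#' Combined population attributable risk of several independent loci
#'
#' Multiplicative combination `1 - prod(1 - PAR_k)` under independence of
#' loci. Per-locus PARs are returned alongside so the additive convention
#' remains auditable.
#'
#' @param p Vector of control risk-allele frequencies.
#' @param or_per_allele Vector of per-allele odds ratios (same length).
#' @return A list: `par_combined`, `par_each`.
#' @examples
#' par_combined(c(0.36, 0.77), c(1.43, 1.32))  # about 0.305, the "~30%"
#' @export
par_combined <- function(p, or_per_allele) {
  if (length(p) == 0) stop("need at least one locus", call. = FALSE)
  if (length(p) != length(or_per_allele))
    stop("'p' and 'or_per_allele' must have the same length", call. = FALSE)
  pars <- mapply(par_locus, p, or_per_allele)
  list(par_combined = 1 - prod(1 - pars), par_each = unname(pars))
}

#' Familial relative risk attributable to a heritable exposure
#'
#' Liability-threshold formalization of how much familial disease clustering
#' an inherited behavioural exposure generates on its own. Exposure
#' (e.g. persistent smoking) is the exceedance of a standard-normal
#' liability over the threshold set by its prevalence; liabilities of two
#' relatives are bivariate normal with correlation
#' `r = relatedness * h2` (additive polygenes, `relatedness` 0.5 for
#' first-degree pairs). Disease risk is `b * rr_exposed` if exposed and `b`
#' otherwise; the familial relative risk
#' `E[risk_1 * risk_2] / E[risk]^2` is independent of the baseline `b`.
#' The joint exposure probability is computed by adaptive quadrature of the
#' bivariate-normal orthant.
#'
#' @param h2 Heritability of the exposure liability, in \[0, 1\].
#' @param prevalence Exposure prevalence, in (0, 1).
#' @param rr_exposed Disease relative risk in the exposed (> 0).
#' @param relatedness Additive kinship coefficient (default 0.5,
#'   first-degree relatives).
#' @return A list: `frr`, the familial relative risk; `joint` with the
#'   orthant probabilities `p11`, `p10`, `p00`; `liability_correlation`.
#' @examples
#' familial_rr_exposure(h2 = 0.6, prevalence = 0.25, rr_exposed = 30)
#' @export
familial_rr_exposure <- function(h2, prevalence, rr_exposed,
                                 relatedness = 0.5) {
  if (!(h2 >= 0 && h2 <= 1)) stop("h2 must be in [0,1]", call. = FALSE)
  if (!(prevalence > 0 && prevalence < 1))
    stop("prevalence must be strictly between 0 and 1", call. = FALSE)
  if (rr_exposed <= 0) stop("rr_exposed must be positive", call. = FALSE)
  if (!(relatedness >= 0 && relatedness <= 1))
    stop("relatedness must be in [0,1]", call. = FALSE)
  r <- relatedness * h2
  t <- stats::qnorm(1 - prevalence)
  p11 <- bvn_upper_orthant(t, r)
  p10 <- prevalence - p11          # one exposed, one not (per ordering)
  p00 <- 1 - 2 * prevalence + p11
  num <- p11 * rr_exposed^2 + 2 * p10 * rr_exposed + p00
  den <- (prevalence * rr_exposed + (1 - prevalence))^2
  list(frr = num / den,
       joint = c(p11 = p11, p10 = p10, p00 = p00),
       liability_correlation = r)
}

# P(X > t, Y > t) for standard bivariate normal with correlation rho,
# by conditioning: integrate phi(x) * P(Y > t | X = x) over x > t.
bvn_upper_orthant <- function(t, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(t, lower.tail = FALSE)^2)
  if (rho > 1 - 1e-12) return(stats::pnorm(t, lower.tail = FALSE))
  s <- sqrt(1 - rho^2)
  stats::integrate(function(x)
    stats::dnorm(x) * stats::pnorm((rho * x - t) / s),
    lower = t, upper = Inf, rel.tol = 1e-10)$value
}
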
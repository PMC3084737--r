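#' Crude genotype odds ratio from a 2x2 sub-table
#'
#' Odds ratio for one genotype against a reference genotype, with a Woolf
#' (log-OR Wald) 95% confidence interval and a two-sided Wald p-value. This
#' is the "crude OR" convention of stratified case-control tables: cell
#' arithmetic only, no model.
#'
#' @param table A [genotype_table()].
#' @param dosage Dosage (0/1/2) of the genotype of interest.
#' @param reference_dosage Dosage of the reference genotype.
#' @param continuity If `TRUE`, a zero cell triggers the Haldane correction
#'   (0.5 added to all four cells) instead of an error; the result is then
#'   flagged `corrected`.
#' @param conf_level Confidence level (default 0.95).
#' @return An `or_result`: `estimate`, `ci_low`, `ci_high`, `se_log`,
#'   `p_value`, `n_used`, `corrected`.
#' @examples
#' gt <- genotype_table("rs12914385", c(1230, 1973, 815), c(373, 413, 121))
#' crude_genotype_or(gt, dosage = 2, reference_dosage = 0)  # OR 2.04
#' @export
crude_genotype_or <- function(table, dosage, reference_dosage,
                              continuity = FALSE, conf_level = 0.95) {
  stopifnot(inherits(table, "genotype_table"))
  if (!dosage %in% 0:2 || !reference_dosage %in% 0:2)
    stop("dosages must be 0, 1 or 2", call. = FALSE)
  if (dosage == reference_dosage)
    stop("'dosage' and 'reference_dosage' must differ", call. = FALSE)
  a <- table$cases[dosage + 1]      # exposed cases
  b <- table$controls[dosage + 1]   # exposed controls
  c_ <- table$cases[reference_dosage + 1]
  d <- table$controls[reference_dosage + 1]
  cells <- c(a, b, c_, d)
  corrected <- FALSE
  if (any(cells == 0)) {
    if (!continuity)
      stop("zero cell in 2x2 sub-table; set continuity = TRUE for the ",
           "Haldane 0.5 correction", call. = FALSE)
    cells <- cells + 0.5
    corrected <- TRUE
  }
  a <- cells[1]; b <- cells[2]; c_ <- cells[3]; d <- cells[4]
  log_or <- log(a * d) - log(b * c_)
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  new_or_result(
    estimate = exp(log_or),
    ci_low = exp(log_or - z * se), ci_high = exp(log_or + z * se),
    se_log = se,
    p_value = 2 * stats::pnorm(-abs(log_or / se)),
    n_used = sum(table$cases[c(dosage, reference_dosage) + 1],
                 table$controls[c(dosage, reference_dosage) + 1]),
    corrected = corrected)
}

new_or_result <- function(estimate, ci_low, ci_high, se_log, p_value, n_used,
                          corrected = FALSE, ...) {
  structure(list(estimate = unname(estimate), ci_low = unname(ci_low),
                 ci_high = unname(ci_high), se_log = unname(se_log),
                 p_value = unname(p_value), n_used = n_used,
                 corrected = corrected, ...),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR %.3f (95%% CI %.3f-%.3f), p = %.3g, n = %d%s\n",
              x$estimate, x$ci_low, x$ci_high, x$p_value, x$n_used,
              if (isTRUE(x$corrected)) " [continuity-corrected]" else ""))
  if (!is.null(x$direction_consistent) && !x$direction_consistent)
    cat("warning: per-allele direction disagrees with the genotype ORs\n")
  invisible(x)
}

#' Per-allele odds ratio by additive logistic regression on grouped counts
#'
#' Fits `logit P(case | g) = alpha + beta g` by maximum likelihood to the
#' grouped genotype counts (binomial IRLS, log-likelihood tolerance 1e-10,
#' at most 100 iterations) and reports `exp(beta)` with a Wald confidence
#' interval and two-sided p-value. Complete separation (all cases or all
#' controls confined to one dosage extreme) raises an explicit error rather
#' than returning a divergent estimate.
#'
#' The result carries `direction_consistent = FALSE` when the per-allele OR
#' and the crude homozygote OR point to opposite sides of 1 — a published
#' per-allele OR that is the reciprocal of the allelic OR computable from
#' its own counts is a real failure mode this flag is meant to surface.
#'
#' @inheritParams crude_genotype_or
#' @return An `or_result` with additional fields `beta` (log OR) and
#'   `direction_consistent`.
#' @examples
#' gt <- genotype_table("rs12914385", c(1230, 1973, 815), c(373, 413, 121))
#' per_allele_or(gt)  # OR 1.43
#' @export
per_allele_or <- function(table, conf_level = 0.95) {
  stopifnot(inherits(table, "genotype_table"))
  tot <- table$cases + table$controls
  if (sum(tot > 0) < 2)
    stop("need at least two occupied dosage groups", call. = FALSE)
  occ <- tot > 0
  if (all(table$cases[occ] == 0) || all(table$controls[occ] == 0))
    stop("need both cases and controls", call. = FALSE)
  # complete separation: among occupied dosages, cases and controls do not
  # overlap in dosage support
  case_d <- which(table$cases > 0) - 1
  ctrl_d <- which(table$controls > 0) - 1
  if (max(case_d) < min(ctrl_d) || max(ctrl_d) < min(case_d))
    stop("complete separation: cases and controls occupy disjoint dosage ",
         "ranges; the per-allele MLE does not exist", call. = FALSE)
  g <- (0:2)[occ]
  fit <- stats::glm(cbind(table$cases[occ], table$controls[occ]) ~ g,
                    family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 100))
  if (!fit$converged)
    stop("per-allele logistic fit did not converge", call. = FALSE)
  beta <- unname(stats::coef(fit)[2])
  se <- sqrt(stats::vcov(fit)[2, 2])
  if (!is.finite(beta) || !is.finite(se) || se > 50)
    stop("per-allele logistic fit is degenerate (quasi-separation)",
         call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  dir_ok <- TRUE
  if (all(tot > 0) && table$cases[1] > 0 && table$controls[1] > 0 &&
      table$cases[3] > 0 && table$controls[3] > 0) {
    hom <- crude_genotype_or(table, 2, 0)
    if ((hom$estimate - 1) * (exp(beta) - 1) < 0 &&
        abs(beta) > 1e-8) dir_ok <- FALSE
  }
  new_or_result(
    estimate = exp(beta),
    ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
    se_log = se,
    p_value = 2 * stats::pnorm(-abs(beta / se)),
    n_used = sum(tot),
    beta = beta, direction_consistent = dir_ok)
}

#' Cochran-Armitage trend test on a genotype count table
#'
#' One-degree-of-freedom chi-squared test for a linear trend in the case
#' proportion across ordered dosage groups, with the variance computed under
#' the null conditional on the table margins. Two-sided p-value from the
#' chi-squared tail.
#'
#' @param table A [genotype_table()].
#' @param weights Numeric scores for the three dosage groups
#'   (default `c(0, 1, 2)`, the additive coding).
#' @return A `trend_result`: `statistic`, `df`, `p_value`, `direction`
#'   (sign of the observed trend).
#' @export
cochran_armitage_trend <- function(table, weights = c(0, 1, 2)) {
  stopifnot(inherits(table, "genotype_table"))
  if (length(weights) != 3L || length(unique(weights)) == 1L)
    stop("'weights' must be three scores, not all equal", call. = FALSE)
  r <- table$cases; s <- table$controls
  n <- r + s
  N <- sum(n); R <- sum(r)
  if (R == 0 || R == N)
    stop("degenerate margins: all subjects have the same status",
         call. = FALSE)
  w <- weights
  # score-test statistic conditional on margins
  t_obs <- sum(w * r) - R * sum(w * n) / N
  v <- R * (N - R) / N * (sum(w^2 * n) / N - (sum(w * n) / N)^2) * N / (N - 1)
  if (v <= 0) {
    stat <- 0
  } else {
    stat <- t_obs^2 / v
  }
  new_trend_result(statistic = stat, df = 1L,
                   p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
                   direction = sign(t_obs))
}

new_trend_result <- function(statistic, df, p_value, direction = NA_real_,
                             ...) {
  structure(list(statistic = unname(statistic), df = df,
                 p_value = unname(min(1, p_value)),
                 direction = unname(direction), ...),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("chi-squared = %.4f, df = %d, p = %.3g", x$statistic, x$df,
              x$p_value))
  if (!is.na(x$direction) && x$direction != 0)
    cat(sprintf(" (direction %s)", if (x$direction > 0) "+" else "-"))
  cat("\n")
  invisible(x)
}

#' Hardy-Weinberg equilibrium chi-squared test
#'
#' One-degree-of-freedom goodness-of-fit chi-squared comparing observed
#' genotype counts at dosage 0/1/2 to the p^2, 2pq, q^2 expectation, with the
#' allele frequency estimated from the same sample. A monomorphic sample is
#' returned as chi-squared 0 with `monomorphic = TRUE` rather than an error.
#'
#' @param counts Integer vector of length 3: genotype counts at dosage 0,1,2
#'   (conventionally the control group).
#' @return A `trend_result` with extra field `monomorphic`.
#' @export
hwe_chi2 <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 3L || anyNA(counts) || any(counts < 0))
    stop("'counts' must be three non-negative genotype counts", call. = FALSE)
  n <- sum(counts)
  if (n <= 0) stop("empty sample", call. = FALSE)
  q <- (counts[2] + 2 * counts[3]) / (2 * n)   # dosage-counted allele
  if (q == 0 || q == 1)
    return(new_trend_result(statistic = 0, df = 1L, p_value = 1,
                            monomorphic = TRUE))
  p <- 1 - q
  expected <- n * c(p^2, 2 * p * q, q^2)
  stat <- sum((counts - expected)^2 / expected)
  new_trend_result(statistic = stat, df = 1L,
                   p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
                   monomorphic = FALSE)
}

#' Covariate-adjusted per-allele odds ratio from individual records
#'
#' Multivariable logistic regression of case status on risk-allele dosage
#' (additive) plus named covariates, by maximum likelihood. Cigarettes per
#' day, when requested via the covariate name `"cpd"`, is entered as the
#' conventional four categories (0-10 reference, 11-20, 21-30, 31+) rather
#' than as a linear term. Records with missing values in any used column are
#' dropped listwise and counted in `n_dropped`.
#'
#' @param records A data frame of individual records (see [read_records()]):
#'   must contain `status` (case/control) and `dosage`, plus the covariates.
#' @param covariates Character vector of covariate column names; `"cpd"`
#'   triggers categorical coding, all other columns enter as given
#'   (factors for character columns).
#' @param conf_level Confidence level.
#' @return An `or_result` for the per-allele dosage term, with `beta` and
#'   `n_dropped`.
#' @export
adjusted_logistic <- function(records, covariates = c("age", "sex", "cpd"),
                              conf_level = 0.95) {
  records <- as.data.frame(records)
  needed <- c("status", "dosage", covariates)
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("records are missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- records[needed]
  keep <- stats::complete.cases(df)
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < 10)
    stop("too few complete records for an adjusted model", call. = FALSE)
  y <- tolower(as.character(df$status)) == "case"
  if (all(y) || !any(y)) stop("need both cases and controls", call. = FALSE)
  if (length(unique(df$dosage)) < 2)
    stop("dosage is constant: per-allele effect is not identifiable",
         call. = FALSE)
  X <- data.frame(dosage = as.numeric(df$dosage))
  for (cv in covariates) {
    if (cv == "cpd") {
      X$cpd_cat <- cut(as.numeric(df$cpd), breaks = c(-Inf, 10, 20, 30, Inf),
                       labels = c("0-10", "11-20", "21-30", "31+"))
    } else {
      v <- df[[cv]]
      X[[cv]] <- if (is.character(v) || is.logical(v)) factor(v)
                 else as.numeric(v)
    }
  }
  mm <- stats::model.matrix(~ ., X)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    bad <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop("singular design matrix; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::glm.fit(mm, y, family = stats::binomial(),
                        control = stats::glm.control(epsilon = 1e-10,
                                                     maxit = 100))
  if (!fit$converged)
    stop("adjusted logistic fit did not converge", call. = FALSE)
  # Wald from the unscaled covariance of the IRLS fit
  w <- fit$weights
  xtwx <- crossprod(mm * sqrt(w))
  vc <- solve(xtwx)
  beta <- fit$coefficients["dosage"]
  se <- sqrt(vc["dosage", "dosage"])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  new_or_result(
    estimate = exp(beta),
    ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
    se_log = se, p_value = 2 * stats::pnorm(-abs(beta / se)),
    n_used = nrow(df), beta = unname(beta), n_dropped = n_dropped)
}

#' Analytic power of the per-allele trend test
#'
#' Power of the 1-df allelic trend test by a non-central chi-squared
#' approximation: the non-centrality parameter is the squared expected
#' allelic log odds ratio over its variance under the alternative, with the
#' case allele frequency implied by the control frequency and the per-allele
#' odds ratio.
#'
#' @param n_cases,n_controls Group sizes (subjects, not alleles).
#' @param raf Risk-allele frequency in controls, in (0, 1).
#' @param or_alt Per-allele odds ratio under the alternative.
#' @param alpha Two-sided significance level, in (0, 1).
#' @return Power, a single number in \[0, 1\].
#' @examples
#' study_power(241, 553, raf = 0.37, or_alt = 1.3)
#' @export
study_power <- function(n_cases, n_controls, raf, or_alt, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)
  if (n_cases <= 0 || n_controls <= 0)
    stop("group sizes must be positive", call. = FALSE)
  if (!(raf > 0 && raf < 1)) stop("raf must be in (0,1)", call. = FALSE)
  if (or_alt <= 0) stop("or_alt must be positive", call. = FALSE)
  p0 <- raf
  p1 <- p0 * or_alt / (1 - p0 + p0 * or_alt)
  v <- 1 / (2 * n_cases * p1) + 1 / (2 * n_cases * (1 - p1)) +
       1 / (2 * n_controls * p0) + 1 / (2 * n_controls * (1 - p0))
  ncp <- log(or_alt)^2 / v
  crit <- stats::qchisq(1 - alpha, df = 1)
  stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
}
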
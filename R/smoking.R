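#' Kruskal-Wallis test of an exposure across genotype groups
#'
#' Rank-based k-sample test (mid-ranks, standard tie correction) of, for
#' example, cigarettes-per-day distributions across dosage groups. A
#' degenerate input in which every pooled value is identical is returned as
#' H = 0, p = 1 with `degenerate = TRUE`.
#'
#' @param groups A list of two or more numeric vectors, one per group.
#' @return A `trend_result` with `statistic` (H), `df` = k - 1, `p_value`,
#'   and `degenerate`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups)) stop("'groups' must be a list", call. = FALSE)
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  groups <- groups[vapply(groups, length, 1L) > 0]
  if (length(groups) < 2)
    stop("need at least two non-empty groups", call. = FALSE)
  pooled <- unlist(groups)
  if (length(unique(pooled)) == 1L)
    return(new_trend_result(statistic = 0, df = length(groups) - 1L,
                            p_value = 1, degenerate = TRUE))
  kt <- stats::kruskal.test(pooled,
                            g = factor(rep(seq_along(groups),
                                           vapply(groups, length, 1L))))
  new_trend_result(statistic = unname(kt$statistic),
                   df = unname(kt$parameter),
                   p_value = kt$p.value, degenerate = FALSE)
}

#' Per-allele effect of genotype on cigarettes per day
#'
#' Linear trend of (optionally log-transformed) CPD on risk-allele dosage
#' among smokers, by least squares. On the log scale the slope is
#' back-transformed to a CPD difference evaluated at the analysed sample's
#' mean CPD, so effects are reported in cigarettes per day either way.
#'
#' @param records Individual-record data frame; only rows with
#'   `smoking_status` of `"current"` or `"former"` and non-missing `cpd`
#'   enter the fit.
#' @param log_scale Analyse `log(cpd)` (default `TRUE`); zero CPD among
#'   smokers is shifted by 0.5 before logging.
#' @return A list: `slope_cpd` (CPD per risk allele, back-transformed if
#'   log scale), `slope_raw` (the fitted slope on the analysis scale),
#'   `se`, `p_value`, `n_used`, `log_scale`, `mean_cpd`.
#' @export
per_allele_cpd_effect <- function(records, log_scale = TRUE) {
  df <- smokers_with_cpd(records)
  if (length(unique(df$dosage)) < 2)
    stop("need at least two dosage groups among smokers with CPD",
         call. = FALSE)
  y <- if (log_scale) log(ifelse(df$cpd == 0, 0.5, df$cpd)) else df$cpd
  fit <- stats::lm(y ~ dosage, data = transform(df, dosage =
                                                  as.numeric(dosage)))
  sm <- summary(fit)$coefficients
  slope <- sm["dosage", "Estimate"]
  m <- mean(df$cpd)
  list(slope_cpd = if (log_scale) m * (exp(slope) - 1) else slope,
       slope_raw = unname(slope),
       se = unname(sm["dosage", "Std. Error"]),
       p_value = unname(sm["dosage", "Pr(>|t|)"]),
       n_used = nrow(df), log_scale = log_scale, mean_cpd = m)
}

smokers_with_cpd <- function(records) {
  records <- as.data.frame(records)
  needed <- c("dosage", "smoking_status", "cpd")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("records are missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  sm <- tolower(as.character(records$smoking_status)) %in%
    c("current", "former")
  df <- records[sm & !is.na(records$cpd), , drop = FALSE]
  if (nrow(df) == 0) stop("no smokers with CPD data", call. = FALSE)
  df
}

#' Risk-allele prevalence in light versus heavy smokers
#'
#' Dichotomizes smokers at a CPD threshold (light = 1 to threshold, heavy =
#' above threshold), reports the risk-allele frequency in each stratum, and
#' tests genotype for trend across the light/heavy contrast with the
#' Cochran-Armitage statistic (heavy playing the role of "case").
#'
#' @param records Individual-record data frame (smokers with CPD analysed).
#' @param threshold CPD cut point; default 20, so heavy means 21+.
#' @return A list: `raf_light`, `raf_heavy`, `n_light`, `n_heavy`, `trend`
#'   (a `trend_result`).
#' @export
heavy_smoking_trend <- function(records, threshold = 20) {
  df <- smokers_with_cpd(records)
  heavy <- df$cpd > threshold
  if (!any(heavy) || all(heavy))
    stop("threshold ", threshold, " leaves an empty light or heavy stratum",
         call. = FALSE)
  counts <- function(sub) tabulate(sub$dosage + 1L, nbins = 3L)
  n_h <- counts(df[heavy, ]); n_l <- counts(df[!heavy, ])
  raf <- function(n) (n[2] + 2 * n[3]) / (2 * sum(n))
  gt <- genotype_table("heavy-vs-light", cases = n_h, controls = n_l,
                       stratum = sprintf("CPD > %g vs 1-%g", threshold,
                                         threshold))
  list(raf_light = raf(n_l), raf_heavy = raf(n_h),
       n_light = sum(n_l), n_heavy = sum(n_h),
       trend = cochran_armitage_trend(gt))
}

#' Trend in a quantitative response across genotype groups
#'
#' One-degree-of-freedom linear trend test of a numeric response (age of
#' onset, age at initiation, smoking duration, ...) on risk-allele dosage,
#' optionally adjusted for covariates by including them in the linear model.
#' A constant response is returned as statistic 0, p = 1.
#'
#' @param records Individual-record data frame.
#' @param response Name of the numeric response column.
#' @param adjust Optional character vector of covariate column names.
#' @param subset Optional logical vector selecting rows before listwise
#'   deletion.
#' @return A list: `slope` (response units per allele), `se`, `p_value`,
#'   `means` (per-genotype means), `n_used`.
#' @export
mean_trend_by_genotype <- function(records, response, adjust = NULL,
                                   subset = NULL) {
  records <- as.data.frame(records)
  needed <- c("dosage", response, adjust)
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("records are missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!is.null(subset)) records <- records[subset, , drop = FALSE]
  df <- records[needed]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < 3) stop("too few complete records", call. = FALSE)
  y <- as.numeric(df[[response]])
  means <- tapply(y, factor(df$dosage, levels = 0:2), mean)
  if (length(unique(y)) == 1L)
    return(list(slope = 0, se = NA_real_, p_value = 1, means = means,
                n_used = nrow(df)))
  df$dosage <- as.numeric(df$dosage)
  for (cv in adjust) {
    v <- df[[cv]]
    if (is.character(v) || is.logical(v)) df[[cv]] <- factor(v)
  }
  fml <- stats::reformulate(c("dosage", adjust),
                            response = sprintf("`%s`", response))
  fit <- stats::lm(fml, data = df)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["dosage", "Estimate"]),
       se = unname(sm["dosage", "Std. Error"]),
       p_value = unname(sm["dosage", "Pr(>|t|)"]),
       means = means, n_used = nrow(df))
}

#' Box-Cox power-transformation parameter by profile likelihood
#'
#' Maximizes the Box-Cox profile log-likelihood over lambda in \[-2, 2\]
#' by golden-section search (tolerance 1e-4) and returns the transformed
#' values `(y^lambda - 1)/lambda` (natural log at lambda = 0).
#'
#' @param values Strictly positive numeric vector.
#' @param interval Search interval for lambda.
#' @return A list: `lambda`, `transformed`, `loglik` (profile log-likelihood
#'   at the optimum).
#' @export
boxcox_lambda <- function(values, interval = c(-2, 2)) {
  y <- as.numeric(values[!is.na(values)])
  if (length(y) < 3) stop("need at least 3 values", call. = FALSE)
  if (any(y <= 0))
    stop("Box-Cox requires strictly positive values; add a shift constant ",
         "before transforming", call. = FALSE)
  ll <- function(lam) boxcox_loglik(y, lam)
  opt <- stats::optimize(ll, interval = interval, maximum = TRUE,
                         tol = 1e-4)
  lam <- opt$maximum
  list(lambda = lam, transformed = boxcox_transform(y, lam),
       loglik = opt$objective)
}

boxcox_transform <- function(y, lambda) {
  if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
}

boxcox_loglik <- function(y, lambda) {
  n <- length(y)
  z <- boxcox_transform(y, lambda)
  -n / 2 * log(sum((z - mean(z))^2) / n) + (lambda - 1) * sum(log(y))
}
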
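#' A single study's contribution to a meta-analysis
#'
#' Either allelic 2x2 counts (risk vs non-risk allele, cases vs controls) or
#' a ready-made log odds ratio with its standard error. Counts are reduced
#' to `log_or`/`se` by [summarize_study()].
#'
#' @param label Study label.
#' @param log_or,se Log odds ratio and its standard error (`se > 0`), if the
#'   study is supplied on the effect scale.
#' @param cases_risk,cases_nonrisk,controls_risk,controls_nonrisk Allele
#'   counts, if the study is supplied as raw genotype/allele frequencies.
#' @param ancestry Free-text ancestry tag; sub-populations of one
#'   publication are separate studies.
#' @return An object of class `study_summary`.
#' @export
study_summary <- function(label, log_or = NULL, se = NULL,
                          cases_risk = NULL, cases_nonrisk = NULL,
                          controls_risk = NULL, controls_nonrisk = NULL,
                          ancestry = NA_character_) {
  has_effect <- !is.null(log_or) && !is.null(se)
  has_counts <- !is.null(cases_risk)
  if (!has_effect && !has_counts)
    stop("supply either (log_or, se) or allele counts", call. = FALSE)
  if (has_effect && (!is.finite(se) || se <= 0))
    stop("'se' must be a positive number", call. = FALSE)
  if (has_counts) {
    counts <- c(cases_risk, cases_nonrisk, controls_risk, controls_nonrisk)
    if (length(counts) != 4L || anyNA(counts) || any(counts < 0))
      stop("allele counts must be four non-negative numbers", call. = FALSE)
  }
  structure(list(label = as.character(label),
                 log_or = if (has_effect) log_or else NULL,
                 se = if (has_effect) se else NULL,
                 counts = if (has_counts)
                   c(cases_risk = cases_risk, cases_nonrisk = cases_nonrisk,
                     controls_risk = controls_risk,
                     controls_nonrisk = controls_nonrisk) else NULL,
                 ancestry = ancestry),
            class = "study_summary")
}

#' Study-specific allelic log odds ratio and standard error
#'
#' From allele counts: the allelic 2x2 log OR with Woolf standard error
#' `sqrt(sum(1/cell))`; any zero cell triggers the Haldane 0.5 correction
#' with a `corrected` flag. A study already supplied on the effect scale is
#' passed through unchanged.
#'
#' @param study A [study_summary()].
#' @return A list: `label`, `log_or`, `se`, `corrected`.
#' @export
summarize_study <- function(study) {
  stopifnot(inherits(study, "study_summary"))
  if (!is.null(study$log_or))
    return(list(label = study$label, log_or = study$log_or, se = study$se,
                corrected = FALSE))
  cells <- study$counts
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  list(label = study$label,
       log_or = log(cells[["cases_risk"]] * cells[["controls_nonrisk"]]) -
         log(cells[["cases_nonrisk"]] * cells[["controls_risk"]]),
       se = sqrt(sum(1 / cells)), corrected = corrected)
}

#' Convert a genotype count table to an allelic meta-analysis study
#'
#' Counts risk and non-risk alleles per group (het contributes one of each,
#' homozygote two) and wraps them as a [study_summary()].
#'
#' @param table A [genotype_table()].
#' @param ancestry Optional ancestry tag.
#' @return A `study_summary` with allele counts.
#' @export
as_study_summary <- function(table, ancestry = NA_character_) {
  stopifnot(inherits(table, "genotype_table"))
  risk <- function(n) n[2] + 2 * n[3]
  nonrisk <- function(n) n[2] + 2 * n[1]
  study_summary(paste(table$label, table$stratum, sep = ":"),
                cases_risk = risk(table$cases),
                cases_nonrisk = nonrisk(table$cases),
                controls_risk = risk(table$controls),
                controls_nonrisk = nonrisk(table$controls),
                ancestry = ancestry)
}

study_effects <- function(studies) {
  if (inherits(studies, "study_summary")) studies <- list(studies)
  if (length(studies) == 0) stop("no studies supplied", call. = FALSE)
  eff <- lapply(studies, summarize_study)
  list(label = vapply(eff, `[[`, character(1), "label"),
       y = vapply(eff, function(e) unname(e$log_or), numeric(1)),
       se = vapply(eff, function(e) unname(e$se), numeric(1)))
}

#' Fixed-effect (inverse-variance) pooling of study log odds ratios
#'
#' Weighted mean of log ORs with weights `1/se^2`; Wald confidence interval
#' and two-sided Z p-value.
#'
#' @param studies A list of [study_summary()] objects.
#' @param conf_level Confidence level.
#' @return A `meta_result` with the fixed-effect fields populated.
#' @export
pool_fixed <- function(studies, conf_level = 0.95) {
  e <- study_effects(studies)
  w <- 1 / e$se^2
  y_f <- sum(w * e$y) / sum(w)
  se_f <- sqrt(1 / sum(w))
  new_meta_result(k = length(e$y),
                  fixed = pooled_block(y_f, se_f, conf_level),
                  studies = e)
}

pooled_block <- function(y, se, conf_level) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(log_or = y, se = se, or = exp(y),
       ci_low = exp(y - z * se), ci_high = exp(y + z * se),
       p_value = 2 * stats::pnorm(-abs(y / se)))
}

new_meta_result <- function(k, fixed = NULL, random = NULL, tau2 = NA_real_,
                            q = NA_real_, q_p = NA_real_, i2 = NA_real_,
                            studies = NULL) {
  structure(list(k = k, fixed = fixed, random = random, tau2 = tau2,
                 q = q, q_p = q_p, i2 = i2, studies = studies),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Meta-analysis of %d studies\n", x$k))
  fmt <- function(b, nm) if (!is.null(b))
    cat(sprintf("  %s: OR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
                nm, b$or, b$ci_low, b$ci_high, b$p_value))
  fmt(x$fixed, "fixed ")
  fmt(x$random, "random")
  if (!is.na(x$tau2))
    cat(sprintf("  tau^2 = %.4f, Q = %.3f (p = %.3g), I^2 = %.1f%%\n",
                x$tau2, x$q, x$q_p, 100 * x$i2))
  invisible(x)
}

#' DerSimonian-Laird random-effects pooling with heterogeneity statistics
#'
#' Cochran's `Q = sum w_i (y_i - y_fixed)^2` with fixed-effect weights;
#' method-of-moments between-study variance
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`; random-effects
#' weights `1/(se_i^2 + tau2)`; `I^2 = max(0, (Q - (k-1))/Q)`; Q p-value
#' from a chi-squared with k-1 degrees of freedom.
#'
#' @inheritParams pool_fixed
#' @return A `meta_result` with fixed, random and heterogeneity fields.
#' @export
pool_random_dl <- function(studies, conf_level = 0.95) {
  e <- study_effects(studies)
  k <- length(e$y)
  if (k < 2)
    stop("between-study variance needs at least two studies", call. = FALSE)
  w <- 1 / e$se^2
  y_f <- sum(w * e$y) / sum(w)
  q <- sum(w * (e$y - y_f)^2)
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (denom > 0) max(0, (q - (k - 1)) / denom) else 0
  wr <- 1 / (e$se^2 + tau2)
  y_r <- sum(wr * e$y) / sum(wr)
  se_r <- sqrt(1 / sum(wr))
  new_meta_result(
    k = k,
    fixed = pooled_block(y_f, sqrt(1 / sum(w)), conf_level),
    random = pooled_block(y_r, se_r, conf_level),
    tau2 = tau2, q = q,
    q_p = stats::pchisq(q, df = k - 1, lower.tail = FALSE),
    i2 = if (q > 0) max(0, (q - (k - 1)) / q) else 0,
    studies = e)
}

#' Egger regression test for funnel-plot asymmetry
#'
#' Inverse-variance weighted regression of the standardized effect
#' `y_i / se_i` on precision `1 / se_i`; the intercept estimates small-study
#' bias and is tested against zero with a t distribution on k - 2 degrees
#' of freedom.
#'
#' @param studies A list of [study_summary()] objects, at least three.
#' @return A list: `intercept`, `se`, `p_value`, `slope` (the
#'   bias-adjusted pooled log OR), `df`.
#' @export
egger_test <- function(studies) {
  e <- study_effects(studies)
  k <- length(e$y)
  if (k < 3) stop("Egger's test needs at least three studies", call. = FALSE)
  z <- e$y / e$se
  prec <- 1 / e$se
  if (stats::sd(prec) < 1e-10 * mean(prec)) {
    # identical precisions: the precision column is collinear with the
    # intercept, so the fit collapses to a one-sample t-test of the mean
    # standardized effect (df k - 1), flagged as degenerate
    tt <- stats::t.test(z)
    return(list(intercept = unname(tt$estimate), se = unname(tt$stderr),
                p_value = tt$p.value, slope = NA_real_,
                df = k - 1L, degenerate_equal_se = TRUE))
  }
  fit <- stats::lm(z ~ prec, weights = prec^2)
  sm <- summary(fit)$coefficients
  list(intercept = unname(sm[1, "Estimate"]),
       se = unname(sm[1, "Std. Error"]),
       p_value = unname(sm[1, "Pr(>|t|)"]),
       slope = unname(sm[2, "Estimate"]), df = k - 2L)
}

#' Leave-one-out sensitivity re-pooling
#'
#' Repeats [pool_random_dl()] k times, each excluding one study; useful for
#' spotting a single study driving heterogeneity.
#'
#' @inheritParams pool_fixed
#' @return A named list of `meta_result` objects (or, at k = 2, of
#'   single-study [pool_fixed()] results), one per omitted study.
#' @export
leave_one_out <- function(studies, conf_level = 0.95) {
  if (inherits(studies, "study_summary")) studies <- list(studies)
  k <- length(studies)
  if (k < 2) stop("need at least two studies", call. = FALSE)
  labels <- vapply(studies, `[[`, character(1), "label")
  out <- lapply(seq_len(k), function(i) {
    rest <- studies[-i]
    if (length(rest) >= 2) pool_random_dl(rest, conf_level)
    else pool_fixed(rest, conf_level)
  })
  names(out) <- paste("omit", labels)
  out
}

#' Funnel-plot data for a set of studies
#'
#' @inheritParams pool_fixed
#' @return A data frame with `label`, `log_or`, `se` — standard error
#'   against effect, ready for plotting or TSV export.
#' @export
funnel_data <- function(studies) {
  e <- study_effects(studies)
  data.frame(label = e$label, log_or = e$y, se = e$se,
             stringsAsFactors = FALSE)
}

#' Read a meta-analysis study table from TSV
#'
#' Accepts either the counts layout
#' `label ancestry cases_risk cases_nonrisk controls_risk controls_nonrisk`
#' or the effect layout `label log_or se` (an `ancestry` column is optional
#' in both).
#'
#' @param path Path to the TSV file.
#' @return A list of [study_summary()] objects.
#' @export
read_study_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("study table has no rows", call. = FALSE)
  anc <- if ("ancestry" %in% names(df)) df$ancestry else
    rep(NA_character_, nrow(df))
  if (all(c("cases_risk", "cases_nonrisk", "controls_risk",
            "controls_nonrisk") %in% names(df))) {
    lapply(seq_len(nrow(df)), function(i)
      study_summary(df$label[i], cases_risk = df$cases_risk[i],
                    cases_nonrisk = df$cases_nonrisk[i],
                    controls_risk = df$controls_risk[i],
                    controls_nonrisk = df$controls_nonrisk[i],
                    ancestry = anc[i]))
  } else if (all(c("log_or", "se") %in% names(df))) {
    lapply(seq_len(nrow(df)), function(i)
      study_summary(df$label[i], log_or = df$log_or[i], se = df$se[i],
                    ancestry = anc[i]))
  } else {
    stop("study table must carry either allele-count columns or ",
         "log_or/se columns", call. = FALSE)
  }
}
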
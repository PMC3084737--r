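test_that("crude ORs use Woolf intervals and behave under inversion", {
  gt <- strata_counts()[["rs12914385:smokers"]]
  r <- crude_genotype_or(gt, 2, 0)
  # hand arithmetic: (815*373)/(1230*121), exp(log OR +- 1.96 sqrt(sum 1/n))
  lo <- log(815 * 373 / (1230 * 121))
  se <- sqrt(1 / 815 + 1 / 373 + 1 / 1230 + 1 / 121)
  expect_equal(r$estimate, exp(lo), tolerance = 1e-12)
  expect_equal(r$ci_low, exp(lo - qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(r$se_log, se)
  expect_true(r$ci_low <= r$estimate && r$estimate <= r$ci_high)

  # swapping dosage and reference inverts the OR and swap-inverts the CI
  inv <- crude_genotype_or(gt, 0, 2)
  expect_equal(inv$estimate, 1 / r$estimate, tolerance = 1e-12)
  expect_equal(inv$ci_low, 1 / r$ci_high, tolerance = 1e-12)
  expect_equal(inv$ci_high, 1 / r$ci_low, tolerance = 1e-12)

  # identical case/control distributions: the null table
  null_t <- genotype_table("null", c(10, 10, 0), c(10, 10, 0))
  expect_equal(crude_genotype_or(null_t, 1, 0)$estimate, 1)
})

test_that("zero cells error unless the Haldane correction is requested", {
  gt <- genotype_table("z", c(5, 3, 0), c(4, 2, 1))
  expect_error(crude_genotype_or(gt, 2, 0), "zero cell")
  r <- crude_genotype_or(gt, 2, 0, continuity = TRUE)
  expect_true(r$corrected)
  expect_equal(r$estimate, (0.5 * 4.5) / (1.5 * 5.5), tolerance = 1e-12)
})

test_that("scaling all cells preserves the OR and shrinks the CI", {
  gt <- strata_counts()[["rs8042374:smokers"]]
  big <- genotype_table("x10", gt$cases * 10, gt$controls * 10)
  r1 <- crude_genotype_or(gt, 2, 0)
  r2 <- crude_genotype_or(big, 2, 0)
  expect_equal(r2$estimate, r1$estimate, tolerance = 1e-12)
  expect_lt(r2$ci_high - r2$ci_low, r1$ci_high - r1$ci_low)
  p1 <- per_allele_or(gt); p2 <- per_allele_or(big)
  expect_equal(p2$estimate, p1$estimate, tolerance = 1e-6)
})

test_that("per-allele OR is the additive-logistic MLE on grouped counts", {
  gt <- strata_counts()
  r <- per_allele_or(gt[["rs12914385:smokers"]])
  expect_equal(round(r$estimate, 2), 1.43)
  expect_equal(round(c(r$ci_low, r$ci_high), 2), c(1.29, 1.59))
  expect_equal(r$p_value, 2.10e-11, tolerance = 0.01)
  r2 <- per_allele_or(gt[["rs8042374:smokers"]])
  expect_equal(round(r2$estimate, 2), 1.32)
  expect_equal(round(c(r2$ci_low, r2$ci_high), 2), c(1.17, 1.50))

  # identical case fraction across dosages -> beta 0
  flat <- genotype_table("flat", c(30, 60, 10), c(60, 120, 20))
  expect_equal(per_allele_or(flat)$beta, 0, tolerance = 1e-8)

  # with only dosages 0 and 1 occupied the MLE equals the crude 2x2 OR
  two <- genotype_table("two", c(40, 25, 0), c(30, 35, 0))
  expect_equal(per_allele_or(two)$estimate,
               crude_genotype_or(two, 1, 0)$estimate, tolerance = 1e-6)
})

test_that("per-allele fit refuses complete separation and flags direction", {
  sep <- genotype_table("sep", c(0, 0, 50), c(50, 0, 0))
  expect_error(per_allele_or(sep), "separation")
  # a table whose per-allele trend opposes its homozygote OR cannot arise
  # from counts; direction consistency must hold on real tables
  ns <- per_allele_or(strata_counts()[["rs12914385:never-smokers"]])
  expect_true(ns$direction_consistent)
  expect_equal(round(ns$estimate, 2), 0.92)  # reciprocal of the quoted 1.09
})

test_that("trend test matches the exhaustive permutation distribution", {
  # identical distributions: exact null
  null_t <- genotype_table("null", c(5, 5, 5), c(5, 5, 5))
  r0 <- cochran_armitage_trend(null_t)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # 8-to-12-subject tables carrying a genuine trend signal; near the exact
  # null the chi-squared tail and any discrete permutation tail separate by
  # construction, so degenerate tables are checked above instead
  small_tables <- list(
    list(ca = c(3, 1, 0), co = c(0, 2, 3)),
    list(ca = c(4, 2, 0), co = c(0, 2, 4)),
    list(ca = c(3, 3, 0), co = c(1, 1, 4)),
    list(ca = c(4, 0, 1), co = c(1, 3, 2)))
  for (tb in small_tables) {
    gt <- genotype_table("toy", tb$ca, tb$co)
    p_asym <- cochran_armitage_trend(gt)$p_value
    p_exact <- perm_trend_p(tb$ca, tb$co)
    expect_lt(abs(p_asym - p_exact), 0.02)
  }
  # the 20-subject example also agrees with its permutation oracle
  gt20 <- genotype_table("toy20", c(4, 3, 3), c(3, 3, 4))
  expect_lt(abs(cochran_armitage_trend(gt20)$p_value -
                  perm_trend_p(c(4, 3, 3), c(3, 3, 4))), 0.02)
})

test_that("trend test agrees with the score-test cross-check at scale", {
  gt <- strata_counts()[["rs12914385:smokers"]]
  r <- cochran_armitage_trend(gt)
  ref <- prop.trend.test(gt$cases, gt$cases + gt$controls)
  # same statistic up to the finite-population factor N/(N-1)
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-3)
  expect_lt(r$p_value, 1e-10)
  expect_gt(r$p_value, 1e-12)
  expect_equal(r$direction, 1)
  expect_error(cochran_armitage_trend(gt, weights = c(1, 1, 1)),
               "not all equal")
  expect_error(
    cochran_armitage_trend(genotype_table("d", c(1, 1, 1), c(0, 0, 0))),
    "at least one")
})

test_that("HWE chi-squared matches the multinomial-expectation hand form", {
  # exactly at HW proportions
  r <- hwe_chi2(c(25, 50, 25))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # hand calculation for the smoker-stratum controls
  cnt <- c(373, 413, 121)
  q <- (413 + 2 * 121) / (2 * 907)
  e <- 907 * c((1 - q)^2, 2 * q * (1 - q), q^2)
  expect_equal(hwe_chi2(cnt)$statistic, sum((cnt - e)^2 / e),
               tolerance = 1e-12)
  expect_gt(hwe_chi2(cnt)$p_value, 0.05)   # controls satisfy HWE
  # gross violation
  expect_lt(hwe_chi2(c(50, 0, 50))$p_value, 1e-3)
  # invariance to allele relabelling (dosage reversal)
  expect_equal(hwe_chi2(c(373, 413, 121))$statistic,
               hwe_chi2(c(121, 413, 373))$statistic, tolerance = 1e-12)
  # monomorphic flag
  m <- hwe_chi2(c(100, 0, 0))
  expect_true(m$monomorphic)
  expect_equal(m$statistic, 0)
})

test_that("adjusted logistic recovers effects and rejects degenerate input", {
  cfg <- simulation_config(n_cases = 2500, n_controls = 2500,
                           direct_log_or_per_allele = 0.3,
                           beta_cpd_per_allele = 0,
                           beta_duration_per_allele = 0, seed = 42)
  rec <- simulate_cohort(cfg)
  fit <- adjusted_logistic(rec, covariates = c("age", "sex", "cpd"))
  expect_lt(abs(fit$beta - 0.3), 0.12)
  # with uninformative covariates, adjusted ~ crude per-allele
  crude <- per_allele_or(records_to_table(rec, stratum = "smokers"))
  fit_sm <- adjusted_logistic(rec[rec$smoking_status != "never", ],
                              covariates = c("age", "sex"))
  expect_lt(abs(fit_sm$beta - crude$beta), 0.06)

  rec0 <- rec; rec0$dosage <- 1
  expect_error(adjusted_logistic(rec0), "constant")
  rec2 <- rec; rec2$age2 <- rec2$age
  expect_error(adjusted_logistic(rec2, covariates = c("age", "age2")),
               "collinear")
})

test_that("analytic trend power agrees with a Monte-Carlo oracle", {
  expect_equal(study_power(500, 500, 0.3, 1.0, alpha = 0.05), 0.05,
               tolerance = 1e-10)
  # monotone in the number of cases
  pw <- vapply(c(100, 300, 900), study_power, numeric(1),
               n_controls = 553, raf = 0.37, or_alt = 1.3)
  expect_true(all(diff(pw) > 0))
  expect_error(study_power(100, 100, 0.3, 1.3, alpha = 1.2), "alpha")

  # empirical power at the never-smoker stratum sizes
  mc_power <- function(n_ca, n_co, raf, or, nsim) {
    f <- c((1 - raf)^2, 2 * raf * (1 - raf), raf^2)
    pg_case <- f * or^(0:2); pg_case <- pg_case / sum(pg_case)
    hits <- 0L
    for (i in seq_len(nsim)) {
      ca <- as.vector(rmultinom(1, n_ca, pg_case))
      co <- as.vector(rmultinom(1, n_co, f))
      p <- tryCatch(
        cochran_armitage_trend(genotype_table("s", ca, co))$p_value,
        error = function(e) 1)
      if (p < 0.05) hits <- hits + 1L
    }
    hits / nsim
  }
  set.seed(7)
  emp <- mc_power(241, 553, 0.37, 1.3, nsim = 3000)
  expect_equal(study_power(241, 553, 0.37, 1.3), emp, tolerance = 0.035)
})
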
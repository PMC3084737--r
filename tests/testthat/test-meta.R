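test_that("study effects reduce counts to Woolf log ORs", {
  # never-smoker allele counts, hand-counted from the genotype table
  ns <- strata_counts()[["rs12914385:never-smokers"]]
  st <- as_study_summary(ns)
  e <- summarize_study(st)
  expect_equal(e$log_or, log((169 * 694) / (309 * 412)), tolerance = 1e-12)
  expect_equal(e$se, sqrt(1 / 169 + 1 / 309 + 1 / 412 + 1 / 694),
               tolerance = 1e-12)
  # symmetric counts give log OR 0
  sym <- study_summary("sym", cases_risk = 50, cases_nonrisk = 50,
                       controls_risk = 80, controls_nonrisk = 80)
  expect_equal(summarize_study(sym)$log_or, 0)
  # effect-scale studies pass through unchanged
  eff <- study_summary("eff", log_or = 0.12, se = 0.05)
  expect_equal(summarize_study(eff)[c("log_or", "se")],
               list(log_or = 0.12, se = 0.05))
  # zero cells get the 0.5 correction with a flag
  z <- summarize_study(study_summary("z", cases_risk = 0, cases_nonrisk = 10,
                                     controls_risk = 5,
                                     controls_nonrisk = 5))
  expect_true(z$corrected)
  expect_true(is.finite(z$log_or))
})

three_studies <- function() list(
  study_summary("s1", log_or = 0.10, se = 0.10),
  study_summary("s2", log_or = 0.30, se = 0.15),
  study_summary("s3", log_or = -0.05, se = 0.20))

test_that("fixed-effect pooling is the inverse-variance mean", {
  s <- three_studies()
  # closed-form hand calculation
  y <- c(0.10, 0.30, -0.05); w <- 1 / c(0.10, 0.15, 0.20)^2
  r <- pool_fixed(s)
  expect_equal(r$fixed$log_or, sum(w * y) / sum(w), tolerance = 1e-10)
  expect_equal(r$fixed$se, sqrt(1 / sum(w)), tolerance = 1e-10)

  # single study passthrough
  r1 <- pool_fixed(s[1])
  expect_equal(r1$fixed$log_or, 0.10)
  expect_equal(r1$fixed$se, 0.10)

  # equal SEs: pooled estimate is the arithmetic mean
  eq <- list(study_summary("a", log_or = 0.2, se = 0.1),
             study_summary("b", log_or = 0.4, se = 0.1))
  expect_equal(pool_fixed(eq)$fixed$log_or, 0.3, tolerance = 1e-12)

  # order invariance and the SE/sqrt(2) merge property
  expect_equal(pool_fixed(rev(s))$fixed$log_or, r$fixed$log_or,
               tolerance = 1e-12)
  merged <- list(study_summary("ab", log_or = 0.2, se = 0.1 / sqrt(2)),
                 s[[3]])
  split2 <- list(study_summary("a", log_or = 0.2, se = 0.1),
                 study_summary("b", log_or = 0.2, se = 0.1), s[[3]])
  expect_equal(pool_fixed(merged)$fixed$log_or,
               pool_fixed(split2)$fixed$log_or, tolerance = 1e-12)
  expect_error(pool_fixed(list()), "no studies")
})

test_that("DerSimonian-Laird pooling matches the hand calculation", {
  s <- three_studies()
  y <- c(0.10, 0.30, -0.05); v <- c(0.10, 0.15, 0.20)^2; w <- 1 / v
  yf <- sum(w * y) / sum(w)
  q <- sum(w * (y - yf)^2)
  tau2 <- max(0, (q - 2) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (v + tau2)
  r <- pool_random_dl(s)
  expect_equal(r$q, q, tolerance = 1e-10)
  expect_equal(r$tau2, tau2, tolerance = 1e-10)
  expect_equal(r$random$log_or, sum(wr * y) / sum(wr), tolerance = 1e-10)
  expect_equal(r$random$se, sqrt(1 / sum(wr)), tolerance = 1e-10)
  expect_equal(r$i2, max(0, (q - 2) / q), tolerance = 1e-10)
  expect_equal(r$q_p, pchisq(q, 2, lower.tail = FALSE), tolerance = 1e-10)

  # identical studies: no heterogeneity, random equals fixed
  same <- list(study_summary("a", log_or = 0.2, se = 0.1),
               study_summary("b", log_or = 0.2, se = 0.1))
  rs <- pool_random_dl(same)
  expect_equal(rs$q, 0)
  expect_equal(rs$tau2, 0)
  expect_equal(rs$i2, 0)
  expect_equal(rs$random$log_or, rs$fixed$log_or, tolerance = 1e-12)
  expect_error(pool_random_dl(s[1]), "two studies")
})

test_that("pooling agrees with an established reference implementation", {
  skip_if_not_installed("metafor")
  s <- three_studies()
  y <- c(0.10, 0.30, -0.05); v <- c(0.10, 0.15, 0.20)^2
  ref <- metafor::rma(yi = y, vi = v, method = "DL")
  r <- pool_random_dl(s)
  expect_equal(r$random$log_or, as.numeric(ref$beta), tolerance = 1e-8)
  expect_equal(r$tau2, ref$tau2, tolerance = 1e-8)
  expect_equal(r$q, ref$QE, tolerance = 1e-8)
  reff <- metafor::rma(yi = y, vi = v, method = "FE")
  expect_equal(r$fixed$log_or, as.numeric(reff$beta), tolerance = 1e-8)
})

test_that("tau2 recovery on simulated study sets", {
  set.seed(61)
  tau2_hat <- replicate(120, {
    y <- rnorm(50, 0.1, sqrt(0.04 + 0.02^2)) # se 0.02 per study
    s <- lapply(seq_along(y), function(i)
      study_summary(paste0("s", i), log_or = y[i], se = 0.02))
    pool_random_dl(s)$tau2
  })
  expect_lt(abs(mean(tau2_hat) - 0.04), 0.2 * 0.04)
})

test_that("Egger regression flags asymmetry and degenerates gracefully", {
  s <- three_studies()
  e <- egger_test(s)
  # independent check via weighted lm on the standardized scale
  y <- c(0.10, 0.30, -0.05); se <- c(0.10, 0.15, 0.20)
  fit <- lm(I(y / se) ~ I(1 / se), weights = 1 / se^2)
  expect_equal(e$intercept, unname(coef(fit)[1]), tolerance = 1e-10)
  expect_error(egger_test(s[1:2]), "three studies")

  # equal SEs: one-sample t of the standardized effects
  eq <- lapply(1:5, function(i)
    study_summary(paste0("e", i), log_or = c(0.1, 0.2, 0, 0.15, 0.05)[i],
                  se = 0.1))
  de <- egger_test(eq)
  expect_true(de$degenerate_equal_se)
  tt <- t.test(c(0.1, 0.2, 0, 0.15, 0.05) / 0.1)
  expect_equal(de$p_value, tt$p.value, tolerance = 1e-12)

  # a strong small-study pattern is detected
  set.seed(8)
  se_g <- seq(0.05, 0.5, length.out = 30)
  sg <- lapply(seq_along(se_g), function(i)
    study_summary(paste0("g", i),
                  log_or = 0.1 + 2 * se_g[i] + rnorm(1, 0, se_g[i] / 3),
                  se = se_g[i]))
  expect_lt(egger_test(sg)$p_value, 0.01)
})

test_that("leave-one-out re-pooling isolates an outlier study", {
  s <- c(three_studies(),
         list(study_summary("outlier", log_or = 1.5, se = 0.12)))
  full <- pool_random_dl(s)
  loo <- leave_one_out(s)
  expect_length(loo, 4)
  expect_named(loo, paste("omit", c("s1", "s2", "s3", "outlier")))
  expect_lt(loo[["omit outlier"]]$i2, full$i2)
  # k = 2: each result is the other single study
  two <- leave_one_out(three_studies()[1:2])
  expect_equal(two[["omit s1"]]$fixed$log_or, 0.30)
  expect_equal(two[["omit s2"]]$fixed$log_or, 0.10)
})

test_that("funnel data and study tables round-trip through TSV", {
  s <- three_studies()
  fd <- funnel_data(s)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write.table(fd, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read.delim(tmp)
  expect_equal(back$log_or, fd$log_or)
  expect_equal(back$se, fd$se)

  fx <- system.file("extdata", "never_smoker_meta_synthetic.tsv",
                    package = "mediassoc")
  studies <- read_study_table(fx)
  expect_length(studies, 6)
  expect_equal(studies[[1]]$label, "primary-never-smokers")
  r <- pool_random_dl(studies)
  expect_equal(r$k, 6)
  expect_true(is.finite(r$random$or))
})
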
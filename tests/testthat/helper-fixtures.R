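# shared fixtures and independent oracles

`%||%` <- function(a, b) if (is.null(a)) b else a

strata_counts <- function() {
  read_count_table(system.file("extdata", "stratified_counts.tsv",
                               package = "mediassoc"))
}

# exhaustive permutation distribution of the Cochran-Armitage statistic:
# enumerate every 2x3 table with the observed margins, weight by the
# multivariate hypergeometric probability, and report the mid-p tail
# P(T > T_obs) + P(T = T_obs)/2 — the standard convention when a discrete
# permutation distribution is compared against a continuous chi-squared tail
perm_trend_p <- function(cases, controls, weights = c(0, 1, 2)) {
  n <- cases + controls
  N <- sum(n); R <- sum(cases)
  stat_of <- function(r) {
    gt <- genotype_table("perm", r, n - r)
    cochran_armitage_trend(gt, weights)$statistic
  }
  obs <- stat_of(cases)
  p_gt <- 0; p_eq <- 0
  for (a0 in 0:min(n[1], R)) {
    for (a1 in 0:min(n[2], R - a0)) {
      a2 <- R - a0 - a1
      if (a2 < 0 || a2 > n[3]) next
      pr <- exp(lchoose(n[1], a0) + lchoose(n[2], a1) + lchoose(n[3], a2) -
                  lchoose(N, R))
      s <- stat_of(c(a0, a1, a2))
      if (s > obs + 1e-9) p_gt <- p_gt + pr
      else if (abs(s - obs) <= 1e-9) p_eq <- p_eq + pr
    }
  }
  p_gt + p_eq / 2
}

# small deterministic record set: 6 smokers with hand-computable values
toy_records <- function() {
  data.frame(
    id = paste0("r", 1:6),
    status = c("case", "case", "case", "control", "control", "control"),
    dosage = c(0, 1, 2, 0, 1, 2),
    age = c(60, 62, 58, 61, 63, 59),
    sex = rep(c("male", "female"), 3),
    smoking_status = rep("current", 6),
    cpd = c(10, 15, 20, 12, 16, 22),
    duration_years = c(30, 32, 28, 31, 33, 29),
    family_history = c(TRUE, FALSE, FALSE, NA, NA, NA),
    stringsAsFactors = FALSE)
}
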
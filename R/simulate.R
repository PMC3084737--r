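#' Configuration of a synthetic case-control cohort
#'
#' Generative parameters of the simulator in [simulate_cohort()]. The
#' defaults describe a population resembling a European lung-cancer
#' case-control series: risk-allele frequency 0.36, 37% never-smokers,
#' log-normal cigarettes-per-day around 20, effective smoking duration
#' around 30 years, a 30-fold disease risk in smokers at the reference
#' exposure, and a genotype that acts only through smoking (no direct
#' term) unless `direct_log_or_per_allele` is set.
#'
#' @param n_cases,n_controls Numbers of cases and controls to ascertain.
#' @param raf Risk-allele frequency (Hardy-Weinberg genotypes).
#' @param beta_cpd_per_allele Shift in mean CPD per risk allele
#'   (cigarettes/day).
#' @param beta_duration_per_allele Shift in mean effective smoking duration
#'   per risk allele (years).
#' @param direct_log_or_per_allele Direct genotype effect on the log-odds of
#'   disease, per allele (default 0: purely indirect model).
#' @param cpd_mean Mean CPD of smokers at dosage 0.
#' @param cpd_sd_log Standard deviation of log CPD.
#' @param never_smoker_fraction Population fraction of never-smokers.
#' @param duration_mean,duration_sd Mean and SD of effective smoking
#'   duration (years beyond the dose-response model's age offset) at
#'   dosage 0.
#' @param age_range Age range (years) for never-smokers; smokers' ages are
#'   tied to their smoking duration.
#' @param baseline_risk Disease probability of a never-smoker at dosage 0.
#' @param smoker_rr Disease relative risk of a smoker at the reference
#'   exposure (`cpd_mean` CPD, `duration_mean` years) versus a never-smoker.
#' @param current_fraction Fraction of smokers labelled current (vs former).
#' @param family_history_rate Family-history probability among cases.
#' @param oversample Source-population size as a multiple of
#'   `n_cases + n_controls`.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_cases = 1000, n_controls = 1000,
                              raf = 0.36,
                              beta_cpd_per_allele = 0,
                              beta_duration_per_allele = 0,
                              direct_log_or_per_allele = 0,
                              cpd_mean = 20, cpd_sd_log = 0.35,
                              never_smoker_fraction = 0.37,
                              duration_mean = 30, duration_sd = 6,
                              age_range = c(40, 85),
                              baseline_risk = 5e-4,
                              smoker_rr = 30,
                              current_fraction = 0.35,
                              family_history_rate = 0.14,
                              oversample = 60,
                              seed = 1L) {
  cfg <- as.list(environment())
  if (n_cases <= 0 || n_controls <= 0) stop("sample sizes must be positive",
                                            call. = FALSE)
  for (f in c("raf", "never_smoker_fraction", "current_fraction",
              "family_history_rate"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("'", f, "' must be in [0,1]", call. = FALSE)
  if (baseline_risk <= 0 || baseline_risk >= 1)
    stop("'baseline_risk' must be a probability", call. = FALSE)
  if (cpd_mean <= 0 || duration_mean <= 0 || smoker_rr <= 0)
    stop("exposure and risk parameters must be positive", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

# stage-keyed sub-streams: one master seed spawns a fixed block of stage
# seeds so appending a stage never perturbs earlier draws
stage_seeds <- function(seed, n = 10L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a case-control cohort under the indirect-effect model
#'
#' Draws a source population (Hardy-Weinberg genotypes at the configured
#' risk-allele frequency; smoking status; for smokers, log-normal CPD with
#' a per-allele mean shift and normal effective duration with a per-allele
#' extension), assigns disease by the Doll-Peto dose-response — probability
#' `baseline_risk * smoker_rr * ((CPD+6)/(cpd_mean+6))^2 *
#' (duration/duration_mean)^4.5 * exp(direct * g)` for smokers and
#' `baseline_risk * exp(direct * g)` for never-smokers — and ascertains the
#' requested numbers of cases and controls by rejection sampling.
#'
#' @param config A [simulation_config()].
#' @return A data frame of individual records with columns `id`, `status`,
#'   `dosage`, `age`, `sex`, `smoking_status`, `cpd`, `duration_years`,
#'   `family_history`; the configuration is attached as attribute
#'   `"config"`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  ss <- stage_seeds(cfg$seed)
  N <- ceiling(cfg$oversample * (cfg$n_cases + cfg$n_controls))

  set.seed(ss[1])                               # genotypes, HWE
  g <- stats::rbinom(N, 2, cfg$raf)

  set.seed(ss[2])                               # smoking status
  never <- stats::runif(N) < cfg$never_smoker_fraction
  current <- !never & (stats::runif(N) < cfg$current_fraction)

  set.seed(ss[3])                               # exposures of smokers
  cpd <- rep(NA_real_, N)
  dur <- rep(NA_real_, N)
  sm <- !never
  mu <- log(pmax(cfg$cpd_mean + cfg$beta_cpd_per_allele * g[sm], 1)) -
    cfg$cpd_sd_log^2 / 2
  cpd[sm] <- exp(stats::rnorm(sum(sm), mu, cfg$cpd_sd_log))
  dur[sm] <- pmax(1, stats::rnorm(sum(sm),
                                  cfg$duration_mean +
                                    cfg$beta_duration_per_allele * g[sm],
                                  cfg$duration_sd))

  set.seed(ss[4])                               # ages and sex
  age <- numeric(N)
  age[never] <- stats::runif(sum(never), cfg$age_range[1], cfg$age_range[2])
  # smokers' age follows their smoking career past the model's age offset
  age[sm] <- 22.5 + dur[sm] + stats::runif(sum(sm), 0, 12)
  sex <- ifelse(stats::runif(N) < 0.5, "male", "female")

  set.seed(ss[5])                               # disease
  p <- rep(cfg$baseline_risk, N)
  p[sm] <- cfg$baseline_risk * cfg$smoker_rr *
    ((cpd[sm] + 6) / (cfg$cpd_mean + 6))^2 *
    (dur[sm] / cfg$duration_mean)^4.5
  p <- pmin(0.95, p * exp(cfg$direct_log_or_per_allele * g))
  case <- stats::runif(N) < p

  if (sum(case) < cfg$n_cases || sum(!case) < cfg$n_controls)
    stop(sprintf(paste0("infeasible sampling: source population of %d gave ",
                        "%d cases and %d non-cases; increase 'oversample'"),
                 N, sum(case), sum(!case)), call. = FALSE)

  set.seed(ss[6])                               # ascertainment
  idx <- c(sample(which(case), cfg$n_cases),
           sample(which(!case), cfg$n_controls))
  status <- rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls))

  set.seed(ss[7])                               # family history (cases)
  fh <- rep(NA, length(idx))
  fh[status == "case"] <- stats::runif(cfg$n_cases) < cfg$family_history_rate

  out <- data.frame(
    id = sprintf("S%06d", seq_along(idx)),
    status = status,
    dosage = g[idx],
    age = round(age[idx], 1),
    sex = sex[idx],
    smoking_status = ifelse(never[idx], "never",
                            ifelse(current[idx], "current", "former")),
    cpd = round(cpd[idx], 2),
    duration_years = round(dur[idx], 2),
    family_history = fh,
    stringsAsFactors = FALSE)
  attr(out, "config") <- cfg
  out
}

#' Build a genotype count table from individual records
#'
#' Tabulates case and control counts by dosage, optionally within a
#' smoking-status stratum.
#'
#' @param records Individual-record data frame.
#' @param label Table label.
#' @param stratum `"all"`, `"smokers"` (current + former) or
#'   `"never-smokers"`.
#' @return A [genotype_table()].
#' @export
records_to_table <- function(records, label = "sim", stratum = "all") {
  records <- as.data.frame(records)
  sm <- tolower(as.character(records$smoking_status))
  keep <- switch(stratum,
                 all = rep(TRUE, nrow(records)),
                 smokers = sm %in% c("current", "former"),
                 "never-smokers" = sm == "never",
                 stop("unknown stratum: ", stratum, call. = FALSE))
  df <- records[keep, , drop = FALSE]
  cnt <- function(st) tabulate(df$dosage[tolower(df$status) == st] + 1L,
                               nbins = 3L)
  genotype_table(label, cases = cnt("case"), controls = cnt("control"),
                 stratum = stratum)
}

#' Simulate a set of meta-analysis studies
#'
#' Per-study true log odds ratios are normal around `true_log_or` with
#' between-study variance `tau2`; allele counts are then binomial at each
#' study's sizes, with control allele frequency `raf` and the case
#' frequency implied by the study's true OR.
#'
#' @param k Number of studies.
#' @param true_log_or Mean true log odds ratio.
#' @param tau2 Between-study variance of the true log OR (>= 0).
#' @param size_range Range of per-group subject counts (uniform integer).
#' @param raf Control risk-allele frequency.
#' @param seed Integer seed.
#' @return A list of [study_summary()] objects with allele counts.
#' @export
simulate_study_set <- function(k, true_log_or = 0, tau2 = 0,
                               size_range = c(200, 2000), raf = 0.35,
                               seed = 1L) {
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  if (tau2 < 0) stop("tau2 must be non-negative", call. = FALSE)
  if (any(size_range < 2)) stop("degenerate study sizes", call. = FALSE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  theta <- stats::rnorm(k, true_log_or, sqrt(tau2))
  n_ca <- sample(size_range[1]:size_range[2], k, replace = TRUE)
  n_co <- sample(size_range[1]:size_range[2], k, replace = TRUE)
  p1 <- raf * exp(theta) / (1 - raf + raf * exp(theta))
  lapply(seq_len(k), function(i) {
    a <- stats::rbinom(1, 2 * n_ca[i], p1[i])
    c_ <- stats::rbinom(1, 2 * n_co[i], raf)
    study_summary(sprintf("study%02d", i),
                  cases_risk = a, cases_nonrisk = 2 * n_ca[i] - a,
                  controls_risk = c_, controls_nonrisk = 2 * n_co[i] - c_)
  })
}
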
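---
title: "Direct or smoking-mediated? Methods behind mediassoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct or smoking-mediated? Methods behind mediassoc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mediassoc)
```

## The question

Variants in the 15q25 *CHRNA5-CHRNA3* nicotinic-receptor region are robustly
associated with lung cancer. Two causal readings compete: the variants act
on the lung directly, or they raise risk only because carriers smoke more
(more cigarettes per day, and for longer). `mediassoc` implements the
statistical chain needed to weigh these readings in any case-control study
of a risk variant and a quantified behavioural exposure:

1. genotype-disease association (crude and per-allele odds ratios, trend
   tests, stratified by exposure status);
2. genotype-exposure association (smoking intensity, heavy smoking,
   age-of-onset trends);
3. a dose-response *sufficiency calculation*: is the genotype's measured
   effect on the exposure enough, under an accepted dose-response model, to
   generate the observed disease association?
4. population attributable risk and the familial clustering an inherited
   exposure generates on its own;
5. meta-analysis of the exposure-free stratum (never-smokers), where a
   direct effect would have to show itself.

## Association statistics

Crude genotype odds ratios use plain 2x2 arithmetic with Woolf (log-OR Wald)
confidence intervals, `exp(ln OR ± 1.96 sqrt(sum 1/cell))` — this convention,
with no continuity correction, is what stratified case-control tables print;
the Haldane 0.5 correction is available behind `continuity = TRUE` and
results are flagged when it fires. Per-allele odds ratios come from the
additive logistic model `logit P(case|g) = a + b g` fitted by maximum
likelihood to the grouped counts (IRLS with log-likelihood tolerance 1e-10,
at most 100 iterations); Wald intervals and two-sided p-values throughout.
Dosage is the number of *risk* alleles — for a variant whose risk allele is
the major allele the homozygous-risk genotype is dosage 2, so the coding is
per-variant input, never alphabetical.

The Cochran-Armitage trend statistic is computed with the variance taken
under the null conditional on both margins (the hypergeometric form, with
the finite-population `N/(N-1)` factor). In tests it is cross-checked two
ways: against `stats::prop.trend.test` at scale, and against the exhaustive
permutation distribution on small tables. For the permutation comparison we
use the mid-p convention — half the probability mass at the observed
statistic — because a discrete tail can sit arbitrarily far above a
continuous chi-squared tail near the null; even so, agreement within ±0.02
should only be expected of tables carrying a genuine trend signal, and the
test fixtures are chosen accordingly.

One deliberate guard: `per_allele_or()` flags `direction_consistent = FALSE`
whenever the per-allele estimate and the homozygote crude OR sit on opposite
sides of 1. Published per-allele ORs are occasionally the reciprocal of what
the printed counts imply (never-smoker strata with ORs below 1 alongside a
per-allele OR above 1); the package never silently inverts, it reports what
the counts give and lets the flag surface the discrepancy.

Analytic power of the per-allele trend test uses a non-central chi-squared
approximation with non-centrality `log(OR)^2 / Var(log OR)`, the variance
from expected allele counts under the alternative. A Monte-Carlo oracle in
the test suite confirms the approximation. Note that at 241 cases vs 553
controls, allele frequency 0.37 and OR 1.3 this gives ≈0.66 — materially
below the ~80% sometimes quoted for strata of this size, which the
Monte-Carlo check supports; quoted power figures deserve recomputation.

## Exposure analyses

Smoking intensity by genotype uses the Kruskal-Wallis rank test (mid-ranks,
standard tie correction). The per-allele CPD effect is a least-squares trend
of log CPD on dosage; because rank tests and log-scale slopes are hard to
read, the slope is back-transformed to a CPD difference at the analysed
sample's mean CPD, so effects are reported in cigarettes per day. Heavy
smoking is dichotomized at >20 CPD (light 1-20, heavy 21+), with risk-allele
frequencies per stratum and a trend test across the contrast. Age-of-onset
and initiation/cessation analyses share one generic operation,
`mean_trend_by_genotype()`, a 1-df linear trend optionally adjusted by
including covariates in the linear model. Box-Cox transformation for
covariate adjustment maximizes the profile log-likelihood over
λ ∈ [−2, 2] by golden-section search (tolerance 1e-4), with `log y` at λ = 0;
non-positive values are rejected with advice to shift.

## The mediation calculation

The dose-response model is the Doll-Peto power law: lung-cancer incidence in
middle-aged smokers proportional to `(CPD + 6)^2 * (age − 22.5)^4.5`. Two
reading choices matter:

* **Duration, not age.** We work in *effective duration* = age − 22.5 years,
  because the mediation hypothesis is that genotype prolongs smoking, not
  that it ages carriers. The exponent 4.5 on duration is what makes modest
  duration differences potent: +1 year on a 30-year baseline multiplies risk
  by `(31/30)^4.5 ≈ 1.16`, dwarfing the `(27/26)^2 ≈ 1.08` of +1 CPD.
* **Explicit baselines.** The model is a ratio, so a baseline CPD and
  duration must be supplied; there are no hidden defaults in the API. The
  conventional illustration — a 1.2-CPD homozygote contrast producing "about
  a 9% increase" — is only reproduced near a 20-21 CPD baseline, and the
  package documents 20 CPD / 30 years as its illustrative scenario rather
  than presenting the 9% as baseline-free.

`mediated_or_per_allele()` evaluates the risk ratio between baseline and
baseline-plus-one-allele exposure; `fraction_explained()` reports
`log(predicted)/log(observed)`. Model risk ratios are compared directly with
case-control odds ratios under the rare-disease approximation, stated as
such. No counterfactual natural-effects machinery is attempted: the claim
being operationalized is a sufficiency argument, not a decomposition.

## Attributable and familial risk

Per-locus population attributable risk is `p(OR−1)/(p(OR−1)+1)` with `p` the
control risk-allele frequency; several loci combine multiplicatively,
`1 − Π(1 − PAR_k)`, under independence. The additive alternative is left
auditable by returning the per-locus values: with (0.36, 1.43) and
(0.77, 1.32) the multiplicative combination gives ≈0.31, which is the
convention that reproduces the familiar "~30%" figure.

The familial relative risk attributable to an inherited exposure uses a
liability-threshold formalization built for this package (the methodology it
stands in for is published only by reference): exposure is the exceedance of
a standard-normal liability over the threshold set by prevalence; relatives'
liabilities correlate at `r = relatedness × h²` (0.5 × h² for any
first-degree pair under pure additivity — dominance is out of scope); the
joint exposure probability is the bivariate-normal orthant, computed by
adaptive quadrature (relative tolerance 1e-10) and cross-checked in tests
against 10⁶ Monte-Carlo draws. With heritability 0.6 and an exposure
relative risk of 30, the familial RR is ≈1.64 at 10% exposure prevalence,
falling to ≈1.40 at 25%: the often-quoted ~1.4 sits at the upper end of the
10–25% prevalence band.

## Meta-analysis engine

Studies enter on the log-OR scale; from raw counts the allelic 2x2 log OR
with Woolf SE is used (each ethnic sub-population of a publication is a
separate study). Fixed-effect pooling is the inverse-variance mean;
random-effects uses DerSimonian-Laird method-of-moments `tau²` (REML is
deliberately out of scope), with Cochran's Q, `I² = max(0, (Q − (k−1))/Q)`,
Egger's inverse-variance-weighted regression of standardized effect on
precision (t test of the intercept, k−2 df; with exactly equal SEs the
regression is singular and the test collapses, flagged, to a one-sample t),
leave-one-out re-pooling and funnel-data export. The engine is written in
full here and cross-checked against `metafor` in the test suite only. The
published pooled never-smoker estimates for 15q25 cannot be recomputed from
shipped data — the external studies' counts are not distributed with this
package — so the shipped study table pairs the real never-smoker counts with
clearly-labelled synthetic placeholders and the tests validate the engine
against hand calculations and calibration, not against those published
numbers.

## The synthetic cohort generator

`simulate_cohort()` draws the *purely indirect* generative model: HWE
genotypes at `raf`; never-smoker status at a population fraction; smokers'
CPD log-normal with the per-allele mean shift `beta_cpd_per_allele` and
effective duration normal with per-allele extension
`beta_duration_per_allele`; disease probability
`baseline_risk × smoker_rr × ((CPD+6)/(cpd_mean+6))² ×
(dur/duration_mean)^4.5 × exp(direct × g)` for smokers and
`baseline_risk × exp(direct × g)` for never-smokers; case-control
ascertainment by rejection sampling from an oversampled source population
(transparent, if slower than analytic outcome-dependent sampling). A master
seed spawns fixed per-stage sub-streams, so adding a stage cannot perturb
earlier draws and identical seeds give byte-identical cohorts.

Defaults were chosen once to emulate a European lung-cancer case-control
series: never-smoker fraction 0.37 (the control series' value; the case
fraction then *emerges* from ascertainment, landing near the observed ~6%,
since smoking drives case status), population CPD mean 20 with log-SD 0.35
(case means ≈23 and control means ≈18 again emerge via ascertainment),
duration mean 30 years (the canonical mediation baseline) with SD 6,
smoker relative risk 30 at the reference exposure, and a never-smoker
baseline risk of 5×10⁻⁴ to keep the rare-disease approximation honest.
What the generator does **not** emulate: under-reported CPD, differential
recall between cases and controls, genotyping error, population
stratification, and any correlation between smoking and other exposures —
so passing calibration here shows internal consistency of the method chain,
not robustness to those real-data pathologies.

The package's central self-consistency check runs end to end: cohorts
generated with +1.0 CPD and +1 year per allele over the 20 CPD / 30 year
baseline and *no* direct term must yield a smoker per-allele log OR within
three Monte-Carlo standard errors of `log` of the Doll-Peto prediction
(≈1.25 per allele), while the never-smoker stratum rejects at roughly the
nominal 5%. The shipped test uses 24 replicates of 2,500 cases and 2,500
controls — sizes chosen to make the Monte-Carlo band a meaningful ±0.016 on
the log OR while keeping the suite quick at a desk.

```{r mediation-example}
predicted <- mediated_or_per_allele(
  doll_peto_model(),
  mediation_scenario(baseline_cpd = 20, baseline_duration = 30,
                     delta_cpd_per_allele = 1,
                     delta_duration_per_allele = 1))
predicted
fraction_explained(predicted, observed_or = 1.43)
```

## Numerical and design notes

* Two-sided p-values everywhere; significance is the reader's call, not the
  package's.
* Listwise deletion per analysis for missing fields, with dropped-row counts
  returned (`n_dropped`), mirroring how real questionnaire-based cohorts
  produce varying denominators.
* Zero cells: errors by default; Haldane 0.5 behind a flag, always flagged
  in the result. Complete separation in the logistic fits is an explicit
  error, never a silently huge OR.
* CPD enters covariate adjustment as the conventional categories 0-10 /
  11-20 / 21-30 / 31+ (reference 0-10).
* `kruskal_wallis()` is invariant to monotone transforms of the pooled
  values, so the raw-vs-log-CPD question affects reported means only; means
  are reported raw.
* Quantile-grouped trends (e.g. CPD across age quantiles) are expressible
  through `mean_trend_by_genotype()` with a user-made grouping variable, but
  no printed value validates a specific quantile count, so none is built in.

## Limitations

The mediation comparison treats odds ratios as risk ratios (rare disease);
the familial model assumes pure additivity of liability; the meta-analysis
engine has no REML or Knapp-Hartung small-k adjustments; and the simulator's
clean exposure measurement is optimistic relative to self-reported smoking
histories. All are deliberate scope choices for a package whose job is the
inferential chain, not a general epidemiology toolkit.
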
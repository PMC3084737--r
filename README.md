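# mediassoc

Tools for asking a specific causal question about genetic association
studies: when a variant is associated with a smoking-related disease, does
it act on the disease directly, or only through its effect on smoking
behaviour? The motivating case is the 15q25 *CHRNA5-CHRNA3* nicotinic
acetylcholine receptor region and lung cancer, but every function takes
ordinary genotype counts or subject records and applies to any
variant-exposure-disease triple of the same shape.

The package is written for genetic epidemiologists and biostatisticians in
plain base-R / S3 style (in the spirit of `survival` and `metafor`), with
no compiled code and only `stats`, `utils` and `jsonlite` as dependencies.

## What it computes

**Association.** Crude genotype odds ratios with Woolf (log-OR Wald)
confidence intervals from a 3-genotype case-control table; the per-allele
odds ratio as the maximum-likelihood fit of the additive logistic model
logit P(case | g) = α + βg to grouped counts; the Cochran-Armitage trend
test with the margin-conditional (hypergeometric) null variance;
Hardy-Weinberg equilibrium χ²; covariate-adjusted logistic regression on
subject records; and analytic power of the trend test via a non-central χ²
approximation.

**Smoking behaviour.** Kruskal-Wallis tests of cigarettes-per-day (CPD) by
genotype, per-allele CPD effects on the log scale back-transformed to
cigarettes, heavy-smoking (>20 CPD) risk-allele frequencies and trend, mean
trends of onset/initiation ages by genotype with optional covariate
adjustment, and Box-Cox transformation selection by profile likelihood.

**Mediation.** The Doll-Peto excess-risk power law — risk ∝
(CPD + 6)² × duration^4.5, with duration the *effective* smoking duration
age − 22.5 — used as a sufficiency calculation: given the measured
per-allele shifts in CPD and duration, is the predicted per-allele risk
ratio large enough to account for the observed per-allele odds ratio?
`fraction_explained()` reports log(predicted)/log(observed).

**Attributable and familial risk.** Per-locus population attributable risk
p(OR−1)/(p(OR−1)+1), multiplicative combination across loci, and the
familial relative risk generated by an inherited exposure under a
liability-threshold model (bivariate-normal orthant probabilities by
adaptive quadrature).

**Meta-analysis.** A from-scratch engine: allelic log odds ratios from
counts, inverse-variance fixed-effect pooling, DerSimonian-Laird
random-effects, Cochran's Q and I², Egger's test, leave-one-out and funnel
data. Cross-checked against `metafor` in the test suite only.

**Simulation.** `simulate_cohort()` generates case-control cohorts under a
*purely indirect* model — genotype shifts CPD and duration, and disease
risk follows the Doll-Peto law — with an optional direct per-allele term,
so the whole inferential chain can be validated end to end against known
truth.

File I/O (subject records, count tables, study tables, JSON analysis
reports) and a command-line interface (`inst/cli/mediassoc.R`) round out
the package.

See the vignette (`vignettes/indirect-risk-methods.Rmd`) for the models,
assumptions, parameter choices and limitations in detail.

## Worked example

The shipped count table `inst/extdata/stratified_counts.tsv` holds genotype
counts for two 15q25 variants in smoker, never-smoker and familial
case-control strata. Starting from the smoker stratum of rs12914385
(risk allele T):

```r
library(mediassoc)
path <- system.file("extdata", "stratified_counts.tsv", package = "mediassoc")
tabs <- read_count_table(path)
gt <- tabs[["rs12914385:smokers"]]
gt
#> Genotype count table: rs12914385 (smokers), risk allele T
#>          dosage0 dosage1 dosage2
#> cases       1230    1973     815
#> controls     373     413     121

crude_genotype_or(gt, dosage = 2, reference_dosage = 0)
#> OR 2.043 (95% CI 1.634-2.554), p = 3.67e-10, n = 2539

per_allele_or(gt)
#> OR 1.434 (95% CI 1.290-1.593), p = 2.1e-11, n = 4925

cochran_armitage_trend(gt)
#> chi-squared = 45.3375, df = 1, p = 1.66e-11 (direction +)
```

Is a per-allele OR of 1.43 explicable by smoking behaviour alone? Suppose
the variant adds one cigarette per day and one year of smoking per risk
allele, on a 20 CPD / 30-year baseline:

```r
pred <- mediated_or_per_allele(
  doll_peto_model(),
  mediation_scenario(baseline_cpd = 20, baseline_duration = 30,
                     delta_cpd_per_allele = 1,
                     delta_duration_per_allele = 1))
pred
#> [1] 1.249864

fraction_explained(pred, observed_or = 1.43)
#> $fraction
#> [1] 0.6235695
#>
#> $fully_accounts
#> [1] FALSE
```

Even a generous behavioural shift predicts a risk ratio of 1.25 — about
62% of the observed association on the log scale — so the behavioural
pathway alone under this model does not fully account for the signal.

Population attributable risk for the two variants combined, using
control risk-allele frequencies and the fitted per-allele ORs:

```r
raf <- c(allele_frequencies(tabs[["rs12914385:smokers"]])$raf_controls,
         allele_frequencies(tabs[["rs8042374:smokers"]])$raf_controls)
round(raf, 3)
#> [1] 0.361 0.770

par_combined(p = raf, or_per_allele = c(1.43, 1.32))
#> $par_combined
#> [1] 0.3051681
#>
#> $par_each
#> [1] 0.1343066 0.1975213
```

And the familial relative risk that a heritable exposure generates on its
own (heritability 0.6, exposure prevalence 25%, exposure relative risk 30):

```r
familial_rr_exposure(h2 = 0.6, prevalence = 0.25, rr_exposed = 30)$frr
#> [1] 1.402857
```

## License

MIT (see `LICENSE`).
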
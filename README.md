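# missenseRisk

Case-control estimation of breast cancer risks conferred by rare missense
variants in susceptibility gene panels (ATM, BRCA1, BRCA2, CHEK2, PALB2).

Most missense variants in these genes are individually too rare to analyze:
the evidence must be pooled across variants. This package implements the two
complementary pooling strategies used in large panel-sequencing
epidemiology, for analysts working with case-control cohorts annotated with
in silico deleteriousness scores and protein-domain labels:

1. **Burden models.** Eligible variants (missense, allele frequency
   < 0.1%, not predicted to disrupt splicing) are partitioned into risk
   categories defined by protein domain and score bins — e.g. for ATM,
   variants inside the FAT or PIK domains with a CADD score in the top
   quintile. A stratified logistic regression with one indicator per
   category and country/ethnicity strata as covariates estimates the
   carrier odds ratio of each category:
   `logit P(case) = mu + s_country + sum_c beta_c I(carrier of c)`.

2. **Mixture models.** Instead of assuming every variant in a category
   carries the same risk, only a proportion `alpha_c` of the variants in
   category `c` is risk-associated, and every risk-associated variant
   confers a common odds ratio `exp(beta)` — either constrained to equal
   the protein-truncating-variant (PTV) odds ratio or left free. The model
   is fitted by an EM algorithm: the E-step computes, per variant, the
   posterior probability of being risk-associated given its carriers'
   case-control data; the M-step refits a weighted stratified logistic
   regression in which each carrier is split into a pathogenic and a benign
   pseudo-observation weighted by that posterior; `alpha_c` updates as the
   mean posterior over the category's variants. Because risk-associated
   variants are over-represented in cases, a bias-corrected `alpha` based
   only on variants seen in controls is also reported.

Around the core sit: a training/validation split with validation
calibration at fixed effect sizes (expected-vs-observed counts and a
goodness-of-fit chi-squared), posterior-probability-weighted predicted odds
ratios, a composite multi-gene model, the familial relative risk
decomposition `lambda = (p r^2 + q (p r + q)^2) / (2 p r + 1 - 2 p)^2`, and
a synthetic cohort generator that reproduces the statistical structure the
models assume (latent per-variant pathogenicity, stratified baselines,
prospective disease model, retrospective case-control sampling).

## Worked example

Simulate a cohort at the default published-study scale (74,500 subjects,
five genes, six country strata), assign ATM risk categories, and fit the
burden and constrained mixture models:

```r
library(missenseRisk)

cfg        <- defaultSimConfig()
ct         <- simulateCatalog(cfg, 1001)
cohort     <- simulateCohort(ct$catalog, ct$truth, cfg, 2001)
assignment <- assignGroups(variants(cohort), builtinScheme("ATM"))

lr <- filterSubjects(cohort, dropPtvCarriersIn = "ATM",
                     dropMultiMissenseGenes = TRUE)
groupBurden(lr, assignment)
#>          category n_variants n_case_carriers n_control_carriers   OR ci_low ci_high        p
#> 1 outside_FAT_PIK        714            1258               1343 1.03  0.956    1.12 4.00e-01
#> 2 FAT_PIK_CADD1_4        171             313                300 1.15  0.985    1.35 7.69e-02
#> 3   FAT_PIK_CADD5        103             250                187 1.48  1.221    1.79 5.92e-05

fit <- fitMixture(cohort, assignment, mixtureSpec("ATM", "constrained"))
fit
#> MixtureFit (ATM, constrained): missense OR 2.387, PTV OR 2.387, converged in 249 EM iterations
#>   alpha:
#>      outside_FAT_PIK FAT_PIK_CADD1_4 FAT_PIK_CADD5
#> risk          0.0074          0.0677        0.4967

round(controlOnlyAlpha(fit), 3)
#> outside_FAT_PIK FAT_PIK_CADD1_4   FAT_PIK_CADD5
#>           0.000           0.060           0.446
```

Reading the output: only the FAT/PIK + CADD-Q5 category shows a burden
association (OR 1.48); under the mixture model about half of its variants
are risk-associated with an OR of 2.39 (this simulation generated the
category with alpha 0.54 and a constrained OR of 2.16), while the other
categories are almost entirely benign. The control-only alpha corrects the
mild case-enrichment bias of the naive estimate.

The full workflow (simulate or read → split → filter → group → burden +
mixture → validation calibration → composite model → familial relative
risk) is orchestrated by `runPipeline()`; a thin command-line wrapper is
provided in `inst/scripts/pipeline.R`.

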
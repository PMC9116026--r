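---
title: "Risk-category burden and mixture models for rare missense variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-category burden and mixture models for rare missense variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Panel sequencing of breast cancer cases and controls yields thousands of
rare missense variants in susceptibility genes. Almost all are too rare for
individual association tests, so inference must pool variants. Pooling by
annotation (protein domain, in silico deleteriousness score) raises a
modelling question this package is built around: within an annotation
category, does *every* variant shift risk a little, or does a *subset*
carry substantial risk while the rest are neutral? The first reading is the
classical burden model; the second is the mixture model, which mirrors how
clinical genetics actually classifies variants (pathogenic vs benign).

# Data model

A `Cohort` couples a variant catalog (gene, HGVS-style id, consequence
class missense/PTV, allele frequency, scores, domain label,
splice-exclusion flag, optional functional-assay and ClinVar classes) with
a subject table (stratum, case/control status, age, population vs familial
study design, carried variant ids). All analyses adjust for stratum
(country, or country-by-ethnicity) by dummy coding with the largest stratum
as reference. Variant ids are opaque strings; the package does no
genomic-coordinate arithmetic.

Eligibility for category schemes is: missense consequence, allele frequency
strictly below 0.1% (the comparison is strict because the threshold is
defined as "< 0.1%"), and no predicted splicing effect (consumed as a
precomputed boolean; the package never runs splice predictors).

# Risk-category schemes

`builtinScheme()` provides the standard per-gene partitions:

* ATM: outside FAT/PIK; inside FAT or PIK with CADD in quintiles 1-4;
  inside FAT or PIK with CADD in quintile 5. The shipped Q4/Q5 boundary is
  3.736542; alternatively compute boundaries from training data with
  `quantileBoundaries()`.
* BRCA1: outside RING/BRCT; inside with Helix-low; inside with Helix-high.
* BRCA2 and CHEK2: Helix-low vs Helix-high.
* PALB2: all eligible carriers as one category.
* Layered schemes put functional-assay classes first: BRCA1
  (INT/LOF by saturation genome editing > domain+Helix for unassayed
  variants > FUNC or outside-domain) and BRCA2 (homology-directed-repair
  LP/P > Helix for unassayed > LB/B).

Numerical conventions: a Helix score of exactly 0.5 is classed *low* (the
dichotomy is defined by "> 0.5 is deleterious" and "< 0.5 is benign",
leaving the boundary unassigned; low is the conservative choice). CADD
quintiles are computed over unique eligible variants (not carriers) with
the type-7 linear-interpolation quantile rule — the most common empirical
default; which population and weighting the original boundary used is not
derivable from its value alone, which is why the published constant is also
shipped. Scheme predicates must partition the eligible set; a variant
matching zero or two categories raises an error naming it, rather than
being silently dropped or double-counted.

# The mixture model and its EM fit

For gene *g* with categories *c*, subject *i* in stratum *s(i)*:

* non-carriers: `logit P(case) = mu + gamma_s`
* PTV carriers: `... + beta_PTV`
* carriers of missense variant *v*: `... + Z_v * beta`, where
  `Z_v ~ Bernoulli(alpha_c(v))` is the variant's latent risk status.

The observed-data log-likelihood marginalizes `Z_v` per variant:
non-carrier and PTV terms plus
`sum_v log(alpha_c L1_v + (1 - alpha_c) L0_v)`, where `L1`/`L0` are the
carrier-data likelihoods of variant *v* under the risk-associated and
benign states (non-carrier factors cancel in the ratio, so they are
excluded; a variant with no carriers has `L1 = L0 = 1`).

EM alternates:

* **E-step**: `p_v = alpha L1 / (alpha L1 + (1 - alpha) L0)`, computed in
  log space with a log-sum-exp to survive variants with many carriers.
* **M-step**: a weighted stratified logistic regression on aggregated
  pseudo-data — each missense carrier contributes a pathogenic row (weight
  `p_v`, exposure indicator) and a benign row (weight `1 - p_v`, no
  exposure); PTV carriers enter at weight one. In the constrained mode the
  pathogenic and PTV rows share one coefficient; unconstrained they have
  separate coefficients; the two-level mode has a high state sharing the
  PTV coefficient plus a moderate state with its own. Because counts are
  aggregated by (variant-state, stratum, outcome), the regression sees a
  few dozen rows regardless of cohort size, which is what makes study-scale
  EM cheap.
* **alpha update**: the unweighted mean posterior over the unique variants
  of the category *observed in the fitting data*. Zero-carrier catalog
  variants have `L1 = L0 = 1` and posterior equal to `alpha`; including
  them would leave the fixed point unchanged while slowing convergence, so
  they are excluded from the update (their reported posterior is
  `alpha_c`).

Both steps maximize the EM minorant, so the observed-data log-likelihood
trace is non-decreasing; the `MixtureFit` validity method enforces this (up
to 1e-8 relative slack) on every fit ever constructed.

Choices the model statement leaves open, decided as follows:

* Subjects carrying two or more eligible missense variants of the gene are
  excluded from mixture fits with a logged count: the per-variant
  likelihood factorization assumes one variant per carrier.
* Subjects with both a PTV and a missense variant of the gene enter as PTV
  carriers; their missense carriage is ignored there.
* The alpha update averages over unique variants, unweighted by carrier
  count: alpha is a proportion *of variants*, not of carriers.
* Control-only alpha averages posteriors over variants with at least one
  control carrier ("reported in controls" read as >= 1 control carrier).
* Initialization: alpha 0.1 per category, missense log-OR log(1.5), PTV
  log-OR from a PTV-only logistic fit, nuisance from a non-carrier fit;
  two additional deterministic starts (alpha 0.5 with log(3), alpha 0.02
  with log(1.2)) guard against local maxima and the best final
  log-likelihood is kept. Convergence: absolute log-likelihood change
  below 1e-6, at most 500 iterations; non-convergence is flagged on the
  fit, not raised.
* Confidence intervals for alpha use the profile likelihood (alpha fixed
  on a grid, all other parameters re-maximized by EM, interval where twice
  the drop from the maximum is within the chi-squared(1) quantile, grid
  crossings linearly interpolated, clipped to [0, 1]). The original
  interval method is not stated anywhere recoverable; profile likelihood
  is the standard choice for a boundary-prone proportion.

# Logistic regression engine

`fitLogistic()` wraps iteratively reweighted least squares with strict
failure modes: rank-deficient designs (duplicated covariates) and
(quasi-)complete separation raise errors instead of returning unusable
estimates. Separation detection is scale-aware — a coefficient is flagged
when its contribution to the linear predictor spans more than 30 logits
over the observed covariate range (a raw |beta| cut would misfire on
covariates measured in tiny units, e.g. allele frequencies). Wald 95%
intervals (`exp(beta +/- 1.96 se)`) are used throughout, with the
log-likelihood exposed for likelihood-ratio comparisons. Fractional
observation weights are honoured exactly, which the EM M-step relies on.
Convergence tolerance 1e-10, at most 100 IRLS iterations.

# Training/validation design

`splitTrainValidation()` samples the validation fraction only from
population-design subjects of the eligible strata, stratified by
(stratum, status) — the source design says only "selected randomly", but
stratification stabilizes the downstream country covariates at no cost.
PTV carriers of the analysis genes are excluded from burden analyses and
re-included in mixture fits; the validation set drops them entirely.

On validation data, effect sizes are fixed and only the intercept and
stratum coefficients are re-estimated (`refitNuisance()`). For mixture
models the fixed per-category offset is `log(alpha_val e^beta + 1 -
alpha_val)` — the exact odds multiplier of a two-component mixture — with
`alpha_val` the case-fraction-weighted average of the posterior-weighted
carrier proportions among training cases and controls
(`adjustedAlpha()`), since alpha in a case-control sample depends on its
case mix.

`calibrationGof()` sums `(O - E)^2 / E` over category-by-outcome cells.
Its default degrees of freedom equal the number of carrier categories
*k*, not *k - 1*: expected case and control counts within a category sum
exactly to that category's observed carrier total (the expectation is
accumulated over exactly its members), so each category contributes one
independent standardized contrast, and the baseline cell is pinned by the
fixed case/control totals. Simulation from an exactly-true fixed-offset
model shows the statistic's mean near *k* (slightly below, since nuisance
estimation absorbs part of the deviation) and shows that *k - 1* degrees
of freedom over-reject. The df remains a user parameter for sensitivity
analyses. Expected cells below 5 warn; an expected cell of zero is an
error.

The per-variant alternative (`ppWeightedOr()`) converts training
posteriors to predicted ORs by the same linear-odds mixing rule,
`PP e^beta + (1 - PP)`, dropping carriers of variants unseen in training;
category-level predictions aggregate per-variant values weighted by
validation carrier counts (the aggregation rule is this package's
declared choice; nothing in the source pins it down).

`compositeFit()` fits all gene-category indicators jointly against
carriers of nothing, excluding subjects with eligible missense variants in
two or more genes (count reported).

# Familial relative risk

For gene *j* with deleterious allele frequency `p` and carrier relative
risk `r`, the single-locus familial relative risk under random mating is
`lambda_j = (p r^2 + q (p r + q)^2) / (2 p r + 1 - 2 p)^2` with
`q = 1 - p`, which reduces to `1 + p (r - 1)^2` for small `p` (a property
tested at p <= 1e-3). `p` is an *allele* frequency: carrier frequencies of
rare heterozygous variants are halved before use — the denominator
`2 p r + 1 - 2 p` is only coherent on the allele scale. Contributions add
across genes (`lambda_mis = 1 + sum(lambda_j - 1)`) and the explained
fraction of an overall familial relative risk of 2 is
`log(lambda_mis) / log 2`. The CHEK2 pathogenic missense carrier frequency
is not recoverable as a printed value (only "comparable to the PTV
frequency"); `referenceFrrInputs()` ships 0.006 with that caveat, and the
aggregate should be read as a consistency band rather than a point
estimate.

# The synthetic cohort generator

`simulateCatalog()` + `simulateCohort()` generate data with exactly the
structure the models assume, so every stage is testable without the
controlled-access originals:

* per category, variant pathogenicity is Bernoulli(alpha); allele
  frequencies are log-uniform within (1e-7, 2e-4) by default — chosen so
  that expected per-category carrier counts at the default cohort size
  match the reference summary table's counts to leading order;
* annotations (domain, CADD, Helix) are drawn from category templates so
  the built-in schemes reproduce the intended labels;
* subjects are simulated *prospectively* — stratum, carrier status
  (carrier probability twice the allele frequency, rare-variant
  heterozygote approximation, homozygotes ignored; at most one eligible
  missense per gene per subject by construction), disease from the
  logistic model — and then sampled *retrospectively* to the target
  case/control counts. This two-stage design makes the logistic model
  literally true and makes bias properties (naive vs control-only alpha)
  testable rather than assumed;
* familial ascertainment is reduced to a case inclusion-probability
  multiplier in familial-design strata: enough to reproduce the direction
  of the alpha bias, nowhere near a pedigree model.

`defaultSimConfig()` mirrors the reference summary table: category sizes,
alpha values, and mixture ORs per gene; six population strata with
prospective baseline case log-odds near logit(0.1); targets 35,500 cases
and 39,000 controls from a pool of 420,000. The CHEK2 PTV odds ratio (2.5)
and per-gene PTV carrier frequencies are field-standard values, needed
because the summary table fixes only the missense side. The default master
seed is 20220518; all randomness flows through the seed arguments and the
caller's RNG state is restored.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: linkage disequilibrium and recurrent
mutation; sequencing and annotation error; frequency-pathogenicity
correlation (real deleterious variants skew rarer); realistic
family-history ascertainment; population substructure beyond discrete
strata; age-dependent risks.

# Problem sizes used by the test suite

Scales are the package's own choices for its checks: oracle comparisons
run on micro-data (2 variants, 8 subjects) against a brute-force grid and
on 100 random 2x2 tables against the closed-form odds ratio; EM
monotonicity runs on 50 random cohorts of ~1,800 subjects; parameter
recovery runs 25 replicates at the full default scale (74,500 subjects,
five genes) for ATM-like and CHEK2-like blocks, comparing Monte-Carlo
means of control-only alpha and the mixture OR with the generating values;
calibration runs 20 validation sets of 5,000 subjects generated exactly
from a trained model's fixed multipliers. Profile-CI behaviour is checked
at reduced scale (a full coverage study over many replicates would
multiply EM runs by the grid size and is out of proportion for a unit
suite).

# Known limitations

* Alpha estimates at the boundary (near 0 or 1) converge slowly; fits
  report `converged = FALSE` after 500 iterations rather than forcing the
  issue. Estimates at that point are typically stable to far more digits
  than the science needs, but the flag should be checked.
* The constrained/unconstrained likelihood-ratio comparison treats alpha
  as an interior parameter; near-boundary alpha makes the chi-squared
  reference conservative.
* Control-only alpha corrects case-enrichment bias but remains a
  proportion over *control-seen* variants; with very low-frequency
  variants and small control counts it can under-shoot the variant-level
  alpha slightly.
* The adjusted-alpha validation offset is exact on the odds scale but the
  mixture of expits is not exactly an expit of mixed odds; at case-control
  baseline probabilities the discrepancy is a fraction of a percent and is
  absorbed by the nuisance refit.
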
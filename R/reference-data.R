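#' Reference risk-group summary table
#'
#' Published population-training summary estimates for the five breast
#' cancer susceptibility genes analyzed by the package: per risk category,
#' the number of unique rare missense variants, case and control carrier
#' counts (with non-carrier rows), logistic regression odds ratios with
#' 95% CIs, mixture-model alpha estimates with CIs, and the mixture-model
#' missense odds ratio (constrained to the PTV odds ratio except for
#' CHEK2, where the unconstrained model fits best). These printed summary
#' numbers parameterize [defaultSimConfig()] and serve as worked-example
#' inputs for [pathogenicCarrierStats()] and [frrTable()].
#'
#' @return data.frame.
#' @export
referenceRiskGroups <- function() {
  path <- system.file("extdata", "reference_risk_groups.tsv",
                      package = "missenseRisk", mustWork = TRUE)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, na.strings = "NA")
}

#' Reference gene-level inputs for the familial relative risk decomposition
#'
#' Carrier frequencies of pathogenic (risk-associated) missense variants
#' and the mixture-model carrier relative risks for ATM, BRCA1, BRCA2 and
#' CHEK2. The CHEK2 pathogenic missense carrier frequency was reported
#' only as comparable to the CHEK2 PTV carrier frequency; the value here
#' (0.006 carrier frequency) sits in that range and the aggregate estimate
#' should be read with that uncertainty.
#'
#' @return data.frame with columns gene, carrier_frequency, p (allele
#'   frequency = carrier_frequency / 2), r.
#' @export
referenceFrrInputs <- function() {
  d <- data.frame(
    gene = c("ATM", "BRCA1", "BRCA2", "CHEK2"),
    carrier_frequency = c(0.0030, 0.00026, 0.00028, 0.006),
    r = c(2.16, 10.61, 5.87, 1.75),
    stringsAsFactors = FALSE)
  d$p <- d$carrier_frequency / 2
  d
}
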
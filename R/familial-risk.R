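#' Familial relative risk contributed by one gene
#'
#' Single-locus familial relative risk under a dominant rare-variant model:
#' lambda = (p r^2 + q (p r + q)^2) / (2 p r + 1 - 2 p)^2, with q = 1 - p,
#' where p is the aggregate allele frequency of deleterious missense
#' variants and r their relative risk. For small p this reduces to
#' 1 + p (r - 1)^2.
#'
#' Note p is an allele frequency; halve a carrier frequency before calling
#' (heterozygous carriers of rare variants carry one allele).
#'
#' @param p deleterious allele frequency in [0, 0.5].
#' @param r carrier relative risk (> 0).
#' @return lambda (>= 1 when r >= 1).
#' @export
lambdaGene <- function(p, r) {
  if (any(p < 0 | p > 0.5)) stopf("p must be in [0, 0.5]")
  if (any(r <= 0)) stopf("r must be > 0")
  q <- 1 - p
  (p * r^2 + q * (p * r + q)^2) / (2 * p * r + 1 - 2 * p)^2
}

#' Aggregate familial relative risk over genes
#'
#' Assumes additive contributions across genes:
#' lambda_mis = 1 + sum(lambda_j - 1).
#'
#' @param lambdas vector of per-gene lambda values (each >= 0).
#' @return aggregate lambda.
#' @export
lambdaMissenseTotal <- function(lambdas) {
  if (any(lambdas < 0)) stopf("lambda values must be >= 0")
  1 + sum(lambdas - 1)
}

#' Proportion of the overall familial relative risk explained
#'
#' log(lambda_mis) / log(overallFrr), assuming variants combine
#' multiplicatively with other familial factors and an overall familial
#' relative risk of 2 by default.
#'
#' @param lambdaMis aggregate lambda (>= 1).
#' @param overallFrr overall familial relative risk (default 2).
#' @return fraction of log familial relative risk explained.
#' @export
frrProportion <- function(lambdaMis, overallFrr = 2) {
  if (lambdaMis < 1) stopf("lambdaMis must be >= 1")
  log(lambdaMis) / log(overallFrr)
}

#' Pathogenic carrier frequency and case-carrier fraction
#'
#' From per-category carrier counts, mixture-model alpha estimates and the
#' risk-associated missense odds ratio:
#' \itemize{
#'   \item control pathogenic-carrier frequency =
#'     sum_c alpha_c * controls_c / total controls;
#'   \item expected fraction of cases carrying a pathogenic variant =
#'     sum_c w_c * cases_c / total cases, where
#'     w_c = alpha_c OR / (alpha_c OR + 1 - alpha_c) is the probability
#'     that a carrier's variant is risk associated given case status
#'     (Bayes weighting of the two mixture components).
#' }
#'
#' @param caseCarriers,controlCarriers per-category carrier counts.
#' @param nonCarrierCases,nonCarrierControls counts of non-carriers.
#' @param alpha per-category proportions of risk-associated variants.
#' @param orMissense mixture-model odds ratio for risk-associated carriers.
#' @return list(control_frequency, case_fraction).
#' @export
pathogenicCarrierStats <- function(caseCarriers, controlCarriers,
                                   nonCarrierCases, nonCarrierControls,
                                   alpha, orMissense) {
  stopifnot(length(caseCarriers) == length(alpha),
            length(controlCarriers) == length(alpha))
  if (any(alpha < 0 | alpha > 1)) stopf("alpha must be in [0, 1]")
  if (any(c(caseCarriers, controlCarriers,
            nonCarrierCases, nonCarrierControls) < 0))
    stopf("counts must be non-negative")
  totCases <- nonCarrierCases + sum(caseCarriers)
  totControls <- nonCarrierControls + sum(controlCarriers)
  if (totCases == 0 || totControls == 0) stopf("zero subject totals")
  w <- alpha * orMissense / (alpha * orMissense + 1 - alpha)
  list(control_frequency = sum(alpha * controlCarriers) / totControls,
       case_fraction = sum(w * caseCarriers) / totCases)
}

#' Familial relative risk decomposition table
#'
#' Convenience wrapper evaluating [lambdaGene()] per gene, aggregating with
#' [lambdaMissenseTotal()] and [frrProportion()].
#'
#' @param summaries data.frame with columns gene, p (allele frequency), r
#'   (carrier relative risk).
#' @param overallFrr overall familial relative risk (default 2).
#' @return data.frame of per-gene rows plus "TOTAL" and "FRR_fraction"
#'   aggregate rows.
#' @export
frrTable <- function(summaries, overallFrr = 2) {
  stopifnot(all(c("gene", "p", "r") %in% names(summaries)))
  lam <- mapply(lambdaGene, summaries$p, summaries$r)
  lamMis <- lambdaMissenseTotal(lam)
  frac <- frrProportion(lamMis, overallFrr)
  rbind(
    data.frame(gene = summaries$gene, p = summaries$p, r = summaries$r,
               lambda = lam, stringsAsFactors = FALSE),
    data.frame(gene = "TOTAL", p = NA_real_, r = NA_real_, lambda = lamMis,
               stringsAsFactors = FALSE),
    data.frame(gene = "FRR_fraction", p = NA_real_, r = NA_real_,
               lambda = frac, stringsAsFactors = FALSE))
}
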
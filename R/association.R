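#' Risk-category burden table
#'
#' Jointly fits one carrier indicator per risk category against non-carriers
#' of any eligible variant of the gene, with country/ethnicity strata as
#' covariates, and reports per-category carrier counts with odds ratios,
#' Wald 95% CIs and p-values. PTV carriers of the gene are expected to have
#' been removed with [filterSubjects()] beforehand (they are re-included
#' only by the mixture models). Categories with zero carriers are reported
#' as NA rows rather than silently dropped.
#'
#' @param cohort a Cohort.
#' @param assignment a [GroupAssignment-class].
#' @return data.frame: category, n_variants, n_case_carriers,
#'   n_control_carriers, OR, ci_low, ci_high, p.
#' @export
groupBurden <- function(cohort, assignment) {
  s <- subjects(cohort)
  mapping <- assignment@mapping
  cats <- names(assignment@scheme@categories)
  memb <- categoryMembership(s$carried, mapping, cats)
  counts <- countsByCategory(memb, s$status, mapping, cats)
  fitCats <- cats[counts$n_case_carriers + counts$n_control_carriers > 0]
  X <- cbind(memb[, fitCats, drop = FALSE], stratumDesign(s$stratum))
  fit <- fitLogistic(s$status, X)
  tab <- orTable(fit)
  out <- counts
  out$OR <- NA_real_; out$ci_low <- NA_real_
  out$ci_high <- NA_real_; out$p <- NA_real_
  m <- match(fitCats, tab$term)
  out[out$category %in% fitCats, c("OR", "ci_low", "ci_high", "p")] <-
    tab[m, c("OR", "ci_low", "ci_high", "p")]
  attr(out, "fit") <- fit
  out
}

# subjects x categories 0/1 indicator matrix ("carries any variant of c")
categoryMembership <- function(carried, mapping, cats) {
  n <- length(carried)
  ids <- unlist(carried, use.names = FALSE)
  subj <- rep.int(seq_len(n), lengths(carried))
  lab <- mapping[ids]
  keep <- !is.na(lab)
  M <- matrix(0, n, length(cats), dimnames = list(NULL, cats))
  if (any(keep))
    M[cbind(subj[keep], match(lab[keep], cats))] <- 1
  M
}

countsByCategory <- function(memb, status, mapping, cats) {
  isCase <- status == "case"
  data.frame(
    category = cats,
    n_variants = as.integer(table(factor(mapping, levels = cats))),
    n_case_carriers = colSums(memb[isCase, , drop = FALSE]),
    n_control_carriers = colSums(memb[!isCase, , drop = FALSE]),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Carrier-only in silico score trend
#'
#' Logistic regression of case/control status on a continuous in silico
#' score plus stratum covariates, restricted to carriers of a rare eligible
#' missense variant of the gene. Subjects carrying more than one eligible
#' variant of the gene are dropped (the carried score would be ambiguous);
#' the count is reported in the `dropped_multi` attribute.
#'
#' @param cohort a Cohort.
#' @param gene gene symbol.
#' @param scoreName one of "cadd", "helix", "bayesdel", "revel",
#'   "align_gvgd".
#' @param rareThreshold eligibility threshold (default 0.001).
#' @return one-row data.frame: OR per unit score, ci_low, ci_high, p, n.
#' @export
carrierScoreTrend <- function(cohort, gene, scoreName, rareThreshold = 0.001) {
  v <- variants(cohort)
  if (!scoreName %in% c("cadd", "helix", "bayesdel", "revel", "align_gvgd"))
    stopf("unknown score '%s'", scoreName)
  elig <- eligibleMissense(v, gene, rareThreshold)
  carr <- geneCarriage(cohort, gene, elig)
  sel <- !is.na(carr$variantOf) & !carr$ptv
  s <- subjects(cohort)[sel, , drop = FALSE]
  score <- v[[scoreName]][match(carr$variantOf[sel], v$variant_id)]
  ok <- !is.na(score)
  s <- s[ok, , drop = FALSE]; score <- score[ok]
  if (length(unique(score)) < 2L) stopf("score is constant among carriers")
  if (length(unique(s$status)) < 2L)
    stopf("need carriers of both outcomes with non-missing score")
  X <- cbind(score = score, stratumDesign(s$stratum))
  fit <- fitLogistic(s$status, X)
  tab <- orTable(fit)
  out <- tab[tab$term == "score", c("OR", "ci_low", "ci_high", "p")]
  out$n <- nrow(s)
  rownames(out) <- NULL
  structure(out, dropped_multi = sum(carr$multi), fit = fit)
}

#' Frequency burden and carrier-only frequency tests
#'
#' Burden: one indicator per allele-frequency bin (< 0.1%, 0.1-0.5%,
#' 0.5-1%, 1-5%) versus non-carriers, fitted jointly with stratum
#' covariates. Carrier-only tests (restricted to variants with frequency
#' < 0.5%): frequency on a continuous scale, on a log scale, and the
#' two-group contrast < 0.1% versus 0.1-0.5%, each adjusted for stratum and
#' optionally for risk-group covariates.
#'
#' @param cohort a Cohort.
#' @param gene gene symbol.
#' @param bins internal breakpoints, default c(0.001, 0.005, 0.01, 0.05).
#' @param adjustAssignment optional [GroupAssignment-class]; adds risk-group
#'   indicator covariates to the carrier-only tests.
#' @return list(burden = per-bin OR table, carrier_tests = data.frame).
#' @export
frequencyBurden <- function(cohort, gene, bins = c(0.001, 0.005, 0.01, 0.05),
                            adjustAssignment = NULL) {
  v <- variants(cohort)
  sel <- v$gene == gene & v$consequence == "missense" &
    !is.na(v$frequency) & v$frequency <= bins[4L] &
    !(v$splice_excluded %in% TRUE)
  if (!any(sel)) stopf("no missense variants for gene '%s'", gene)
  vv <- v[sel, , drop = FALSE]
  binOf <- setNames(classifyFrequency(vv$frequency, bins), vv$variant_id)
  s <- subjects(cohort)
  memb <- categoryMembership(s$carried, binOf, FREQ_BIN_LABELS)
  counts <- countsByCategory(memb, s$status, binOf, FREQ_BIN_LABELS)
  nonEmpty <- FREQ_BIN_LABELS[counts$n_case_carriers +
                              counts$n_control_carriers > 0]
  X <- cbind(memb[, nonEmpty, drop = FALSE], stratumDesign(s$stratum))
  colnames(X)[seq_along(nonEmpty)] <- nonEmpty
  fit <- fitLogistic(s$status, X)
  tab <- orTable(fit)
  burden <- counts
  burden$OR <- NA_real_; burden$ci_low <- NA_real_
  burden$ci_high <- NA_real_; burden$p <- NA_real_
  m <- match(nonEmpty, tab$term)
  burden[burden$category %in% nonEmpty, c("OR", "ci_low", "ci_high", "p")] <-
    tab[m, c("OR", "ci_low", "ci_high", "p")]

  # carrier-only tests on variants with frequency < 0.5%
  rareIds <- vv$variant_id[vv$frequency < bins[2L]]
  carr <- geneCarriage(cohort, gene, rareIds)
  cs <- !is.na(carr$variantOf) & !carr$ptv
  sc <- s[cs, , drop = FALSE]
  f <- vv$frequency[match(carr$variantOf[cs], vv$variant_id)]
  adj <- stratumDesign(sc$stratum)
  if (!is.null(adjustAssignment)) {
    g <- categoryMembership(sc$carried, adjustAssignment@mapping,
                            names(adjustAssignment@scheme@categories))
    ref <- adjustAssignment@scheme@baseline
    g <- g[, setdiff(colnames(g), ref), drop = FALSE]
    g <- g[, colSums(g) > 0, drop = FALSE]
    adj <- cbind(adj, g)
  }
  oneTest <- function(x, name) {
    if (length(unique(x)) < 2L || length(unique(sc$status)) < 2L)
      return(data.frame(test = name, OR = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_, n = nrow(sc)))
    ft <- fitLogistic(sc$status, cbind(x = x, adj))
    tb <- orTable(ft)
    cbind(test = name, tb[tb$term == "x", c("OR", "ci_low", "ci_high", "p")],
          n = nrow(sc), row.names = NULL)
  }
  tests <- rbind(
    oneTest(f, "continuous"),
    oneTest(log(f), "log"),
    oneTest(as.numeric(f < bins[1L]), "rare_vs_lowfreq"))
  list(burden = burden, carrier_tests = tests)
}

#' Single-variant odds ratio
#'
#' Carrier indicator for one variant versus non-carriers of that variant,
#' adjusted for stratum. If carriers appear in only one outcome class, the
#' crude (cross-product with zero cell) estimate is returned with
#' `unbounded = TRUE` rather than letting the fit diverge.
#'
#' @param cohort a Cohort.
#' @param variantId variant id present in the catalog.
#' @return one-row data.frame: variant_id, n_case_carriers,
#'   n_control_carriers, OR, ci_low, ci_high, p, unbounded.
#' @export
singleVariantOr <- function(cohort, variantId) {
  s <- subjects(cohort)
  if (!variantId %in% variants(cohort)$variant_id)
    stopf("unknown variant '%s'", variantId)
  carries <- vapply(s$carried, function(ids) variantId %in% ids, logical(1L))
  if (!any(carries)) stopf("variant '%s' has no carriers", variantId)
  isCase <- s$status == "case"
  a <- sum(carries & isCase); b <- sum(carries & !isCase)
  if (a == 0L || b == 0L) {
    orCrude <- if (b == 0L) Inf else 0
    return(data.frame(variant_id = variantId, n_case_carriers = a,
                      n_control_carriers = b, OR = orCrude,
                      ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                      unbounded = TRUE, stringsAsFactors = FALSE))
  }
  X <- cbind(carrier = as.numeric(carries), stratumDesign(s$stratum))
  fit <- fitLogistic(s$status, X)
  tab <- orTable(fit)
  r <- tab[tab$term == "carrier", ]
  data.frame(variant_id = variantId, n_case_carriers = a,
             n_control_carriers = b, OR = r$OR, ci_low = r$ci_low,
             ci_high = r$ci_high, p = r$p, unbounded = FALSE,
             stringsAsFactors = FALSE)
}

#' Case-only age trend in risk-category membership
#'
#' Among case carriers of the gene's eligible variants, fits membership in
#' the top risk category (versus all other carrier categories) on age at
#' diagnosis plus stratum covariates, returning the per-year odds ratio.
#' Subjects with missing age are dropped and counted.
#'
#' @param cohort a Cohort.
#' @param assignment a [GroupAssignment-class].
#' @param topCategory label of the high-risk category.
#' @return one-row data.frame: OR (per year), ci_low, ci_high, p, n,
#'   n_dropped_age.
#' @export
caseOnlyAgeTrend <- function(cohort, assignment, topCategory) {
  cats <- names(assignment@scheme@categories)
  if (!topCategory %in% cats) stopf("unknown category '%s'", topCategory)
  carr <- geneCarriage(cohort, assignment@gene, names(assignment@mapping))
  s <- subjects(cohort)
  sel <- s$status == "case" & !is.na(carr$variantOf) & !carr$ptv
  cat <- assignment@mapping[carr$variantOf[sel]]
  age <- s$age[sel]
  strat <- s$stratum[sel]
  dropped <- sum(is.na(age))
  ok <- !is.na(age)
  cat <- cat[ok]; strat <- strat[ok]; age <- age[ok]
  if (length(unique(cat)) < 2L)
    stopf("case carriers present in fewer than 2 categories")
  if (length(unique(age)) < 2L) stopf("age is constant")
  y <- as.numeric(cat == topCategory)
  fit <- fitLogistic(y, cbind(age = age, stratumDesign(strat)))
  tab <- orTable(fit)
  r <- tab[tab$term == "age", ]
  data.frame(OR = r$OR, ci_low = r$ci_low, ci_high = r$ci_high, p = r$p,
             n = length(y), n_dropped_age = dropped)
}
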
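#' Refit nuisance parameters on the validation set with fixed effect sizes
#'
#' The per-category carrier log odds ratios from the training model enter
#' as a fixed offset; only the intercept and stratum coefficients are
#' re-estimated (case-control proportions may differ between training and
#' validation). Validation strata unseen in training simply get their own
#' re-estimated coefficient.
#'
#' @param validation a Cohort.
#' @param assignment a [GroupAssignment-class].
#' @param fixedBetas named numeric: category -> fixed log OR (categories
#'   missing from the vector contribute 0).
#' @return a [LogisticFit-class] (intercept + stratum terms only).
#' @export
refitNuisance <- function(validation, assignment, fixedBetas) {
  s <- subjects(validation)
  cats <- names(assignment@scheme@categories)
  memb <- categoryMembership(s$carried, assignment@mapping, cats)
  beta <- setNames(rep(0, length(cats)), cats)
  beta[intersect(names(fixedBetas), cats)] <-
    fixedBetas[intersect(names(fixedBetas), cats)]
  offset <- drop(memb %*% beta)
  bad <- tapply(s$status, s$stratum, function(x) length(unique(x)) < 2L)
  if (any(bad))
    stopf("stratum with a single outcome class: %s",
          paste(names(bad)[bad], collapse = ", "))
  fitLogistic(s$status, stratumDesign(s$stratum), offset = offset)
}

#' Adjusted validation-set alpha
#'
#' The training-set alpha is a property of the training case-control mix;
#' for a validation set with a different case fraction, alpha is the
#' case-fraction-weighted average of the posterior-weighted carrier
#' proportions among training cases and training controls.
#'
#' @param caseAlpha,controlAlpha proportions of training case / control
#'   carriers of the category whose variant is risk associated.
#' @param validationCaseFraction case fraction among validation carriers.
#' @return alpha for the validation set.
#' @export
adjustedAlpha <- function(caseAlpha, controlAlpha, validationCaseFraction) {
  stopifnot(all(c(caseAlpha, controlAlpha, validationCaseFraction) >= 0),
            all(c(caseAlpha, controlAlpha, validationCaseFraction) <= 1))
  validationCaseFraction * caseAlpha +
    (1 - validationCaseFraction) * controlAlpha
}

#' Goodness-of-fit calibration of a trained model on a validation set
#'
#' With training effect sizes fixed (and, for mixture models, the adjusted
#' alpha), re-estimates the intercept and stratum coefficients, extracts
#' each subject's predicted case probability, and accumulates expected case
#' and control counts per risk category. The chi-squared statistic sums
#' (O - E)^2 / E over category x outcome cells (carrier categories), with
#' df = number of categories by default: within each category the expected
#' case and control counts sum exactly to the observed carrier total, so the
#' two outcome cells form one independent standardized contrast per
#' category (the baseline cell is pinned by the fixed case/control totals).
#' Alternative df choices can be supplied. Observed ORs come from an
#' unconstrained refit for the observed-versus-expected table.
#'
#' For a mixture model the carrier odds multiplier of category c is
#' alpha_c * exp(beta) + (1 - alpha_c): the exact marginal odds factor of a
#' two-component mixture of carrier odds ratios.
#'
#' @param validation a Cohort.
#' @param assignment a [GroupAssignment-class].
#' @param model list; either `list(type = "lr", betas = named log-ORs)` or
#'   `list(type = "mixture", alpha = named per-category alpha, beta =
#'   log OR of risk-associated carriers)`.
#' @param df degrees of freedom for the GOF test (default: number of
#'   carrier categories).
#' @return a [ValidationReport-class].
#' @export
calibrationGof <- function(validation, assignment, model, df = NULL) {
  s <- subjects(validation)
  cats <- names(assignment@scheme@categories)
  memb <- categoryMembership(s$carried, assignment@mapping, cats)
  betas <- modelOffsets(model, cats)
  nuis <- refitNuisance(validation, assignment, betas)
  eta <- nuisanceEta(nuis, s$stratum) + drop(memb %*% betas)
  p <- plogis(eta)
  isCase <- s$status == "case"
  catLab <- rep("baseline", nrow(s))
  hit <- rowSums(memb) > 0
  catLab[hit] <- colnames(memb)[max.col(memb[hit, , drop = FALSE])]
  obsCase <- tapply(isCase, factor(catLab, levels = c(cats, "baseline")), sum)
  obsCase[is.na(obsCase)] <- 0
  obsCtl <- tapply(!isCase, factor(catLab, levels = c(cats, "baseline")), sum)
  obsCtl[is.na(obsCtl)] <- 0
  expCase <- tapply(p, factor(catLab, levels = c(cats, "baseline")), sum)
  expCase[is.na(expCase)] <- 0
  expCtl <- tapply(1 - p, factor(catLab, levels = c(cats, "baseline")), sum)
  expCtl[is.na(expCtl)] <- 0

  eC <- expCase[cats]; eL <- expCtl[cats]
  if (any(c(eC, eL) == 0)) stopf("expected cell equal to zero")
  if (any(c(eC, eL) < 5))
    warnf("expected cell below 5; chi-squared approximation may be poor")
  chiSq <- sum((obsCase[cats] - eC)^2 / eC + (obsCtl[cats] - eL)^2 / eL)
  df <- df %||% length(cats)
  pval <- pchisq(chiSq, df, lower.tail = FALSE)

  obsOr <- tryCatch(groupBurden(validation, assignment),
                    error = function(e) NULL)
  tab <- data.frame(
    category = c(cats, "baseline"),
    observed_cases = as.numeric(obsCase),
    observed_controls = as.numeric(obsCtl),
    expected_cases = as.numeric(expCase),
    expected_controls = as.numeric(expCtl),
    predicted_OR = c(exp(betas), 1),
    observed_OR = NA_real_, observed_ci_low = NA_real_,
    observed_ci_high = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(obsOr)) {
    m <- match(obsOr$category, tab$category)
    tab$observed_OR[m] <- obsOr$OR
    tab$observed_ci_low[m] <- obsOr$ci_low
    tab$observed_ci_high[m] <- obsOr$ci_high
  }
  new("ValidationReport", table = tab, chiSq = unname(chiSq),
      df = as.numeric(df), p = unname(pval), excludedMultigene = 0)
}

modelOffsets <- function(model, cats) {
  if (model$type == "lr") {
    b <- setNames(rep(0, length(cats)), cats)
    b[intersect(names(model$betas), cats)] <-
      model$betas[intersect(names(model$betas), cats)]
    return(b)
  }
  if (model$type == "mixture") {
    a <- setNames(rep(0, length(cats)), cats)
    a[intersect(names(model$alpha), cats)] <-
      model$alpha[intersect(names(model$alpha), cats)]
    return(setNames(log(a * exp(model$beta) + (1 - a)), cats))
  }
  stopf("unknown model type '%s'", model$type)
}

nuisanceEta <- function(nuisFit, stratum) {
  cf <- coef(nuisFit)
  eta <- rep(unname(cf["(Intercept)"]), length(stratum))
  sn <- paste0("stratum", stratum)
  hit <- sn %in% names(cf)
  eta[hit] <- eta[hit] + cf[sn[hit]]
  eta
}

#' Posterior-probability-weighted predicted odds ratios
#'
#' Predicted validation OR per variant = PP * exp(betaMis) + (1 - PP),
#' where PP is the training posterior probability that the variant is risk
#' associated (the linear-odds mixing rule). Carriers of variants absent
#' from the training posteriors are dropped, per the validation design.
#' The per-category predicted OR aggregates per-variant predictions
#' weighted by validation carrier counts.
#'
#' @param validation a Cohort.
#' @param assignment a [GroupAssignment-class].
#' @param posteriors named numeric: training PP per variant id.
#' @param betaMis log OR of risk-associated missense carriers.
#' @return data.frame: category, n_carriers_used, n_carriers_dropped,
#'   predicted_OR (NA when no overlapping variants).
#' @export
ppWeightedOr <- function(validation, assignment, posteriors, betaMis) {
  s <- subjects(validation)
  carr <- geneCarriage(validation, assignment@gene, names(assignment@mapping))
  sel <- !is.na(carr$variantOf) & !carr$ptv
  vid <- carr$variantOf[sel]
  known <- vid %in% names(posteriors)
  cats <- names(assignment@scheme@categories)
  catOf <- assignment@mapping
  out <- do.call(rbind, lapply(cats, function(cc) {
    inC <- catOf[vid] == cc
    used <- inC & known
    dropped <- sum(inC & !known)
    if (!any(used))
      return(data.frame(category = cc, n_carriers_used = 0L,
                        n_carriers_dropped = dropped,
                        predicted_OR = NA_real_, stringsAsFactors = FALSE))
    pp <- posteriors[vid[used]]
    orV <- pp * exp(betaMis) + (1 - pp)
    data.frame(category = cc, n_carriers_used = sum(used),
               n_carriers_dropped = dropped,
               predicted_OR = mean(orV), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Composite multi-gene risk-category model
#'
#' One unconstrained logistic regression over all risk categories of all
#' genes, with non-carriers of any eligible missense variant as the
#' baseline group and stratum covariates. Subjects carrying eligible
#' missense variants in two or more genes are excluded (count reported).
#'
#' @param validation a Cohort.
#' @param assignments list of [GroupAssignment-class], one per gene.
#' @return a [ValidationReport-class] whose table holds per-(gene,
#'   category) counts and ORs; chi-squared slots are NA (no GOF here).
#' @export
compositeFit <- function(validation, assignments) {
  genes <- vapply(assignments, function(a) a@gene, character(1L))
  if (anyDuplicated(genes)) stopf("one assignment per gene required")
  s <- subjects(validation)
  membs <- lapply(assignments, function(a) {
    cats <- names(a@scheme@categories)
    m <- categoryMembership(s$carried, a@mapping, cats)
    colnames(m) <- paste(a@gene, cats, sep = ":")
    m
  })
  M <- do.call(cbind, membs)
  carriesGene <- vapply(membs, function(m) rowSums(m) > 0, logical(nrow(s)))
  nGenes <- rowSums(carriesGene)
  excluded <- sum(nGenes >= 2L)
  keep <- nGenes < 2L
  sK <- s[keep, , drop = FALSE]
  MK <- M[keep, , drop = FALSE]
  isCase <- sK$status == "case"
  counts <- data.frame(
    category = colnames(MK),
    n_case_carriers = colSums(MK[isCase, , drop = FALSE]),
    n_control_carriers = colSums(MK[!isCase, , drop = FALSE]),
    row.names = NULL, stringsAsFactors = FALSE)
  nonEmpty <- counts$category[counts$n_case_carriers +
                              counts$n_control_carriers > 0]
  fit <- fitLogistic(sK$status,
                     cbind(MK[, nonEmpty, drop = FALSE],
                           stratumDesign(sK$stratum)))
  tb <- orTable(fit)
  counts$OR <- NA_real_; counts$ci_low <- NA_real_
  counts$ci_high <- NA_real_; counts$p <- NA_real_
  m <- match(nonEmpty, tb$term)
  counts[counts$category %in% nonEmpty, c("OR", "ci_low", "ci_high", "p")] <-
    tb[m, c("OR", "ci_low", "ci_high", "p")]
  new("ValidationReport", table = counts, chiSq = NA_real_, df = NA_real_,
      p = NA_real_, excludedMultigene = excluded)
}
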
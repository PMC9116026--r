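#' @rdname Cohort-class
#' @param x,object a Cohort.
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))

#' @rdname Cohort-class
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))

#' @rdname Cohort-class
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname Cohort-class
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname MixtureFit-class
#' @param object a MixtureFit.
#' @export
setGeneric("alphaEstimates", function(object) standardGeneric("alphaEstimates"))

#' @rdname MixtureFit-class
#' @export
setGeneric("posteriors", function(object) standardGeneric("posteriors"))

#' @rdname MixtureFit-class
#' @export
setGeneric("loglikTrace", function(object) standardGeneric("loglikTrace"))

#' Odds-ratio table of a fit
#'
#' One row per coefficient with OR, Wald 95% CI and p-value.
#' @param object a LogisticFit.
#' @export
setGeneric("orTable", function(object) standardGeneric("orTable"))

setMethod("subjects", "Cohort", function(x) x@subjects)
setMethod("variants", "Cohort", function(x) x@variants)
setMethod("nSubjects", "Cohort", function(x) nrow(x@subjects))
setMethod("nVariants", "Cohort", function(x) nrow(x@variants))

setMethod("show", "Cohort", function(object) {
  s <- object@subjects
  cat(sprintf("Cohort: %d subjects (%d cases / %d controls), %d variants\n",
              nrow(s), sum(s$status == "case"), sum(s$status == "control"),
              nrow(object@variants)))
  cat(sprintf("  strata: %s\n", paste(sort(unique(s$stratum)), collapse = ", ")))
  cat(sprintf("  design: %d population, %d familial\n",
              sum(s$design == "population"), sum(s$design == "familial")))
  genes <- sort(unique(object@variants$gene))
  cat(sprintf("  genes: %s\n", paste(genes, collapse = ", ")))
})

setMethod("show", "RiskScheme", function(object) {
  cat(sprintf("RiskScheme for %s: %s (baseline: %s)\n", object@gene,
              paste(names(object@categories), collapse = " | "),
              object@baseline))
})

setMethod("show", "GroupAssignment", function(object) {
  tab <- table(object@mapping)
  cat(sprintf("GroupAssignment (%s): %d eligible variants\n",
              object@gene, length(object@mapping)))
  for (lb in names(object@scheme@categories))
    cat(sprintf("  %-40s %d\n", lb, if (lb %in% names(tab)) tab[[lb]] else 0L))
})

setMethod("show", "LogisticFit", function(object) {
  cat(sprintf("LogisticFit: %d terms, n = %g, logLik = %.4f, converged = %s\n",
              length(object@coefficients), object@n, object@loglik,
              object@converged))
  print(orTable(object), digits = 4)
})

setMethod("show", "MixtureFit", function(object) {
  cat(sprintf("MixtureFit (%s, %s): missense OR %.3f, PTV OR %.3f, %s\n",
              object@gene, object@mode, exp(object@betaMis),
              exp(object@betaPtv),
              if (object@converged) sprintf("converged in %d EM iterations",
                                            length(object@loglikTrace))
              else "NOT converged"))
  cat("  alpha:\n")
  print(round(object@alpha, 4))
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport: chi-squared %.3f on %d df, p = %.3g\n",
              object@chiSq, object@df, object@p))
  if (object@excludedMultigene > 0)
    cat(sprintf("  %d multi-gene carriers excluded\n", object@excludedMultigene))
  print(object@table, digits = 4)
})

setMethod("alphaEstimates", "MixtureFit", function(object) object@alpha)
setMethod("posteriors", "MixtureFit", function(object) object@posteriors)
setMethod("loglikTrace", "MixtureFit", function(object) object@loglikTrace)

#' @export
#' @describeIn orTable OR, Wald CI and p per coefficient
setMethod("orTable", "LogisticFit", function(object) {
  beta <- object@coefficients
  se <- sqrt(pmax(diag(object@covariance), 0))
  data.frame(term = names(beta), logOR = unname(beta), se = unname(se),
             OR = exp(unname(beta)),
             ci_low = exp(unname(beta) - 1.96 * unname(se)),
             ci_high = exp(unname(beta) + 1.96 * unname(se)),
             p = 2 * pnorm(-abs(unname(beta) / unname(se))),
             row.names = NULL, stringsAsFactors = FALSE)
})

#' @export
setMethod("coef", "LogisticFit", function(object) object@coefficients)

#' @export
setMethod("vcov", "LogisticFit", function(object) object@covariance)

#' @export
setMethod("logLik", "LogisticFit", function(object) object@loglik)
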
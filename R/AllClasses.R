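#' Cohort: case-control subjects plus a variant catalog
#'
#' The central container consumed by every analysis stage. `variants` holds
#' one row per catalogued variant (gene, HGVS-style id, consequence class,
#' allele frequency, in silico scores, protein-domain label, splice-exclusion
#' flag, functional assay and clinical classes). `subjects` holds one row per
#' study participant (id, country/ethnicity stratum, case/control status,
#' age at diagnosis/interview, population vs familial study design, and the
#' set of carried variant ids as a list column).
#'
#' Validity enforces referential integrity: unique subject and variant ids,
#' allele frequencies in [0, 1], binary status, non-empty strata, and every
#' carried variant id resolving to a catalog row.
#'
#' @slot subjects data.frame with columns subject_id, stratum, status
#'   ("case"/"control"), age (numeric, NA allowed), design
#'   ("population"/"familial"), carried (list of character vectors).
#' @slot variants data.frame with columns gene, variant_id, consequence
#'   ("missense"/"PTV"), frequency, cadd, helix, bayesdel, revel, align_gvgd,
#'   domain, splice_excluded, sge_class, hdr_class, clinvar_class.
#' @slot metadata list of bookkeeping entries (e.g. removal logs).
#' @export
setClass("Cohort",
  representation(subjects = "data.frame", variants = "data.frame",
                 metadata = "list"),
  prototype(metadata = list()))

SUBJECT_COLS <- c("subject_id", "stratum", "status", "age", "design", "carried")
VARIANT_COLS <- c("gene", "variant_id", "consequence", "frequency",
                  "cadd", "helix", "bayesdel", "revel", "align_gvgd",
                  "domain", "splice_excluded", "sge_class", "hdr_class",
                  "clinvar_class")

setValidity("Cohort", function(object) {
  s <- object@subjects; v <- object@variants
  msgs <- character(0)
  if (!all(SUBJECT_COLS %in% names(s)))
    msgs <- c(msgs, paste("subjects missing columns:",
                          paste(setdiff(SUBJECT_COLS, names(s)), collapse = ", ")))
  if (!all(c("gene", "variant_id", "consequence", "frequency") %in% names(v)))
    msgs <- c(msgs, "variants missing required columns")
  if (length(msgs)) return(msgs)
  if (anyDuplicated(s$subject_id))
    msgs <- c(msgs, paste("duplicated subject_id:",
                          s$subject_id[duplicated(s$subject_id)][1L]))
  if (anyDuplicated(v$variant_id))
    msgs <- c(msgs, paste("duplicated variant_id:",
                          v$variant_id[duplicated(v$variant_id)][1L]))
  if (!all(s$status %in% c("case", "control")))
    msgs <- c(msgs, "status must be 'case' or 'control'")
  if (any(is.na(s$stratum) | !nzchar(s$stratum)))
    msgs <- c(msgs, "stratum labels must be non-empty")
  if (!all(s$design %in% c("population", "familial")))
    msgs <- c(msgs, "design must be 'population' or 'familial'")
  if (!all(v$consequence %in% c("missense", "PTV")))
    msgs <- c(msgs, "consequence must be 'missense' or 'PTV'")
  bad <- !is.na(v$frequency) & (v$frequency < 0 | v$frequency > 1)
  if (any(bad))
    msgs <- c(msgs, paste("frequency outside [0,1] for", v$variant_id[bad][1L]))
  carried <- unique(unlist(s$carried, use.names = FALSE))
  unknown <- setdiff(carried, v$variant_id)
  if (length(unknown))
    msgs <- c(msgs, paste("carried variant id not in catalog:", unknown[1L]))
  if (length(msgs)) msgs else TRUE
})

#' Risk-category scheme for one gene
#'
#' An ordered list of mutually exclusive category predicates over variant
#' annotations. Predicates must partition the eligible (rare, non
#' splice-excluded missense) variants of the gene: `assignGroups()` raises a
#' partition error if any variant matches zero or more than one category.
#'
#' @slot gene gene symbol.
#' @slot categories named list: label -> predicate function(variants df)
#'   returning a logical vector.
#' @slot baseline label of the within-gene reference category.
#' @slot params named list of scheme constants (e.g. cadd_boundary,
#'   helix_cut, rare_threshold).
#' @slot descriptor list representation used for YAML round-trips (empty for
#'   hand-built function predicates).
#' @export
setClass("RiskScheme",
  representation(gene = "character", categories = "list",
                 baseline = "character", params = "list",
                 descriptor = "list"),
  prototype(params = list(), descriptor = list()))

setValidity("RiskScheme", function(object) {
  if (length(object@gene) != 1L || !nzchar(object@gene))
    return("gene must be a single non-empty symbol")
  if (length(object@categories) < 1L)
    return("at least one category required")
  if (is.null(names(object@categories)) || anyDuplicated(names(object@categories)))
    return("categories must be uniquely labelled")
  if (!all(vapply(object@categories, is.function, logical(1L))))
    return("category predicates must be functions")
  TRUE
})

#' Variant-to-category assignment realizing a scheme
#'
#' @slot gene gene symbol.
#' @slot mapping named character vector: variant_id -> category label.
#' @slot scheme the RiskScheme that produced the mapping.
#' @export
setClass("GroupAssignment",
  representation(gene = "character", mapping = "character",
                 scheme = "RiskScheme"))

setValidity("GroupAssignment", function(object) {
  if (length(object@mapping) &&
      !all(object@mapping %in% names(object@scheme@categories)))
    return("mapping contains labels not in the scheme")
  TRUE
})

#' Maximum-likelihood logistic regression fit
#'
#' @slot coefficients named log-odds estimates.
#' @slot covariance coefficient covariance matrix (inverse observed
#'   information at the MLE).
#' @slot loglik maximized Bernoulli log-likelihood.
#' @slot n number of subjects (sum of weights) used.
#' @slot converged logical.
#' @export
setClass("LogisticFit",
  representation(coefficients = "numeric", covariance = "matrix",
                 loglik = "numeric", n = "numeric", converged = "logical"))

setValidity("LogisticFit", function(object) {
  p <- length(object@coefficients)
  if (!all(dim(object@covariance) == c(p, p)))
    return("covariance dimension does not match coefficients")
  if (p && max(abs(object@covariance - t(object@covariance))) > 1e-6)
    return("covariance must be symmetric")
  TRUE
})

#' Fitted per-category mixture model
#'
#' Captures the EM solution: per-category proportions of risk-associated
#' variants (alpha; one row per risk state for the two-level model), the
#' pathogenic missense and PTV log odds ratios, nuisance (intercept +
#' stratum) coefficients, per-variant posterior probabilities of being
#' risk-associated, and the observed-data log-likelihood trace.
#'
#' @slot alpha numeric matrix, states x categories.
#' @slot betaMis numeric; log OR for pathogenic missense carriers (for the
#'   two-level model, the moderate-state log OR).
#' @slot betaPtv numeric; PTV log OR.
#' @slot nuisance named numeric (intercept + stratum coefficients).
#' @slot posteriors matrix, variants x states, rownames = variant ids.
#' @slot loglikTrace numeric vector of observed-data log-likelihoods.
#' @slot converged logical.
#' @slot mode "constrained", "unconstrained" or "two_level".
#' @slot gene gene symbol.
#' @slot details list: data fingerprint, per-variant category, carrier
#'   counts, exclusion log, variant likelihood table.
#' @export
setClass("MixtureFit",
  representation(alpha = "matrix", betaMis = "numeric", betaPtv = "numeric",
                 nuisance = "numeric", posteriors = "matrix",
                 loglikTrace = "numeric", converged = "logical",
                 mode = "character", gene = "character", details = "list"))

setValidity("MixtureFit", function(object) {
  if (any(object@alpha < -1e-12 | object@alpha > 1 + 1e-12))
    return("alpha outside [0,1]")
  if (length(object@posteriors) &&
      any(object@posteriors < -1e-9 | object@posteriors > 1 + 1e-9))
    return("posteriors outside [0,1]")
  tr <- object@loglikTrace
  if (length(tr) > 1L && any(diff(tr) < -1e-8 * pmax(1, abs(tr[-length(tr)]))))
    return("observed-data log-likelihood trace must be non-decreasing")
  TRUE
})

#' Validation calibration report
#'
#' @slot table data.frame of per-category observed/expected counts, observed
#'   OR with CI and the model-predicted OR.
#' @slot chiSq goodness-of-fit chi-squared statistic.
#' @slot df degrees of freedom.
#' @slot p p-value.
#' @slot excludedMultigene number of multi-gene carriers excluded (composite
#'   analyses; 0 otherwise).
#' @export
setClass("ValidationReport",
  representation(table = "data.frame", chiSq = "numeric", df = "numeric",
                 p = "numeric", excludedMultigene = "numeric"))

setValidity("ValidationReport", function(object) {
  if (length(object@chiSq) && !is.na(object@chiSq) && object@chiSq < 0)
    return("chiSq must be >= 0")
  TRUE
})
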
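#' Eligible rare missense variants of a gene
#'
#' Eligibility for the category schemes: missense consequence, allele
#' frequency strictly below `rareThreshold`, and not flagged as predicted to
#' affect RNA splicing.
#'
#' @param catalog variant data.frame (or a Cohort, whose catalog is used).
#' @param gene gene symbol; must be present in the catalog.
#' @param rareThreshold frequency threshold in (0, 0.05]; default 0.001
#'   (i.e. < 0.1%).
#' @return character vector of variant ids.
#' @export
eligibleMissense <- function(catalog, gene, rareThreshold = 0.001) {
  if (is(catalog, "Cohort")) catalog <- variants(catalog)
  if (!is.numeric(rareThreshold) || rareThreshold <= 0 || rareThreshold > 0.05)
    stopf("'rareThreshold' must be in (0, 0.05]")
  if (!gene %in% catalog$gene) stopf("unknown gene '%s'", gene)
  spl <- if (is.null(catalog$splice_excluded)) rep(FALSE, nrow(catalog))
         else catalog$splice_excluded %in% TRUE
  sel <- catalog$gene == gene &
    catalog$consequence == "missense" &
    !is.na(catalog$frequency) & catalog$frequency < rareThreshold &
    !spl
  catalog$variant_id[sel]
}

FREQ_BIN_LABELS <- c("<0.1%", "0.1-0.5%", "0.5-1%", "1-5%")

#' Classify an allele frequency into the four burden-analysis bins
#'
#' Bins: < 0.1%; 0.1-0.5%; 0.5-1%; 1-5%. Intervals are left-closed /
#' right-open except the first (which is right-open at 0.1%).
#'
#' @param frequency numeric vector of allele frequencies in [0, 0.05].
#' @param bins internal breakpoints; default c(0.001, 0.005, 0.01, 0.05).
#' @return character vector of bin labels.
#' @export
classifyFrequency <- function(frequency, bins = c(0.001, 0.005, 0.01, 0.05)) {
  if (any(is.na(frequency)) || any(frequency < 0 | frequency > bins[4L]))
    stopf("frequency outside [0, %g]", bins[4L])
  # left-closed/right-open bins via findInterval on the lower edges
  idx <- findInterval(frequency, c(-Inf, bins[1L], bins[2L], bins[3L]))
  FREQ_BIN_LABELS[idx]
}

#' Empirical quantile boundaries
#'
#' Internal cut points (k - 1 boundaries) for k equal-probability bins of
#' the supplied score values, using the type-7 linear-interpolation quantile
#' rule. The top bin is "strictly greater than the last boundary".
#'
#' @param values numeric vector (e.g. CADD scores of a gene's unique
#'   eligible variants in the training set).
#' @param k number of bins (>= 2).
#' @return numeric vector of k - 1 boundaries.
#' @export
quantileBoundaries <- function(values, k) {
  values <- values[!is.na(values)]
  if (length(unique(values)) < k)
    stopf("need at least %d distinct values", k)
  unname(quantile(values, probs = seq_len(k - 1L) / k, type = 7))
}

#' Dichotomize a Helix score
#'
#' High (predicted deleterious) iff score > cut; a score exactly at the cut
#' is assigned "low" (the published definition leaves the boundary
#' unassigned; low is the conservative choice).
#'
#' @param score numeric vector; missing scores raise an error (a variant
#'   without a Helix score cannot enter a Helix-based scheme).
#' @param cut threshold, default 0.5.
#' @return character vector, "high"/"low".
#' @export
helixClass <- function(score, cut = 0.5) {
  if (any(is.na(score))) stopf("missing Helix score")
  ifelse(score > cut, "high", "low")
}

newScheme <- function(gene, categories, baseline, params = list(),
                      descriptor = list()) {
  new("RiskScheme", gene = gene, categories = categories,
      baseline = baseline, params = params, descriptor = descriptor)
}

needScore <- function(x, what, ids) {
  if (any(is.na(x)))
    stopf("missing %s score for variant(s): %s", what,
          paste(head(ids[is.na(x)], 3L), collapse = ", "))
  x
}

#' Built-in per-gene risk-category schemes
#'
#' Construct the standard scheme for one of the five panel genes:
#' \describe{
#'   \item{ATM}{outside FAT/PIK; inside FAT or PIK and CADD quintiles 1-4;
#'     inside FAT or PIK and CADD quintile 5. `caddBoundary` is the Q4/Q5
#'     cut; the published boundary 3.736542 ships as the default, or pass a
#'     boundary computed by [quantileBoundaries()] on training data.}
#'   \item{BRCA1}{outside RING/BRCT; inside RING or BRCT and Helix-low;
#'     inside RING or BRCT and Helix-high.}
#'   \item{BRCA2, CHEK2}{Helix-low; Helix-high.}
#'   \item{PALB2}{a single category of all eligible carriers.}
#' }
#' With `layered = TRUE`, the functional-assay layered schemes:
#' \describe{
#'   \item{BRCA1}{SGE classes prioritized where available: INT/LOF-SGE;
#'     RING/BRCT + Helix-high (SGE missing); RING/BRCT + Helix-low (SGE
#'     missing); FUNC-SGE or outside domains.}
#'   \item{BRCA2}{HDR classification prioritized: LP/P; Helix-high
#'     (unassayed); Helix-low (unassayed); LB/B.}
#' }
#'
#' @param gene one of "ATM", "BRCA1", "BRCA2", "CHEK2", "PALB2".
#' @param caddBoundary ATM CADD Q4/Q5 boundary.
#' @param helixCut Helix dichotomy threshold.
#' @param rareThreshold eligibility frequency threshold.
#' @param layered use the functional-assay layered scheme (BRCA1/BRCA2).
#' @return a [RiskScheme-class].
#' @export
builtinScheme <- function(gene = c("ATM", "BRCA1", "BRCA2", "CHEK2", "PALB2"),
                          caddBoundary = 3.736542, helixCut = 0.5,
                          rareThreshold = 0.001, layered = FALSE) {
  gene <- match.arg(gene)
  params <- list(helix_cut = helixCut, rare_threshold = rareThreshold)
  inDomain <- function(v, doms) !is.na(v$domain) & v$domain %in% doms
  hx <- function(v) needScore(v$helix, "Helix", v$variant_id) > helixCut

  if (gene == "ATM") {
    params$cadd_boundary <- caddBoundary
    cats <- list(
      "outside_FAT_PIK" = function(v) !inDomain(v, c("FAT", "PIK")),
      "FAT_PIK_CADD1_4" = function(v)
        inDomain(v, c("FAT", "PIK")) &
          needScore(v$cadd, "CADD", v$variant_id) <= caddBoundary,
      "FAT_PIK_CADD5" = function(v)
        inDomain(v, c("FAT", "PIK")) &
          needScore(v$cadd, "CADD", v$variant_id) > caddBoundary)
    return(newScheme(gene, cats, "outside_FAT_PIK", params))
  }
  if (gene == "BRCA1" && !layered) {
    cats <- list(
      "outside_RING_BRCT" = function(v) !inDomain(v, c("RING", "BRCT")),
      "RING_BRCT_helix_low" = function(v) inDomain(v, c("RING", "BRCT")) & !hx(v),
      "RING_BRCT_helix_high" = function(v) inDomain(v, c("RING", "BRCT")) & hx(v))
    return(newScheme(gene, cats, "outside_RING_BRCT", params))
  }
  if (gene == "BRCA1" && layered) {
    cats <- list(
      "INT_LOF_SGE" = function(v)
        !is.na(v$sge_class) & v$sge_class %in% c("LOF", "INT"),
      "RING_BRCT_helix_high_SGE_missing" = function(v)
        is.na(v$sge_class) & inDomain(v, c("RING", "BRCT")) & hx(v),
      "RING_BRCT_helix_low_SGE_missing" = function(v)
        is.na(v$sge_class) & inDomain(v, c("RING", "BRCT")) & !hx(v),
      "FUNC_SGE_or_outside" = function(v)
        (!is.na(v$sge_class) & v$sge_class == "FUNC") |
          (is.na(v$sge_class) & !inDomain(v, c("RING", "BRCT"))))
    return(newScheme(gene, cats, "FUNC_SGE_or_outside", params))
  }
  if (gene == "BRCA2" && layered) {
    cats <- list(
      "LP_P_HDR" = function(v) !is.na(v$hdr_class) & v$hdr_class == "LP_P",
      "helix_high_unassayed" = function(v) is.na(v$hdr_class) & hx(v),
      "helix_low_unassayed" = function(v) is.na(v$hdr_class) & !hx(v),
      "LB_B_HDR" = function(v) !is.na(v$hdr_class) & v$hdr_class == "LB_B")
    return(newScheme(gene, cats, "LB_B_HDR", params))
  }
  if (gene %in% c("BRCA2", "CHEK2")) {
    cats <- list(
      "helix_low" = function(v) !hx(v),
      "helix_high" = function(v) hx(v))
    return(newScheme(gene, cats, "helix_low", params))
  }
  # PALB2: all eligible carriers in one category
  newScheme(gene, list(carriers = function(v) rep(TRUE, nrow(v))),
            "carriers", params)
}

#' Build a custom scheme from predicate functions
#'
#' @param gene gene symbol.
#' @param categories named list of functions over the variant data.frame,
#'   each returning a logical vector; they must partition the eligible set.
#' @param baseline reference category label.
#' @param params named list of constants.
#' @return a [RiskScheme-class].
#' @export
riskScheme <- function(gene, categories, baseline = names(categories)[1L],
                       params = list()) {
  newScheme(gene, categories, baseline, params)
}

#' Assign eligible variants of a gene to risk categories
#'
#' Applies the scheme's predicates to the gene's eligible rare missense
#' variants. Predicates must partition the eligible set: a variant matching
#' zero or more than one category raises a partition error naming it.
#'
#' @param catalog variant data.frame or Cohort.
#' @param scheme a [RiskScheme-class].
#' @return a [GroupAssignment-class].
#' @export
assignGroups <- function(catalog, scheme) {
  if (is(catalog, "Cohort")) catalog <- variants(catalog)
  thr <- scheme@params$rare_threshold %||% 0.001
  ids <- eligibleMissense(catalog, scheme@gene, thr)
  if (length(ids) == 0L) stopf("no eligible variants for gene '%s'", scheme@gene)
  v <- catalog[match(ids, catalog$variant_id), , drop = FALSE]
  hits <- vapply(scheme@categories, function(f) {
    h <- f(v)
    if (!is.logical(h) || length(h) != nrow(v))
      stopf("category predicate must return a logical vector over variants")
    h & !is.na(h)
  }, logical(nrow(v)))
  if (nrow(v) == 1L) hits <- matrix(hits, nrow = 1L,
                                    dimnames = list(NULL, names(scheme@categories)))
  nHit <- rowSums(hits)
  if (any(nHit != 1L)) {
    bad <- which(nHit != 1L)[1L]
    stopf("variant '%s' matches %d categories (must match exactly 1)",
          v$variant_id[bad], nHit[bad])
  }
  lab <- colnames(hits)[max.col(hits)]
  new("GroupAssignment", gene = scheme@gene,
      mapping = setNames(lab, v$variant_id), scheme = scheme)
}

# ---- YAML (de)serialization of schemes -------------------------------------
# Restricted declarative predicate grammar so users can define categories
# without code: each category is a list of AND-ed conditions with fields
#   domain_in / domain_not_in: [labels]      ("none" matches no-domain)
#   score: {name, op (gt|le|lt|ge), value}
#   helix: high|low
#   sge_in: [classes] | sge_missing: true
#   hdr_in: [classes] | hdr_missing: true
#   clinvar_in: [classes]
#   all: true

conditionToPredicate <- function(cond, params) {
  force(cond)
  helixCut <- params$helix_cut %||% 0.5
  function(v) {
    ok <- rep(TRUE, nrow(v))
    if (!is.null(cond$all)) return(ok)
    if (!is.null(cond$domain_in))
      ok <- ok & !is.na(v$domain) & v$domain %in% unlist(cond$domain_in)
    if (!is.null(cond$domain_not_in))
      ok <- ok & !(!is.na(v$domain) & v$domain %in% unlist(cond$domain_not_in))
    if (!is.null(cond$score)) {
      sc <- needScore(v[[cond$score$name]], cond$score$name, v$variant_id)
      ok <- ok & switch(cond$score$op,
        gt = sc > cond$score$value, ge = sc >= cond$score$value,
        lt = sc < cond$score$value, le = sc <= cond$score$value,
        stopf("unknown score op '%s'", cond$score$op))
    }
    if (!is.null(cond$helix)) {
      cls <- helixClass(needScore(v$helix, "Helix", v$variant_id), helixCut)
      ok <- ok & cls == cond$helix
    }
    if (!is.null(cond$sge_in))
      ok <- ok & !is.na(v$sge_class) & v$sge_class %in% unlist(cond$sge_in)
    if (isTRUE(cond$sge_missing)) ok <- ok & is.na(v$sge_class)
    if (!is.null(cond$hdr_in))
      ok <- ok & !is.na(v$hdr_class) & v$hdr_class %in% unlist(cond$hdr_in)
    if (isTRUE(cond$hdr_missing)) ok <- ok & is.na(v$hdr_class)
    if (!is.null(cond$clinvar_in))
      ok <- ok & !is.na(v$clinvar_class) &
        v$clinvar_class %in% unlist(cond$clinvar_in)
    ok
  }
}

#' Read a risk scheme from YAML
#'
#' The YAML document carries `gene`, `baseline`, optional `params`
#' (helix_cut, cadd_boundary, rare_threshold) and a `categories` map of
#' label -> condition list in the declarative grammar documented in the
#' package vignette.
#'
#' @param path YAML file path.
#' @return a [RiskScheme-class].
#' @export
schemeFromYaml <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$gene) || is.null(doc$categories))
    stopf("scheme YAML must contain 'gene' and 'categories'")
  params <- doc$params %||% list()
  cats <- lapply(doc$categories, conditionToPredicate, params = params)
  names(cats) <- names(doc$categories)
  newScheme(doc$gene, cats, doc$baseline %||% names(cats)[1L], params,
            descriptor = doc$categories)
}

#' Write a declarative risk scheme to YAML
#'
#' Only schemes built from the declarative grammar (i.e. read with
#' [schemeFromYaml()] or constructed with a descriptor) can be serialized;
#' hand-written function predicates have no declarative form.
#'
#' @param scheme a [RiskScheme-class] carrying a descriptor.
#' @param path output path.
#' @export
schemeToYaml <- function(scheme, path) {
  if (length(scheme@descriptor) == 0L)
    stopf("scheme has no declarative descriptor; cannot serialize")
  yaml::write_yaml(list(gene = scheme@gene, baseline = scheme@baseline,
                        params = scheme@params,
                        categories = scheme@descriptor), path)
  invisible(path)
}
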
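#' Per-gene simulation configuration
#'
#' @param gene gene symbol.
#' @param categories list of category descriptors, each a list with
#'   `label`, `n_variants`, `alpha` (prior proportion of risk-associated
#'   variants in [0,1]) and `template` (annotation template: optional
#'   `domain` labels to sample from, `cadd_range`, `helix_range`).
#' @param orMissense odds ratio of risk-associated (pathogenic) missense
#'   carriers.
#' @param orPtv odds ratio of PTV carriers.
#' @param ptvCarrierFreq PTV carrier probability.
#' @param freqDist log-uniform allele-frequency bounds, within (0, 0.05].
#' @return list of class "GeneSimConfig".
#' @export
geneSimConfig <- function(gene, categories, orMissense, orPtv,
                          ptvCarrierFreq, freqDist = c(1e-7, 2e-4)) {
  stopifnot(orMissense > 0, orPtv > 0,
            ptvCarrierFreq >= 0, ptvCarrierFreq < 1,
            length(freqDist) == 2L, freqDist[1L] > 0,
            freqDist[2L] <= 0.05, freqDist[1L] < freqDist[2L])
  for (cc in categories) {
    stopifnot(!is.null(cc$label), !is.null(cc$n_variants),
              !is.null(cc$alpha))
    if (cc$alpha < 0 || cc$alpha > 1) stopf("alpha must be in [0,1]")
  }
  structure(list(gene = gene, categories = categories,
                 orMissense = orMissense, orPtv = orPtv,
                 ptvCarrierFreq = ptvCarrierFreq, freqDist = freqDist),
            class = "GeneSimConfig")
}

#' Cohort simulation configuration
#'
#' @param genes list of [geneSimConfig()] objects.
#' @param strata data.frame with columns label, baseline (case log-odds in
#'   the prospective population), prop (sampling proportion) and design
#'   ("population"/"familial").
#' @param poolN prospective pool size.
#' @param targetCases,targetControls retrospective sample sizes.
#' @param familialOversample case inclusion-probability multiplier for
#'   familial-design strata (>= 1).
#' @param seed default seed used when none is passed to the simulators.
#' @return list of class "SimulationConfig".
#' @export
simulationConfig <- function(genes, strata, poolN, targetCases,
                             targetControls, familialOversample = 1,
                             seed = 20220518) {
  stopifnot(poolN > 0, targetCases > 0, targetControls > 0,
            familialOversample >= 1,
            all(c("label", "baseline", "prop", "design") %in% names(strata)))
  structure(list(genes = genes, strata = strata, poolN = poolN,
                 targetCases = targetCases, targetControls = targetControls,
                 familialOversample = familialOversample, seed = seed),
            class = "SimulationConfig")
}

# annotation templates for the built-in risk-category schemes
CADD_Q5_BOUNDARY <- 3.736542

defaultTemplates <- function() {
  list(
    outside_FAT_PIK = list(domain = "none", cadd_range = c(-3, 8),
                           helix_range = c(0, 1)),
    FAT_PIK_CADD1_4 = list(domain = c("FAT", "PIK"),
                           cadd_range = c(-3, CADD_Q5_BOUNDARY),
                           helix_range = c(0, 1)),
    FAT_PIK_CADD5 = list(domain = c("FAT", "PIK"),
                         cadd_range = c(CADD_Q5_BOUNDARY, 12),
                         helix_range = c(0, 1)),
    outside_RING_BRCT = list(domain = "none", cadd_range = c(-3, 8),
                             helix_range = c(0, 1)),
    RING_BRCT_helix_low = list(domain = c("RING", "BRCT"),
                               cadd_range = c(-3, 8),
                               helix_range = c(0, 0.5)),
    RING_BRCT_helix_high = list(domain = c("RING", "BRCT"),
                                cadd_range = c(-3, 8),
                                helix_range = c(0.5, 1)),
    helix_low = list(domain = "none", cadd_range = c(-3, 8),
                     helix_range = c(0, 0.5)),
    helix_high = list(domain = "none", cadd_range = c(-3, 8),
                      helix_range = c(0.5, 1)),
    carriers = list(domain = "none", cadd_range = c(-3, 8),
                    helix_range = c(0, 1)))
}

#' Default simulation configuration at published study scale
#'
#' Genes, category labels, variant counts, alpha values and odds ratios
#' mirror the reference population-training summary table
#' ([referenceRiskGroups()]): e.g. ATM with alpha 0.54 in the
#' FAT/PIK + CADD-Q5 category and constrained OR 2.16, CHEK2 with alpha
#' 0.95 / 0.33 and unconstrained missense OR 1.75, PALB2 with alpha near
#' zero. The CHEK2 PTV odds ratio (2.5) and the per-gene PTV carrier
#' frequencies are set to field-standard values since the summary table
#' fixes only the missense parameters. Six population strata with
#' prospective baseline case log-odds near logit(0.1) are scaled so the
#' retrospective targets (35,500 cases / 39,000 controls) are attainable
#' from the default pool of 420,000.
#'
#' @param poolN prospective pool size (default 420000).
#' @return a [simulationConfig()].
#' @export
defaultSimConfig <- function(poolN = 420000) {
  ref <- referenceRiskGroups()
  tmpl <- defaultTemplates()
  ptvFreq <- c(ATM = 0.0034, BRCA1 = 0.0014, BRCA2 = 0.0031,
               CHEK2 = 0.0050, PALB2 = 0.0013)
  genes <- lapply(unique(ref$gene), function(g) {
    rows <- ref[ref$gene == g & ref$category != "noncarrier", , drop = FALSE]
    cats <- lapply(seq_len(nrow(rows)), function(i) {
      list(label = rows$category[i], n_variants = rows$n_variants[i],
           alpha = rows$alpha[i], template = tmpl[[rows$category[i]]])
    })
    constrained <- rows$constrained[1L]
    geneSimConfig(g, cats, orMissense = rows$mix_or[1L],
                  orPtv = if (constrained) rows$mix_or[1L] else 2.5,
                  ptvCarrierFreq = unname(ptvFreq[g]))
  })
  strata <- data.frame(
    label = c("UK", "Germany", "Denmark", "Sweden", "USA", "Singapore"),
    baseline = qlogis(c(0.11, 0.10, 0.09, 0.10, 0.12, 0.08)),
    prop = c(0.30, 0.22, 0.16, 0.14, 0.10, 0.08),
    design = "population",
    stringsAsFactors = FALSE)
  simulationConfig(genes, strata, poolN = poolN, targetCases = 35500,
                   targetControls = 39000)
}

#' Simulate a variant catalog with latent pathogenicity
#'
#' Per category, each variant's latent risk status is Bernoulli(alpha);
#' allele frequencies are log-uniform within the gene's bounds; domain and
#' score annotations are drawn from the category template so the built-in
#' scheme predicates reproduce the intended category labels. One PTV
#' record per gene is added (frequency = PTV carrier frequency / 2).
#'
#' @param config a [simulationConfig()].
#' @param seed integer seed (default from config).
#' @return list(catalog = variant data.frame, truth = named logical;
#'   truth is for test assertions only and is never used by the fitters).
#' @export
simulateCatalog <- function(config, seed = config$seed) {
  withSeed(seed, {
    rows <- list(); truth <- logical(0)
    for (gc in config$genes) {
      for (cc in gc$categories) {
        n <- cc$n_variants
        ids <- sprintf("%s_%s_%04d", gc$gene, cc$label, seq_len(n))
        tm <- cc$template %||% list()
        dom <- sample(tm$domain %||% "none", n, replace = TRUE)
        cr <- tm$cadd_range %||% c(-3, 8)
        hr <- tm$helix_range %||% c(0, 1)
        freq <- exp(runif(n, log(gc$freqDist[1L]), log(gc$freqDist[2L])))
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gc$gene, variant_id = ids, consequence = "missense",
          frequency = freq, cadd = runif(n, cr[1L], cr[2L]),
          helix = runif(n, hr[1L], hr[2L]), bayesdel = NA_real_,
          revel = NA_real_, align_gvgd = NA_real_, domain = dom,
          splice_excluded = FALSE, sge_class = NA_character_,
          hdr_class = NA_character_, clinvar_class = NA_character_,
          stringsAsFactors = FALSE)
        truth <- c(truth, setNames(as.logical(rbinom(n, 1L, cc$alpha)), ids))
      }
      if (gc$ptvCarrierFreq > 0) {
        pid <- paste0(gc$gene, "_ptv")
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gc$gene, variant_id = pid, consequence = "PTV",
          frequency = gc$ptvCarrierFreq / 2, cadd = NA_real_,
          helix = NA_real_, bayesdel = NA_real_, revel = NA_real_,
          align_gvgd = NA_real_, domain = "none", splice_excluded = FALSE,
          sge_class = NA_character_, hdr_class = NA_character_,
          clinvar_class = NA_character_, stringsAsFactors = FALSE)
        truth <- c(truth, setNames(TRUE, pid))
      }
    }
    list(catalog = do.call(rbind, rows), truth = truth)
  })
}

#' Simulate a retrospective case-control cohort
#'
#' Prospective simulation followed by retrospective sampling: subjects are
#' assigned strata, carrier status is drawn per gene from variant
#' frequencies (carrier probability twice the allele frequency; at most
#' one eligible missense variant per gene per subject by construction),
#' disease status follows a logistic model with the stratum baseline plus
#' log(orMissense) for carriers of a truly risk-associated missense
#' variant and log(orPtv) for PTV carriers (a subject with both a PTV and
#' a missense variant of a gene counts as a PTV carrier). Cases and
#' controls are then sampled to the target counts, with the case inclusion
#' probability multiplied by `familialOversample` in familial-design
#' strata.
#'
#' @param catalog,truth from [simulateCatalog()].
#' @param config a [simulationConfig()].
#' @param seed integer seed (default from config, offset so catalog and
#'   cohort draws differ).
#' @return a [Cohort-class].
#' @export
simulateCohort <- function(catalog, truth, config, seed = config$seed + 1) {
  withSeed(seed, {
    n <- config$poolN
    st <- config$strata
    stratum <- sample(st$label, n, replace = TRUE, prob = st$prop)
    si <- match(stratum, st$label)
    eta <- st$baseline[si]
    design <- st$design[si]

    carriedIdx <- vector("list", length(config$genes) * 2L)
    carriedIds <- vector("list", length(config$genes) * 2L)
    k <- 0L
    for (gc in config$genes) {
      mis <- catalog[catalog$gene == gc$gene &
                     catalog$consequence == "missense", , drop = FALSE]
      pTot <- sum(2 * mis$frequency)
      if (pTot >= 1) stopf("missense carrier probability >= 1 for %s", gc$gene)
      isCarrier <- runif(n) < pTot
      idx <- which(isCarrier)
      vid <- mis$variant_id[sample.int(nrow(mis), length(idx), replace = TRUE,
                                       prob = mis$frequency)]
      isPtv <- runif(n) < gc$ptvCarrierFreq
      pidx <- which(isPtv)
      patho <- truth[vid]
      # PTV status dominates: missense effect only for non-PTV carriers
      misEffect <- rep(0, n)
      misEffect[idx[patho]] <- log(gc$orMissense)
      misEffect[pidx] <- 0
      eta <- eta + misEffect
      eta[pidx] <- eta[pidx] + log(gc$orPtv)
      k <- k + 1L
      carriedIdx[[k]] <- idx; carriedIds[[k]] <- vid
      if (length(pidx)) {
        k <- k + 1L
        carriedIdx[[k]] <- pidx
        carriedIds[[k]] <- rep(paste0(gc$gene, "_ptv"), length(pidx))
      }
    }
    y <- rbinom(n, 1L, plogis(eta))
    caseIdx <- which(y == 1L); ctlIdx <- which(y == 0L)
    if (length(caseIdx) < config$targetCases ||
        length(ctlIdx) < config$targetControls)
      stopf(paste("prospective pool yielded %d cases / %d controls;",
                  "increase poolN to reach the targets"),
            length(caseIdx), length(ctlIdx))
    wCase <- ifelse(design[caseIdx] == "familial",
                    config$familialOversample, 1)
    selCase <- caseIdx[sample.int(length(caseIdx), config$targetCases,
                                  prob = wCase)]
    selCtl <- ctlIdx[sample.int(length(ctlIdx), config$targetControls)]
    sel <- c(selCase, selCtl)

    # carried list for the sampled subjects only
    allIdx <- unlist(carriedIdx[seq_len(k)], use.names = FALSE)
    allIds <- unlist(carriedIds[seq_len(k)], use.names = FALSE)
    pos <- match(allIdx, sel)
    keep <- !is.na(pos)
    carried <- split(allIds[keep], factor(pos[keep], levels = seq_along(sel)))
    carried <- unname(lapply(carried, as.character))

    age <- round(pmin(pmax(rnorm(length(sel), 55, 10), 25), 85))
    subjectsDf <- data.frame(
      subject_id = sprintf("S%07d", seq_along(sel)),
      stratum = stratum[sel],
      status = rep(c("case", "control"),
                   c(config$targetCases, config$targetControls)),
      age = age,
      design = design[sel],
      stringsAsFactors = FALSE)
    subjectsDf$carried <- carried
    Cohort(subjectsDf, catalog)
  })
}
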
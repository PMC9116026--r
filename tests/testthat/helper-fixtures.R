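# shared fixture builders; everything is generated in code at test time

`%||%` <- function(x, y) if (is.null(x)) y else x

tinyVariants <- function() {
  data.frame(
    gene = c("ATM", "ATM", "BRCA1"),
    variant_id = c("ATM:c.1A>G", "ATM:c.2C>T", "BRCA1:c.3G>A"),
    consequence = c("missense", "PTV", "missense"),
    frequency = c(5e-4, 2e-4, 8e-5),
    cadd = c(4.1, NA, 1.2),
    helix = c(0.9, NA, 0.3),
    bayesdel = NA_real_, revel = NA_real_, align_gvgd = NA_real_,
    domain = c("FAT", "none", "RING"),
    splice_excluded = FALSE,
    sge_class = NA_character_, hdr_class = NA_character_,
    clinvar_class = NA_character_,
    stringsAsFactors = FALSE)
}

tinySubjects <- function() {
  s <- data.frame(
    subject_id = paste0("S", 1:5),
    stratum = c("UK", "UK", "DE", "DE", "UK"),
    status = c("case", "control", "case", "control", "case"),
    age = c(45, 60, NA, 52, 38),
    design = c("population", "population", "familial", "population",
               "population"),
    stringsAsFactors = FALSE)
  s$carried <- list("ATM:c.1A>G", character(0), c("ATM:c.2C>T", "BRCA1:c.3G>A"),
                    "BRCA1:c.3G>A", character(0))
  s
}

tinyCohort <- function() Cohort(tinySubjects(), tinyVariants())

writeTinyFiles <- function(dir = tempfile()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeCohort(tinyCohort(), dir)
}

# a cohort realizing exact per-category carrier counts in a single stratum;
# cats: named list label -> c(cases, controls, helix, domain)
countCohort <- function(gene, catDefs, nonCase, nonCtl, stratum = "X") {
  vrows <- lapply(names(catDefs), function(lb) {
    d <- catDefs[[lb]]
    data.frame(gene = gene, variant_id = paste0(gene, ":", lb),
               consequence = "missense", frequency = 5e-4,
               cadd = d$cadd %||% 1, helix = d$helix %||% 0.2,
               bayesdel = NA_real_, revel = NA_real_, align_gvgd = NA_real_,
               domain = d$domain %||% "none", splice_excluded = FALSE,
               sge_class = NA_character_, hdr_class = NA_character_,
               clinvar_class = NA_character_, stringsAsFactors = FALSE)
  })
  catalog <- do.call(rbind, vrows)
  status <- c(rep("case", nonCase), rep("control", nonCtl))
  carried <- rep(list(character(0)), nonCase + nonCtl)
  for (lb in names(catDefs)) {
    d <- catDefs[[lb]]
    vid <- paste0(gene, ":", lb)
    status <- c(status, rep("case", d$cases), rep("control", d$controls))
    carried <- c(carried, rep(list(vid), d$cases + d$controls))
  }
  s <- data.frame(subject_id = sprintf("S%06d", seq_along(status)),
                  stratum = stratum, status = status, age = 50,
                  design = "population", stringsAsFactors = FALSE)
  s$carried <- carried
  Cohort(s, catalog)
}

# compact two-category single-gene simulation config for fast runs
smallSimConfig <- function(alphaLow = 0.3, alphaHigh = 0.9, orMis = 1.8,
                           orPtv = 2.5, nLow = 60, nHigh = 50,
                           ptvFreq = 0.004, poolN = 60000,
                           nCase = 5000, nCtl = 5500,
                           freqDist = c(1e-6, 4e-4),
                           gene = "CHEK2", strata = NULL,
                           familialOversample = 1) {
  g <- geneSimConfig(gene, categories = list(
    list(label = "helix_low", n_variants = nLow, alpha = alphaLow,
         template = list(domain = "none", helix_range = c(0, 0.5))),
    list(label = "helix_high", n_variants = nHigh, alpha = alphaHigh,
         template = list(domain = "none", helix_range = c(0.5, 1)))),
    orMissense = orMis, orPtv = orPtv, ptvCarrierFreq = ptvFreq,
    freqDist = freqDist)
  if (is.null(strata))
    strata <- data.frame(label = c("A", "B"),
                         baseline = qlogis(c(0.10, 0.12)),
                         prop = c(0.6, 0.4), design = "population",
                         stringsAsFactors = FALSE)
  simulationConfig(list(g), strata, poolN = poolN, targetCases = nCase,
                   targetControls = nCtl,
                   familialOversample = familialOversample)
}

simSmallCohort <- function(seed, ...) {
  cfg <- smallSimConfig(...)
  ct <- simulateCatalog(cfg, seed)
  list(cohort = simulateCohort(ct$catalog, ct$truth, cfg, seed + 1),
       truth = ct$truth, config = cfg)
}

chek2Scheme <- function() builtinScheme("CHEK2")

# fully-specified micro cohort for exact mixture checks:
# 2 variants, 8 subjects, single stratum, no PTVs
microCohort <- function() {
  vdf <- data.frame(gene = "G", variant_id = c("v1", "v2"),
                    consequence = "missense", frequency = 5e-4,
                    helix = c(0.8, 0.2), stringsAsFactors = FALSE)
  sdf <- data.frame(subject_id = paste0("s", 1:8), stratum = "X",
                    status = c("case", "case", "control", "case", "control",
                               "case", "control", "control"),
                    age = 50, design = "population", stringsAsFactors = FALSE)
  sdf$carried <- list("v1", "v1", "v1", "v2", "v2",
                      character(0), character(0), character(0))
  Cohort(sdf, vdf)
}

microAssignment <- function(coh) {
  assignGroups(variants(coh),
               riskScheme("G", list(all = function(v) rep(TRUE, nrow(v))),
                          "all"))
}

# independent oracle: observed-data log-likelihood by explicit two-component
# marginalization per variant (no strata)
microLoglik <- function(alpha, beta, mu) {
  ycar <- list(v1 = c(1, 1, 0), v2 = c(1, 0))
  tot <- log(plogis(mu)) + 2 * log(1 - plogis(mu))  # s6 case, s7/s8 controls
  for (v in names(ycar)) {
    y <- ycar[[v]]
    lik <- function(b) prod(plogis(mu + b)^y * (1 - plogis(mu + b))^(1 - y))
    tot <- tot + log(alpha * lik(beta) + (1 - alpha) * lik(0))
  }
  tot
}
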
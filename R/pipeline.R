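# posterior-weighted carrier alpha among training cases / controls, the
# ingredients of the validation-set adjusted alpha
trainingCarrierAlpha <- function(fit) {
  cnt <- fit@details$counts
  cats <- colnames(fit@alpha)
  post <- rowSums(fit@posteriors[cnt$carriedIds, , drop = FALSE])
  catV <- factor(cnt$category, levels = cats)
  nCase <- rowSums(cnt$Vcase); nCtl <- rowSums(cnt$Vctl)
  byCat <- function(w) {
    num <- tapply(post * w, catV, sum)
    den <- tapply(w, catV, sum)
    out <- as.numeric(num) / as.numeric(den)
    setNames(out, cats)
  }
  list(case = byCat(nCase), control = byCat(nCtl))
}

defaultMixtureModes <- function(genes) {
  modes <- setNames(rep("constrained", length(genes)), genes)
  modes[genes == "CHEK2"] <- "unconstrained"
  modes
}

#' Run the full analysis pipeline
#'
#' Orchestrates: data acquisition (simulation or TSV input), the
#' training/validation split, subject filtering, per-gene risk grouping,
#' logistic burden models, mixture-model fits (PTV carriers re-included),
#' validation calibration with fixed training effect sizes, the composite
#' multi-gene model, and the familial relative risk decomposition. All
#' result tables are written as TSV with a JSON manifest, plus a run
#' metadata file recording the seed, a configuration digest and the
#' package version. Reported training estimates use population-design
#' subjects only.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{simulate}{a [simulationConfig()] (or the string "default"),
#'       mutually exclusive with `input`.}
#'     \item{input}{list(variants, subjects) file paths.}
#'     \item{schemes}{optional named list gene -> [RiskScheme-class]
#'       (default [builtinScheme()] per gene).}
#'     \item{split}{list(fraction, eligibleStrata); default 0.2 and all
#'       population strata.}
#'     \item{mixtureModes}{optional named character gene -> mode; default
#'       constrained everywhere except CHEK2 (unconstrained).}
#'     \item{outDir}{output directory.}
#'     \item{seed}{integer seed for split and simulation.}
#'   }
#' @return manifest data.frame (invisibly also written to outDir).
#' @export
runPipeline <- function(config) {
  if (is.null(config$outDir)) stopf("config$outDir is required")
  if (is.null(config$seed)) stopf("config$seed is required")
  seed <- config$seed

  if (!is.null(config$schemes) && !is.null(names(config$schemes))) {
    for (nm in names(config$schemes))
      if (!is(config$schemes[[nm]], "RiskScheme"))
        stopf("scheme for '%s' is not a RiskScheme", nm)
  }

  if (!is.null(config$input)) {
    for (p in unlist(config$input))
      if (!file.exists(p)) stopf("configuration error: missing input '%s'", p)
    cohort <- readCohort(config$input$variants, config$input$subjects)
    truth <- NULL
  } else {
    sim <- config$simulate %||% "default"
    if (identical(sim, "default")) sim <- defaultSimConfig()
    cat <- simulateCatalog(sim, seed)
    cohort <- simulateCohort(cat$catalog, cat$truth, sim, seed + 1)
    truth <- cat$truth
  }

  genes <- config$genes %||% unique(variants(cohort)$gene)
  schemes <- config$schemes %||%
    setNames(lapply(genes, function(g) builtinScheme(g)), genes)
  modes <- config$mixtureModes %||% defaultMixtureModes(genes)

  split <- config$split %||% list()
  fraction <- split$fraction %||% 0.2
  eligible <- split$eligibleStrata %||%
    unique(subjects(cohort)$stratum[subjects(cohort)$design == "population"])
  parts <- splitTrainValidation(cohort, fraction, eligible, seed + 2)
  training <- parts$training
  validation <- filterSubjects(parts$validation, dropPtvCarriersIn = genes,
                               dropMultiMissenseGenes = TRUE)

  # population-design training subjects drive the reported estimates
  popTraining <- Cohort(
    subjects(training)[subjects(training)$design == "population", ,
                       drop = FALSE],
    variants(training), metadata = training@metadata)
  lrTraining <- filterSubjects(popTraining, dropPtvCarriersIn = genes,
                               dropMultiMissenseGenes = TRUE)

  tables <- list()
  frrRows <- list()
  assignments <- list()
  for (g in genes) {
    a <- assignGroups(variants(cohort), schemes[[g]])
    assignments[[g]] <- a
    burden <- groupBurden(lrTraining, a)
    tables[[paste0("burden_", g)]] <- burden
    spec <- mixtureSpec(g, mode = modes[[g]])
    fit <- fitMixture(popTraining, a, spec)
    ctrlAlpha <- suppressWarnings(controlOnlyAlpha(fit))
    alphaRow <- if (is.matrix(ctrlAlpha)) ctrlAlpha[1L, ] else ctrlAlpha
    mixTab <- data.frame(
      category = colnames(fit@alpha),
      alpha_naive = as.numeric(fit@alpha[1L, ]),
      alpha_control_only = as.numeric(alphaRow),
      or_missense = exp(fit@betaMis), or_ptv = exp(fit@betaPtv),
      loglik = max(fit@loglikTrace), converged = fit@converged,
      stringsAsFactors = FALSE)
    tables[[paste0("mixture_", g)]] <- mixTab

    ca <- trainingCarrierAlpha(fit)
    valS <- subjects(validation)
    valCaseFrac <- mean(valS$status == "case")
    aVal <- adjustedAlpha(ifelse(is.na(ca$case), 0, ca$case),
                          ifelse(is.na(ca$control), 0, ca$control),
                          valCaseFrac)
    rep <- tryCatch(
      calibrationGof(validation, a,
                     list(type = "mixture", alpha = aVal,
                          beta = fit@betaMis)),
      error = function(e) NULL)
    if (!is.null(rep)) {
      tb <- rep@table
      tb$chi_sq <- rep@chiSq; tb$df <- rep@df; tb$p_gof <- rep@p
      tables[[paste0("validation_", g)]] <- tb
    }
    pp <- setNames(rowSums(fit@posteriors), rownames(fit@posteriors))
    tables[[paste0("pp_or_", g)]] <- ppWeightedOr(validation, a, pp,
                                                  fit@betaMis)
    post <- data.frame(variant_id = rownames(fit@posteriors),
                       category = fit@details$category[rownames(fit@posteriors)],
                       posterior = rowSums(fit@posteriors),
                       stringsAsFactors = FALSE)
    tables[[paste0("posteriors_", g)]] <- post

    cnt <- fit@details$counts
    ctl <- as.numeric(tapply(rowSums(cnt$Vctl),
                             factor(cnt$category,
                                    levels = colnames(fit@alpha)), sum))
    ctl[is.na(ctl)] <- 0
    cse <- as.numeric(tapply(rowSums(cnt$Vcase),
                             factor(cnt$category,
                                    levels = colnames(fit@alpha)), sum))
    cse[is.na(cse)] <- 0
    stats <- pathogenicCarrierStats(
      caseCarriers = cse, controlCarriers = ctl,
      nonCarrierCases = sum(cnt$ncCase), nonCarrierControls = sum(cnt$ncCtl),
      alpha = as.numeric(ifelse(is.na(alphaRow), fit@alpha[1L, ], alphaRow)),
      orMissense = exp(fit@betaMis))
    frrRows[[g]] <- data.frame(gene = g, p = stats$control_frequency / 2,
                               r = exp(fit@betaMis), stringsAsFactors = FALSE)
  }

  comp <- compositeFit(validation, assignments)
  compTab <- comp@table
  compTab$excluded_multigene <- comp@excludedMultigene
  tables[["composite_validation"]] <- compTab
  tables[["frr"]] <- frrTable(do.call(rbind, frrRows))

  manifest <- writeReport(tables, config$outDir)
  meta <- list(seed = seed,
               package_version = as.character(packageVersion("missenseRisk")),
               config_digest = configDigest(config),
               n_training = nSubjects(training),
               n_validation = nSubjects(validation))
  jsonlite::write_json(meta, file.path(config$outDir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

configDigest <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config[setdiff(names(config), "outDir")], tmp)
  unname(tools::md5sum(tmp))
}
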
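test_that("latent pathogenicity follows the category alpha exactly at the extremes", {
  cfg1 <- smallSimConfig(alphaLow = 1, alphaHigh = 0)
  ct <- simulateCatalog(cfg1, 5)
  lows <- grep("helix_low", names(ct$truth), value = TRUE)
  highs <- grep("helix_high", names(ct$truth), value = TRUE)
  expect_true(all(ct$truth[lows]))
  expect_false(any(ct$truth[highs]))
})

test_that("catalog and cohort generation are deterministic for a fixed seed", {
  cfg <- smallSimConfig(poolN = 20000, nCase = 1500, nCtl = 1500)
  c1 <- simulateCatalog(cfg, 77)
  c2 <- simulateCatalog(cfg, 77)
  expect_identical(c1, c2)
  coh1 <- simulateCohort(c1$catalog, c1$truth, cfg, 78)
  coh2 <- simulateCohort(c2$catalog, c2$truth, cfg, 78)
  expect_identical(subjects(coh1), subjects(coh2))
  coh3 <- simulateCohort(c1$catalog, c1$truth, cfg, 79)
  expect_false(identical(subjects(coh1)$carried, subjects(coh3)$carried))
})

test_that("simulated annotations reproduce the intended category labels", {
  cfg <- smallSimConfig()
  ct <- simulateCatalog(cfg, 7)
  a <- assignGroups(ct$catalog, chek2Scheme())
  expected <- ifelse(grepl("helix_low", names(a@mapping)),
                     "helix_low", "helix_high")
  expect_equal(unname(a@mapping), expected)
})

test_that("null effects give equal carrier frequencies in cases and controls", {
  diffs <- vapply(1:12, function(r) {
    res <- simSmallCohort(300 + r, alphaLow = 0.5, alphaHigh = 0.5,
                          orMis = 1, orPtv = 1, poolN = 20000,
                          nCase = 2000, nCtl = 2000)
    s <- subjects(res$cohort)
    carrier <- vapply(s$carried, function(ids) any(grepl("helix", ids)),
                      logical(1L))
    mean(carrier[s$status == "case"]) - mean(carrier[s$status == "control"])
  }, numeric(1L))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se + 1e-12)
})

test_that("no subject carries two eligible missense variants of one gene", {
  res <- simSmallCohort(320, poolN = 30000, nCase = 2500, nCtl = 2500)
  v <- variants(res$cohort)
  mis <- v$variant_id[v$consequence == "missense"]
  nPerGene <- vapply(subjects(res$cohort)$carried,
                     function(ids) sum(ids %in% mis), integer(1L))
  expect_true(all(nPerGene <= 1L))
})

test_that("unreachable retrospective targets fail with advice", {
  cfg <- smallSimConfig(poolN = 2000, nCase = 1900, nCtl = 1900)
  ct <- simulateCatalog(cfg, 9)
  expect_error(simulateCohort(ct$catalog, ct$truth, cfg, 10), "poolN")
})

test_that("familial oversampling enriches familial-design cases", {
  strata <- data.frame(label = c("POP", "FAM"),
                       baseline = qlogis(c(0.1, 0.1)),
                       prop = c(0.5, 0.5),
                       design = c("population", "familial"),
                       stringsAsFactors = FALSE)
  cfgF <- smallSimConfig(poolN = 30000, nCase = 2000, nCtl = 2000,
                         strata = strata)
  cfgF$familialOversample <- 4
  ct <- simulateCatalog(cfgF, 11)
  coh <- simulateCohort(ct$catalog, ct$truth, cfgF, 12)
  s <- subjects(coh)
  famShareCases <- mean(s$design[s$status == "case"] == "familial")
  famShareCtls <- mean(s$design[s$status == "control"] == "familial")
  expect_gt(famShareCases, famShareCtls + 0.1)
})

test_that("the default configuration mirrors the reference summary table", {
  cfg <- defaultSimConfig()
  genes <- vapply(cfg$genes, `[[`, "", "gene")
  expect_setequal(genes, c("ATM", "BRCA1", "BRCA2", "CHEK2", "PALB2"))
  atm <- cfg$genes[[which(genes == "ATM")]]
  top <- atm$categories[[which(vapply(atm$categories, `[[`, "", "label") ==
                               "FAT_PIK_CADD5")]]
  expect_equal(top$alpha, 0.54)
  expect_equal(atm$orMissense, 2.16)
  chek2 <- cfg$genes[[which(genes == "CHEK2")]]
  expect_equal(chek2$orMissense, 1.75)
  expect_gt(chek2$orPtv, chek2$orMissense)  # unconstrained gene
  brca1 <- cfg$genes[[which(genes == "BRCA1")]]
  expect_equal(brca1$orMissense, 10.61)
  palb2 <- cfg$genes[[which(genes == "PALB2")]]
  alphas <- vapply(palb2$categories, `[[`, 1, "alpha")
  expect_true(all(alphas < 0.001))
})

test_that("carrier odds ratios converge to the generating value with size", {
  # crude carrier OR of truly pathogenic variants approaches orMissense
  est <- vapply(c(20000, 80000), function(pool) {
    res <- simSmallCohort(400, alphaLow = 0.5, alphaHigh = 0.5, orMis = 2.2,
                          orPtv = 2.2, ptvFreq = 0, poolN = pool,
                          nCase = round(pool * 0.08),
                          nCtl = round(pool * 0.08))
    s <- subjects(res$cohort)
    patho <- names(res$truth)[res$truth]
    carrier <- vapply(s$carried, function(ids) any(ids %in% patho),
                      logical(1L))
    isCase <- s$status == "case"
    (sum(carrier & isCase) * sum(!carrier & !isCase)) /
      (sum(carrier & !isCase) * sum(!carrier & isCase))
  }, numeric(1L))
  expect_lt(abs(log(est[2]) - log(2.2)), abs(log(est[1]) - log(2.2)) + 0.25)
  expect_lt(abs(log(est[2]) - log(2.2)), 0.2)
})
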
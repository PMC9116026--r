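test_that("nuisance refit with zero offsets reduces to the covariate-only fit", {
  res <- simSmallCohort(201, poolN = 20000, nCase = 1500, nCtl = 1500)
  coh <- res$cohort
  a <- assignGroups(variants(coh), chek2Scheme())
  f0 <- refitNuisance(coh, a, c(helix_low = 0, helix_high = 0))
  s <- subjects(coh)
  plain <- fitLogistic(s$status, missenseRisk:::stratumDesign(s$stratum))
  expect_equal(coef(f0), coef(plain), tolerance = 1e-8)

  # single-outcome-class stratum is refused
  sBad <- s
  sBad$status[sBad$stratum == "B"] <- "case"
  expect_error(refitNuisance(Cohort(sBad, variants(coh)), a,
                             c(helix_low = 0)), "single outcome class")
})

test_that("adjusted alpha is the case-fraction weighted average", {
  expect_equal(adjustedAlpha(0.4, 0.2, 0.5), 0.3)
  expect_equal(adjustedAlpha(0.7, 0.7, 0.123), 0.7)
  expect_equal(adjustedAlpha(0.4, 0.2, 0), 0.2)
  expect_error(adjustedAlpha(1.4, 0.2, 0.5))
})

test_that("a perfectly calibrated table gives chi-squared zero", {
  # every category and the baseline have 1:1 case:control mix; with fixed
  # betas of 0 the fitted probability is exactly 0.5 everywhere, so
  # expected counts equal observed counts
  coh <- countCohort("BRCA2",
    list(low = list(cases = 30, controls = 30, helix = 0.2),
         high = list(cases = 20, controls = 20, helix = 0.8)),
    nonCase = 200, nonCtl = 200)
  a <- assignGroups(variants(coh), builtinScheme("BRCA2"))
  rep <- calibrationGof(coh, a, list(type = "lr",
                                     betas = c(helix_low = 0, helix_high = 0)))
  expect_equal(rep@chiSq, 0, tolerance = 1e-10)
  expect_equal(rep@p, 1, tolerance = 1e-8)
  expect_equal(rep@df, 2)  # one independent contrast per carrier category
})

test_that("expected counts conserve observed totals and respect strata", {
  res <- simSmallCohort(211, poolN = 30000, nCase = 2500, nCtl = 2500)
  coh <- res$cohort
  a <- assignGroups(variants(coh), chek2Scheme())
  rep <- calibrationGof(coh, a, list(type = "mixture",
                                     alpha = c(helix_low = 0.3,
                                               helix_high = 0.9),
                                     beta = log(1.8)))
  tb <- rep@table
  expect_equal(sum(tb$expected_cases), sum(tb$observed_cases),
               tolerance = 1e-6)
  expect_equal(sum(tb$expected_controls), sum(tb$observed_controls),
               tolerance = 1e-6)

  # chi-squared invariant to stratum relabeling
  s2 <- subjects(coh); s2$stratum <- paste0("q_", s2$stratum)
  rep2 <- calibrationGof(Cohort(s2, variants(coh)), a,
                         list(type = "mixture",
                              alpha = c(helix_low = 0.3, helix_high = 0.9),
                              beta = log(1.8)))
  expect_equal(rep2@chiSq, rep@chiSq, tolerance = 1e-8)

  # the mixture offset is the linear-odds mixing rule
  off <- missenseRisk:::modelOffsets(list(type = "mixture",
                                          alpha = c(helix_low = 0.3,
                                                    helix_high = 0.9),
                                          beta = log(1.8)),
                                     c("helix_low", "helix_high"))
  expect_equal(unname(exp(off)), c(0.3 * 1.8 + 0.7, 0.9 * 1.8 + 0.1))
})

test_that("zero-carrier categories break the expected-count computation loudly", {
  coh <- countCohort("BRCA2",
    list(low = list(cases = 30, controls = 30, helix = 0.2)),
    nonCase = 200, nonCtl = 200)
  a <- assignGroups(variants(coh), builtinScheme("BRCA2"))
  expect_error(
    calibrationGof(coh, a, list(type = "lr", betas = c(helix_low = 0))),
    "zero")
  # small expected cells warn
  coh2 <- countCohort("BRCA2",
    list(low = list(cases = 30, controls = 30, helix = 0.2),
         high = list(cases = 2, controls = 2, helix = 0.8)),
    nonCase = 200, nonCtl = 200)
  a2 <- assignGroups(variants(coh2), builtinScheme("BRCA2"))
  expect_warning(
    calibrationGof(coh2, a2, list(type = "lr",
                                  betas = c(helix_low = 0, helix_high = 0))),
    "below 5")
})

test_that("posterior-weighted predicted odds ratios follow the mixing rule", {
  coh <- countCohort("BRCA2",
    list(low = list(cases = 30, controls = 30, helix = 0.2),
         high = list(cases = 20, controls = 20, helix = 0.8)),
    nonCase = 100, nonCtl = 100)
  a <- assignGroups(variants(coh), builtinScheme("BRCA2"))
  pp1 <- setNames(c(1, 1), c("BRCA2:low", "BRCA2:high"))
  r1 <- ppWeightedOr(coh, a, pp1, log(3))
  expect_equal(r1$predicted_OR, c(3, 3))
  pp0 <- setNames(c(0, 0), c("BRCA2:low", "BRCA2:high"))
  expect_equal(ppWeightedOr(coh, a, pp0, log(3))$predicted_OR, c(1, 1))
  ppH <- setNames(c(0.5, 0.5), c("BRCA2:low", "BRCA2:high"))
  expect_equal(ppWeightedOr(coh, a, ppH, log(3))$predicted_OR, c(2, 2))
  # carriers of variants unseen in training are dropped and counted
  ppPart <- setNames(0.5, "BRCA2:low")
  rP <- ppWeightedOr(coh, a, ppPart, log(3))
  expect_equal(rP$n_carriers_dropped[rP$category == "helix_high"], 40L)
  expect_true(is.na(rP$predicted_OR[rP$category == "helix_high"]))
})

test_that("the composite model excludes multi-gene carriers and nests per-gene fits", {
  # two genes; one subject carries variants of both
  v1 <- data.frame(gene = "G1", variant_id = "G1:v", consequence = "missense",
                   frequency = 5e-4, helix = 0.8, stringsAsFactors = FALSE)
  v2 <- data.frame(gene = "G2", variant_id = "G2:v", consequence = "missense",
                   frequency = 5e-4, helix = 0.8, stringsAsFactors = FALSE)
  catalog <- rbind(v1, v2)
  status <- c(rep("case", 60), rep("control", 60))
  carried <- rep(list(character(0)), 120)
  carried[1:10] <- list("G1:v")       # 10 case carriers of G1
  carried[61:66] <- list("G1:v")      # 6 control carriers of G1
  carried[11:18] <- list("G2:v")
  carried[67:78] <- list("G2:v")
  carried[[19]] <- c("G1:v", "G2:v")  # the multi-gene carrier
  s <- data.frame(subject_id = sprintf("S%03d", 1:120), stratum = "X",
                  status = status, age = 50, design = "population",
                  stringsAsFactors = FALSE)
  s$carried <- carried
  coh <- Cohort(s, catalog)
  sch <- function(g) riskScheme(g, list(hit = function(v) v$helix > 0.5),
                                "hit")
  a1 <- assignGroups(catalog, sch("G1"))
  a2 <- assignGroups(catalog, sch("G2"))
  comp <- compositeFit(coh, list(a1, a2))
  expect_equal(comp@excludedMultigene, 1)
  expect_setequal(comp@table$category, c("G1:hit", "G2:hit"))

  # with a single gene the composite equals the per-gene burden
  compOne <- compositeFit(coh, list(a1))
  burdOne <- groupBurden(coh, a1)
  expect_equal(compOne@table$OR, burdOne$OR, tolerance = 1e-8)
})
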
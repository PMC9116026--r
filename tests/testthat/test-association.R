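test_that("group burden reproduces published crude odds ratios from counts", {
  coh <- countCohort("BRCA2",
    list(helix_low = list(cases = 2062, controls = 2323, helix = 0.2),
         helix_high = list(cases = 114, controls = 94, helix = 0.8)),
    nonCase = 33006, nonCtl = 36517)
  a <- assignGroups(variants(coh), builtinScheme("BRCA2"))
  tab <- groupBurden(coh, a)
  low <- tab[tab$category == "helix_low", ]
  expect_equal(round(low$OR, 2), 0.98)
  expect_equal(low$n_case_carriers, 2062)
  expect_equal(low$n_control_carriers, 2323)
  # joint fit with disjoint indicators equals per-category cross-products
  high <- tab[tab$category == "helix_high", ]
  expect_equal(high$OR, (114 * 36517) / (94 * 33006), tolerance = 1e-6)
})

test_that("empty categories yield NA rows, not silent drops", {
  coh <- countCohort("BRCA2",
    list(helix_low = list(cases = 40, controls = 50, helix = 0.2)),
    nonCase = 500, nonCtl = 500)
  a <- assignGroups(variants(coh), builtinScheme("BRCA2"))
  tab <- groupBurden(coh, a)
  expect_true("helix_high" %in% tab$category)
  expect_true(is.na(tab$OR[tab$category == "helix_high"]))
  expect_false(is.na(tab$OR[tab$category == "helix_low"]))
})

test_that("group burden is invariant to row order and stratum relabeling", {
  res <- simSmallCohort(31)
  a <- assignGroups(variants(res$cohort), chek2Scheme())
  tab1 <- groupBurden(res$cohort, a)
  s <- subjects(res$cohort)
  perm <- sample(nrow(s))
  coh2 <- Cohort(s[perm, ], variants(res$cohort))
  tab2 <- groupBurden(coh2, a)
  expect_equal(tab1$OR, tab2$OR, tolerance = 1e-9)
  s3 <- s; s3$stratum <- paste0("zz_", s3$stratum)
  tab3 <- groupBurden(Cohort(s3, variants(res$cohort)), a)
  expect_equal(tab1$OR, tab3$OR, tolerance = 1e-9)
})

test_that("permutation of outcomes gives null category odds ratios", {
  res <- simSmallCohort(32, poolN = 40000, nCase = 3000, nCtl = 3000)
  a <- assignGroups(variants(res$cohort), chek2Scheme())
  s <- subjects(res$cohort)
  cover <- 0; total <- 0
  set.seed(99)
  for (r in 1:20) {
    s2 <- s; s2$status <- sample(s2$status)
    tab <- groupBurden(Cohort(s2, variants(res$cohort)), a)
    ok <- !is.na(tab$OR)
    cover <- cover + sum(tab$ci_low[ok] <= 1 & tab$ci_high[ok] >= 1)
    total <- total + sum(ok)
  }
  expect_gte(cover / total, 0.9)
})

test_that("carrier score trend recovers a known slope and is shift invariant", {
  # carriers only: one variant per subject with score-driven case odds
  set.seed(71)
  n <- 10000
  score <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.1 + 0.5 * score))
  vdf <- data.frame(gene = "G", variant_id = paste0("v", 1:n),
                    consequence = "missense", frequency = 1e-5,
                    cadd = score, stringsAsFactors = FALSE)
  sdf <- data.frame(subject_id = paste0("s", 1:n), stratum = "X",
                    status = ifelse(y == 1, "case", "control"), age = 50,
                    design = "population", stringsAsFactors = FALSE)
  sdf$carried <- as.list(vdf$variant_id)
  coh <- Cohort(sdf, vdf)
  tr <- carrierScoreTrend(coh, "G", "cadd")
  expect_true(tr$ci_low <= exp(0.5) && exp(0.5) <= tr$ci_high)

  vdf2 <- vdf; vdf2$cadd <- vdf2$cadd + 10
  tr2 <- carrierScoreTrend(Cohort(sdf, vdf2), "G", "cadd")
  expect_equal(tr2$OR, tr$OR, tolerance = 1e-6)

  vdf3 <- vdf; vdf3$cadd <- 1
  expect_error(carrierScoreTrend(Cohort(sdf, vdf3), "G", "cadd"), "constant")
})

test_that("frequency burden is consistent with overall burden and reparameterizes", {
  coh <- countCohort("G",
    list(only = list(cases = 120, controls = 100, helix = 0.2)),
    nonCase = 4000, nonCtl = 4000)
  fb <- frequencyBurden(coh, "G")
  # all variants in one bin: that bin equals the all-carriers burden
  bin <- fb$burden[fb$burden$category == "<0.1%", ]
  expect_equal(bin$OR, (120 * 4000) / (100 * 4000), tolerance = 1e-6)
  expect_true(all(is.na(fb$burden$OR[fb$burden$category != "<0.1%"])))

  # carrier-only log test equals a hand-built fit on log frequencies
  res <- simSmallCohort(33)
  fb2 <- frequencyBurden(res$cohort, "CHEK2")
  ct <- fb2$carrier_tests
  expect_true(all(c("continuous", "log", "rare_vs_lowfreq") %in% ct$test))
  v <- variants(res$cohort)
  s <- subjects(res$cohort)
  vid <- vapply(s$carried, function(ids) {
    mis <- ids[ids %in% v$variant_id[v$consequence == "missense"]]
    if (length(mis) == 1L) mis else NA_character_
  }, character(1L))
  hasPtv <- vapply(s$carried, function(ids) "CHEK2_ptv" %in% ids, logical(1L))
  keep <- !is.na(vid) & !hasPtv &
    v$frequency[match(vid, v$variant_id)] < 0.005
  f <- v$frequency[match(vid[keep], v$variant_id)]
  hand <- fitLogistic(s$status[keep],
                      cbind(x = log(f),
                            missenseRisk:::stratumDesign(s$stratum[keep])))
  expect_equal(ct$OR[ct$test == "log"], exp(unname(coef(hand)["x"])),
               tolerance = 1e-6)
})

test_that("single-variant odds ratios match the closed form and flag zero cells", {
  coh <- countCohort("G",
    list(v = list(cases = 29, controls = 2, helix = 0.2)),
    nonCase = 34191, nonCtl = 37996)
  r <- singleVariantOr(coh, "G:v")
  expect_equal(r$OR, (29 * 37996) / (2 * 34191), tolerance = 1e-6)
  expect_equal(round(r$OR, 2), 16.11)
  expect_false(r$unbounded)

  coh2 <- countCohort("G",
    list(v = list(cases = 5, controls = 0, helix = 0.2)),
    nonCase = 500, nonCtl = 500)
  r2 <- singleVariantOr(coh2, "G:v")
  expect_true(r2$unbounded)
  expect_equal(r2$OR, Inf)

  coh3 <- countCohort("G",
    list(v = list(cases = 1, controls = 1, helix = 0.2)),
    nonCase = 500, nonCtl = 500)
  r3 <- singleVariantOr(coh3, "G:v")
  expect_equal(r3$OR, 1, tolerance = 1e-6)
})

test_that("case-only age trend recovers a known age effect and nulls out", {
  set.seed(81)
  n <- 10000
  age <- round(runif(n, 30, 75))
  top <- rbinom(n, 1, plogis(0.8 - 0.02 * age))
  vdf <- data.frame(gene = "G", variant_id = paste0("v", 1:n),
                    consequence = "missense", frequency = 1e-5,
                    helix = ifelse(top == 1, 0.9, 0.1),
                    stringsAsFactors = FALSE)
  sdf <- data.frame(subject_id = paste0("s", 1:n), stratum = "X",
                    status = "case", age = age, design = "population",
                    stringsAsFactors = FALSE)
  sdf$carried <- as.list(vdf$variant_id)
  # add a control pair so the Cohort has two classes elsewhere
  coh <- Cohort(sdf, vdf)
  a <- assignGroups(vdf, riskScheme("G", list(
    other = function(v) v$helix <= 0.5,
    top = function(v) v$helix > 0.5), baseline = "other"))
  tr <- caseOnlyAgeTrend(coh, a, "top")
  expect_true(tr$ci_low <= exp(-0.02) && exp(-0.02) <= tr$ci_high)

  # permuted age: per-year OR near 1
  sdfP <- sdf; sdfP$age <- sample(sdfP$age)
  trP <- caseOnlyAgeTrend(Cohort(sdfP, vdf), a, "top")
  expect_true(trP$ci_low <= 1 && 1 <= trP$ci_high)

  vdf1 <- vdf; vdf1$helix <- 0.9
  a1 <- assignGroups(vdf1, riskScheme("G", list(
    other = function(v) v$helix <= 0.5,
    top = function(v) v$helix > 0.5), baseline = "other"))
  expect_error(caseOnlyAgeTrend(Cohort(sdf, vdf1), a1, "top"), "categories")
})
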
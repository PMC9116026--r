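test_that("component likelihoods match hand evaluation of the expit products", {
  vdf <- data.frame(gene = "G", variant_id = c("w", "u"),
                    consequence = "missense", frequency = 1e-4,
                    stringsAsFactors = FALSE)
  sdf <- data.frame(subject_id = c("c1", "c2"), stratum = "X",
                    status = c("case", "control"), age = 50,
                    design = "population", stringsAsFactors = FALSE)
  sdf$carried <- list("w", character(0))
  coh <- Cohort(sdf, vdf)
  cl <- componentLikelihoods(coh, "w", c("(Intercept)" = 0), log(2))
  expect_equal(cl$L1, 2 / 3, tolerance = 1e-12)
  expect_equal(cl$L0, 1 / 2, tolerance = 1e-12)
  # no carriers: both components are 1
  cl0 <- componentLikelihoods(coh, "u", c("(Intercept)" = 0), log(2))
  expect_equal(c(cl0$L1, cl0$L0), c(1, 1))
  # beta = 0 collapses the two components
  clB <- componentLikelihoods(coh, "w", c("(Intercept)" = -1), 0)
  expect_equal(clB$L1, clB$L0)
  expect_error(componentLikelihoods(coh, "nope", c("(Intercept)" = 0), 1),
               "unknown variant")
})

test_that("the expectation step is the two-component Bayes ratio", {
  expect_equal(eStep(0.9, 0.5, 0), 0)
  expect_equal(eStep(0.7, 0.7, 0.3), 0.3)
  expect_equal(eStep(2 / 3, 1 / 2, 0.5), 4 / 7, tolerance = 1e-12)
  expect_error(eStep(0.5, 0.5, 1.2), "alpha")
})

test_that("EM solution matches a brute-force grid search on micro data", {
  coh <- microCohort()
  a <- microAssignment(coh)
  fit <- fitMixture(coh, a, mixtureSpec("G", "unconstrained",
                                        includePtvCarriers = FALSE))
  g <- expand.grid(alpha = seq(0.001, 0.999, length.out = 80),
                   beta = seq(-3, 5, length.out = 120),
                   mu = seq(-3, 2, length.out = 120))
  gridMax <- max(mapply(microLoglik, g$alpha, g$beta, g$mu))
  emll <- max(loglikTrace(fit))
  expect_gte(emll + 1e-9, gridMax)          # EM at least as good as the grid
  expect_equal(emll, gridMax, tolerance = 1e-3)
  # the fitted parameters reproduce the reported log-likelihood
  expect_equal(emll, microLoglik(alphaEstimates(fit)["risk", "all"],
                                 fit@betaMis, fit@nuisance[["(Intercept)"]]),
               tolerance = 1e-6)
})

test_that("alpha fixed at one reproduces the plain carrier logistic model", {
  coh <- microCohort()
  a <- microAssignment(coh)
  fit1 <- fitMixture(coh, a, mixtureSpec("G", "unconstrained",
                                         includePtvCarriers = FALSE),
                     fixedAlpha = list(all = 1))
  carrier <- vapply(subjects(coh)$carried, length, 1L) > 0
  lr <- fitLogistic(subjects(coh)$status, cbind(carrier = as.numeric(carrier)))
  expect_equal(max(loglikTrace(fit1)), logLik(lr), tolerance = 1e-8)
  expect_equal(fit1@betaMis, unname(coef(lr)["carrier"]), tolerance = 1e-6)
})

test_that("the log-likelihood trace is monotone on random small cohorts", {
  for (seed in c(101, 102, 103)) {
    res <- simSmallCohort(seed, poolN = 20000, nCase = 1500, nCtl = 1500)
    a <- assignGroups(variants(res$cohort), chek2Scheme())
    for (mode in c("constrained", "unconstrained")) {
      fit <- suppressWarnings(
        fitMixture(res$cohort, a, mixtureSpec("CHEK2", mode)))
      tr <- loglikTrace(fit)
      expect_true(all(diff(tr) >= -1e-8 * pmax(1, abs(tr[-length(tr)]))))
    }
  }
})

test_that("posteriors respond monotonically to added case carriers", {
  nuis <- c("(Intercept)" = -0.1)
  beta <- log(2.5)
  post <- vapply(0:5, function(k) {
    vdf <- data.frame(gene = "G", variant_id = "v",
                      consequence = "missense", frequency = 1e-4,
                      stringsAsFactors = FALSE)
    n <- k + 2L
    sdf <- data.frame(subject_id = paste0("s", seq_len(n)), stratum = "X",
                      status = c(rep("case", k), "control", "control"),
                      age = 50, design = "population", stringsAsFactors = FALSE)
    sdf$carried <- c(rep(list("v"), k + 1L), list(character(0)))
    cl <- componentLikelihoods(Cohort(sdf, vdf), "v", nuis, beta)
    eStep(cl$L1, cl$L0, 0.2)
  }, numeric(1L))
  expect_true(all(diff(post) > 0))
})

test_that("control-only alpha follows its definition and bias direction", {
  # two variants: one control-carried with high posterior, one case-only
  res <- simSmallCohort(111, poolN = 30000, nCase = 2500, nCtl = 2500)
  a <- assignGroups(variants(res$cohort), chek2Scheme())
  fit <- suppressWarnings(
    fitMixture(res$cohort, a, mixtureSpec("CHEK2", "unconstrained")))
  ctl <- controlOnlyAlpha(fit)
  ids <- fit@details$control_carried
  catOf <- fit@details$category
  for (cc in names(ctl)) {
    idsC <- ids[catOf[ids] == cc]
    if (length(idsC))
      expect_equal(unname(ctl[cc]), mean(fit@posteriors[idsC, "risk"]),
                   tolerance = 1e-12)
  }
  # case-enriched sampling biases the naive alpha upward on average
  diffs <- vapply(c(121, 122, 123, 124, 125), function(seed) {
    r <- simSmallCohort(seed, poolN = 60000, nCase = 4000, nCtl = 2000)
    aa <- assignGroups(variants(r$cohort), chek2Scheme())
    f <- suppressWarnings(
      fitMixture(r$cohort, aa, mixtureSpec("CHEK2", "unconstrained")))
    co <- controlOnlyAlpha(f)
    mean(alphaEstimates(f)["risk", ] - co)
  }, numeric(1L))
  expect_gt(mean(diffs), 0)
})

test_that("log-likelihood comparisons respect data identity and nesting", {
  coh <- microCohort()
  a <- microAssignment(coh)
  spec <- mixtureSpec("G", "unconstrained", includePtvCarriers = FALSE)
  fit <- fitMixture(coh, a, spec)
  expect_equal(compareLoglik(fit, fit), 0)
  # alpha free vs alpha fixed at its MLE: non-negative statistic
  fitF <- fitMixture(coh, a, spec,
                     fixedAlpha = list(all = unname(
                       alphaEstimates(fit)["risk", "all"])))
  expect_gte(compareLoglik(fit, fitF), -1e-6)
  # different subject sets are refused
  coh2 <- Cohort(subjects(coh)[1:7, ], variants(coh))
  fit2 <- fitMixture(coh2, a, spec)
  expect_error(compareLoglik(fit, fit2), "identical")
})

test_that("profile intervals bracket the estimate and hit the zero boundary", {
  res <- simSmallCohort(131, poolN = 30000, nCase = 2500, nCtl = 2500)
  a <- assignGroups(variants(res$cohort), chek2Scheme())
  spec <- mixtureSpec("CHEK2", "unconstrained")
  fit <- suppressWarnings(fitMixture(res$cohort, a, spec))
  ci <- suppressWarnings(
    alphaProfileCi(res$cohort, a, spec, fit, "helix_high", gridN = 21))
  ahat <- alphaEstimates(fit)["risk", "helix_high"]
  expect_lte(ci["lower"], ahat + 1e-6)
  expect_gte(ci["upper"], ahat - 1e-6)

  # null data: no case excess -> lower bound at 0
  r0 <- simSmallCohort(132, alphaLow = 0, alphaHigh = 0, orMis = 1,
                       orPtv = 1, poolN = 20000, nCase = 1500, nCtl = 1500)
  a0 <- assignGroups(variants(r0$cohort), chek2Scheme())
  f0 <- suppressWarnings(fitMixture(r0$cohort, a0, spec))
  ci0 <- suppressWarnings(
    alphaProfileCi(r0$cohort, a0, spec, f0, "helix_high", gridN = 21))
  expect_equal(unname(ci0["lower"]), 0, tolerance = 1e-6)
})

test_that("the two-level mixture separates a high and a moderate risk state", {
  res <- simSmallCohort(141, alphaLow = 0.4, alphaHigh = 0.9, orMis = 1.6,
                        orPtv = 3, ptvFreq = 0.01, poolN = 80000,
                        nCase = 7000, nCtl = 7000)
  a <- assignGroups(variants(res$cohort), chek2Scheme())
  fit <- suppressWarnings(
    fitMixture(res$cohort, a, mixtureSpec("CHEK2", "two_level")))
  expect_equal(rownames(alphaEstimates(fit)), c("high", "moderate"))
  expect_true(all(colSums(alphaEstimates(fit)) <= 1 + 1e-9))
  expect_gt(fit@betaPtv, fit@betaMis)  # high state anchored to the PTV OR
  tr <- loglikTrace(fit)
  expect_true(all(diff(tr) >= -1e-8 * pmax(1, abs(tr[-length(tr)]))))
})

test_that("mixture specifications validate their arguments", {
  expect_error(mixtureSpec("G", tol = -1), "tol")
  expect_error(mixtureSpec("G", mode = "bogus"))
  expect_error(fitMixture(tinyCohort(),
                          microAssignment(microCohort()),
                          mixtureSpec("G")), "catalog|carrier|variant")
})
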
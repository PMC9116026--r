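#' Mixture model specification
#'
#' @param gene gene symbol.
#' @param mode "constrained" (pathogenic missense log-OR tied to the PTV
#'   log-OR), "unconstrained" (free missense log-OR), or "two_level" (a
#'   high-risk state tied to the PTV log-OR plus a moderate-risk state with
#'   its own log-OR).
#' @param includePtvCarriers keep PTV carriers of the gene in the fit
#'   (default TRUE; they anchor the PTV odds ratio that the constrained
#'   modes borrow).
#' @param tol EM stopping tolerance on the observed-data log-likelihood.
#' @param maxIter maximum EM iterations.
#' @return list of class "MixtureSpec".
#' @export
mixtureSpec <- function(gene, mode = c("constrained", "unconstrained",
                                       "two_level"),
                        includePtvCarriers = TRUE, tol = 1e-6,
                        maxIter = 500L) {
  mode <- match.arg(mode)
  if (!is.numeric(tol) || tol <= 0) stopf("tol must be > 0")
  structure(list(gene = gene, mode = mode,
                 includePtvCarriers = includePtvCarriers,
                 tol = tol, maxIter = as.integer(maxIter)),
            class = "MixtureSpec")
}

#' Carrier-data likelihood components for one variant
#'
#' The likelihood of the case/control observations on a variant's carriers
#' under the risk-associated state (carrier log-OR `betaState`) and under
#' the benign state (log-OR 0):
#' L_state = prod over carriers i of pi_i^y_i (1 - pi_i)^(1 - y_i) with
#' pi_i = expit(intercept + stratum_i + betaState). Non-carrier terms are
#' excluded; they cancel in the posterior ratio. A variant with no carriers
#' has L1 = L0 = 1.
#'
#' @param cohort a Cohort.
#' @param variantId catalog variant id.
#' @param nuisance named numeric: "(Intercept)" plus stratum coefficients
#'   named by stratum label (missing labels contribute 0, i.e. reference).
#' @param betaState log odds ratio of the risk-associated state.
#' @return list(variant_id, L1, L0).
#' @export
componentLikelihoods <- function(cohort, variantId, nuisance, betaState) {
  v <- variants(cohort)
  if (!variantId %in% v$variant_id) stopf("unknown variant '%s'", variantId)
  s <- subjects(cohort)
  carries <- vapply(s$carried, function(ids) variantId %in% ids, logical(1L))
  if (!any(carries))
    return(list(variant_id = variantId, L1 = 1, L0 = 1))
  y <- as.numeric(s$status[carries] == "case")
  eta0 <- nuisance[["(Intercept)"]] +
    vapply(s$stratum[carries],
           function(st) if (st %in% names(nuisance)) nuisance[[st]] else 0,
           numeric(1L))
  lik <- function(beta) {
    p <- plogis(eta0 + beta)
    prod(p^y * (1 - p)^(1 - y))
  }
  list(variant_id = variantId, L1 = lik(betaState), L0 = lik(0))
}

#' Posterior probability that a variant is risk associated
#'
#' The expectation step: p = alpha * L1 / (alpha * L1 + (1 - alpha) * L0).
#'
#' @param L1,L0 carrier-data likelihoods under the risk-associated and
#'   benign states (vectors allowed).
#' @param alpha prior proportion of risk-associated variants in the
#'   variant's category (scalar or vector, in [0, 1]).
#' @return posterior probabilities in [0, 1].
#' @export
eStep <- function(L1, L0, alpha) {
  if (any(alpha < 0 | alpha > 1)) stopf("alpha must be in [0, 1]")
  num <- alpha * L1
  den <- num + (1 - alpha) * L0
  ifelse(den == 0, alpha, num / den)
}

# ---- internal EM machinery --------------------------------------------------

# per-variant log-likelihood under carrier log-OR beta, given stratum linear
# predictors eta (length S); counts Vcase/Vctl are variants x strata
variantLogLik <- function(Vcase, Vctl, eta, beta) {
  lp <- log(plogis(eta + beta))
  lq <- log1p(-plogis(eta + beta))
  drop(Vcase %*% lp + Vctl %*% lq)
}

marginLogLik <- function(nCase, nCtl, eta, beta) {
  sum(nCase * log(plogis(eta + beta)) + nCtl * log1p(-plogis(eta + beta)))
}

# observed-data log-likelihood and per-variant posteriors at given params
mixtureEval <- function(cnt, mode, alpha, betaMis, betaPtv, nuis) {
  # nuisance is ordered (Intercept), stratum coefs for cnt$strata[-1]
  eta <- rep(unname(nuis[1L]), length(cnt$strata))
  if (length(nuis) > 1L) eta <- eta + c(0, unname(nuis[-1L]))
  ll <- marginLogLik(cnt$ncCase, cnt$ncCtl, eta, 0) +
    marginLogLik(cnt$ptvCase, cnt$ptvCtl, eta, betaPtv)
  catIdx <- match(cnt$category, colnames(alpha))
  l0 <- variantLogLik(cnt$Vcase, cnt$Vctl, eta, 0)
  if (mode == "two_level") {
    lH <- variantLogLik(cnt$Vcase, cnt$Vctl, eta, betaPtv)
    lM <- variantLogLik(cnt$Vcase, cnt$Vctl, eta, betaMis)
    aH <- alpha["high", catIdx]; aM <- alpha["moderate", catIdx]
    aB <- pmax(1 - aH - aM, 0)
    tH <- log(aH) + lH; tM <- log(aM) + lM; tB <- log(aB) + l0
    lse <- logsumexp3(tH, tM, tB)
    post <- cbind(high = exp(tH - lse), moderate = exp(tM - lse))
    post[is.nan(post)] <- 0
    ll <- ll + sum(lse)
  } else {
    beta1 <- if (mode == "constrained") betaPtv else betaMis
    l1 <- variantLogLik(cnt$Vcase, cnt$Vctl, eta, beta1)
    a <- alpha["risk", catIdx]
    t1 <- log(a) + l1; t0 <- log1p(-a) + l0
    lse <- logsumexp2(t1, t0)
    post <- cbind(risk = pmin(pmax(exp(t1 - lse), 0), 1))
    ll <- ll + sum(lse)
  }
  rownames(post) <- cnt$carriedIds
  list(loglik = ll, post = post, logL1 = if (mode == "two_level")
         cbind(high = lH, moderate = lM) else cbind(risk = l1),
       logL0 = l0)
}

# weighted-logistic maximization step on aggregated pseudo-data
mixtureMStep <- function(cnt, mode, post) {
  S <- length(cnt$strata)
  sd0 <- stratumDesign(cnt$strata, levels = cnt$strata)
  catCols <- switch(mode,
    constrained = "carrier",
    unconstrained = c("mis", "ptv"),
    two_level = c("high", "moderate"))
  rows <- list()
  addRows <- function(wCase, wCtl, expo) {
    for (yv in c(1, 0)) {
      w <- if (yv == 1) wCase else wCtl
      keep <- w > 0
      if (!any(keep)) next
      ex <- matrix(0, sum(keep), length(catCols),
                   dimnames = list(NULL, catCols))
      if (!is.null(expo)) ex[, expo] <- 1
      rows[[length(rows) + 1L]] <<- list(
        y = rep(yv, sum(keep)), X = cbind(sd0[keep, , drop = FALSE], ex),
        w = w[keep])
    }
  }
  # non-carrier + benign pseudo-weights share covariates
  benignCase <- drop(crossprod(1 - rowSums(post), cnt$Vcase))
  benignCtl <- drop(crossprod(1 - rowSums(post), cnt$Vctl))
  addRows(cnt$ncCase + benignCase, cnt$ncCtl + benignCtl, NULL)
  if (mode == "constrained") {
    riskCase <- drop(crossprod(post[, "risk"], cnt$Vcase))
    riskCtl <- drop(crossprod(post[, "risk"], cnt$Vctl))
    addRows(cnt$ptvCase + riskCase, cnt$ptvCtl + riskCtl, "carrier")
  } else if (mode == "unconstrained") {
    addRows(drop(crossprod(post[, "risk"], cnt$Vcase)),
            drop(crossprod(post[, "risk"], cnt$Vctl)), "mis")
    addRows(cnt$ptvCase, cnt$ptvCtl, "ptv")
  } else {
    addRows(cnt$ptvCase + drop(crossprod(post[, "high"], cnt$Vcase)),
            cnt$ptvCtl + drop(crossprod(post[, "high"], cnt$Vctl)), "high")
    addRows(drop(crossprod(post[, "moderate"], cnt$Vcase)),
            drop(crossprod(post[, "moderate"], cnt$Vctl)), "moderate")
  }
  y <- unlist(lapply(rows, `[[`, "y"))
  X <- do.call(rbind, lapply(rows, `[[`, "X"))
  w <- unlist(lapply(rows, `[[`, "w"))
  # drop exposure columns with no weight (e.g. no PTV carriers)
  keepCol <- c(rep(TRUE, ncol(sd0)),
               colSums(X[, catCols, drop = FALSE] * w) > 0)
  Xk <- X[, keepCol, drop = FALSE]
  fit <- fitLogistic(y, Xk, weights = w)
  beta <- setNames(rep(0, length(catCols)), catCols)
  got <- intersect(names(coef(fit)), catCols)
  beta[got] <- coef(fit)[got]
  nuisNames <- c("(Intercept)", colnames(sd0))
  nuis <- setNames(rep(0, length(nuisNames)), nuisNames)
  gotN <- intersect(names(coef(fit)), nuisNames)
  nuis[gotN] <- coef(fit)[gotN]
  list(beta = beta, nuis = nuis, fit = fit)
}

emAlphaUpdate <- function(cnt, mode, post, alpha, fixedAlpha = NULL) {
  cats <- colnames(alpha)
  cat <- factor(cnt$category, levels = cats)
  upd <- function(p, state) {
    m <- tapply(p, cat, mean)
    out <- alpha[state, ]
    out[!is.na(m)] <- m[!is.na(m)]
    out
  }
  if (mode == "two_level") {
    alpha["high", ] <- upd(post[, "high"], "high")
    alpha["moderate", ] <- upd(post[, "moderate"], "moderate")
  } else {
    alpha["risk", ] <- upd(post[, "risk"], "risk")
  }
  if (!is.null(fixedAlpha))
    for (nm in names(fixedAlpha)) alpha[, nm] <- fixedAlpha[[nm]]
  pmin(pmax(alpha, 0), 1)
}

runEM <- function(cnt, mode, init, tol, maxIter, fixedAlpha = NULL) {
  alpha <- init$alpha
  if (!is.null(fixedAlpha))
    for (nm in names(fixedAlpha)) alpha[, nm] <- fixedAlpha[[nm]]
  betaMis <- init$betaMis; betaPtv <- init$betaPtv; nuis <- init$nuis
  trace <- numeric(0)
  converged <- FALSE
  ev <- NULL
  for (it in seq_len(maxIter)) {
    ev <- mixtureEval(cnt, mode, alpha, betaMis, betaPtv, nuis)
    trace <- c(trace, ev$loglik)
    if (it > 1L && abs(trace[it] - trace[it - 1L]) < tol) {
      converged <- TRUE
      break
    }
    m <- tryCatch(mixtureMStep(cnt, mode, ev$post), error = function(e) NULL)
    if (is.null(m)) break  # boundary-degenerate M-step; keep current params
    nuis <- m$nuis
    if (mode == "constrained") {
      betaPtv <- unname(m$beta["carrier"]); betaMis <- betaPtv
    } else if (mode == "unconstrained") {
      betaMis <- unname(m$beta["mis"])
      if (cnt$nPtvCarriers > 0) betaPtv <- unname(m$beta["ptv"])
    } else {
      betaPtv <- unname(m$beta["high"])
      betaMis <- unname(m$beta["moderate"])
    }
    alpha <- emAlphaUpdate(cnt, mode, ev$post, alpha, fixedAlpha)
  }
  list(alpha = alpha, betaMis = betaMis, betaPtv = betaPtv, nuis = nuis,
       post = ev$post, trace = trace, converged = converged)
}

emInits <- function(cnt, mode, cats) {
  S <- length(cnt$strata)
  sd0 <- stratumDesign(cnt$strata, levels = cnt$strata)
  aggFit <- function(case, ctl, extra = NULL) {
    y <- c(rep(1, S), rep(0, S))
    X <- rbind(sd0, sd0)
    w <- c(case, ctl)
    keep <- w > 0
    fitLogistic(y[keep], X[keep, , drop = FALSE], weights = w[keep])
  }
  nuisNames <- c("(Intercept)", colnames(sd0))
  nuis <- setNames(rep(0, length(nuisNames)), nuisNames)
  ncFit <- tryCatch(aggFit(cnt$ncCase, cnt$ncCtl), error = function(e) NULL)
  if (!is.null(ncFit)) {
    nuis[names(coef(ncFit))] <- coef(ncFit)
  } else {
    # degenerate non-carrier margin (e.g. micro data); overall case odds
    tot <- sum(cnt$ncCase, cnt$ptvCase, cnt$Vcase) + 0.5
    totN <- sum(cnt$ncCtl, cnt$ptvCtl, cnt$Vctl) + 0.5
    nuis[1L] <- log(tot / totN)
  }
  betaPtv <- log(2)
  if (cnt$nPtvCarriers > 0) {
    y <- c(rep(1, 2L * S), rep(0, 2L * S))
    X <- cbind(rbind(sd0, sd0, sd0, sd0),
               ptv = rep(c(0, 1, 0, 1), each = S))
    w <- c(cnt$ncCase, cnt$ptvCase, cnt$ncCtl, cnt$ptvCtl)
    keep <- w > 0
    pf <- tryCatch(fitLogistic(y[keep], X[keep, , drop = FALSE],
                               weights = w[keep]),
                   error = function(e) NULL)
    if (!is.null(pf) && "ptv" %in% names(coef(pf)))
      betaPtv <- unname(coef(pf)["ptv"])
  }
  states <- if (mode == "two_level") c("high", "moderate") else "risk"
  mkAlpha <- function(a) matrix(a, length(states), length(cats),
                                dimnames = list(states, cats))
  base <- list(alpha = mkAlpha(if (mode == "two_level") 0.05 else 0.1),
               betaMis = if (mode == "constrained") betaPtv else log(1.5),
               betaPtv = betaPtv, nuis = nuis)
  alt1 <- base; alt1$alpha <- mkAlpha(0.5)
  alt1$betaMis <- if (mode == "constrained") betaPtv else log(3)
  alt2 <- base; alt2$alpha <- mkAlpha(0.02)
  alt2$betaMis <- if (mode == "constrained") betaPtv else log(1.2)
  list(base, alt1, alt2)
}

#' Fit the per-category mixture model by EM
#'
#' Each eligible missense variant of the gene is latently risk-associated
#' with category-specific prior probability alpha. The expectation step
#' computes, for every variant, the posterior probability of being risk
#' associated given the case-control data on its carriers and the current
#' parameters; the maximization step refits a weighted stratified logistic
#' regression in which every missense carrier is expanded into a pathogenic
#' pseudo-observation (weighted by the posterior, carrying the exposure
#' indicator) and a benign pseudo-observation (complementary weight, no
#' exposure), with PTV carriers included at weight one; alpha is then
#' updated as the unweighted mean posterior over the unique variants of
#' each category observed in the data. Iteration stops when the
#' observed-data log-likelihood changes by less than `tol`.
#'
#' Subjects carrying more than one eligible missense variant of the gene
#' are excluded (count reported in `details$excluded_multi`); subjects
#' carrying both a PTV and a missense variant of the gene enter as PTV
#' carriers. Three deterministic starting points guard against local
#' maxima; the best final log-likelihood is kept.
#'
#' @param cohort a Cohort. PTV carriers of the gene should still be present
#'   when `spec$includePtvCarriers` is TRUE.
#' @param assignment a [GroupAssignment-class].
#' @param spec a [mixtureSpec()].
#' @param init optional list(alpha, betaMis, betaPtv, nuis) overriding the
#'   default starting points (a single start is then used).
#' @param fixedAlpha optional named list category -> fixed alpha value;
#'   those categories are held fixed (e.g. all 1 collapses the mixture to
#'   the plain carrier logistic model).
#' @return a [MixtureFit-class].
#' @export
fitMixture <- function(cohort, assignment, spec, init = NULL,
                       fixedAlpha = NULL) {
  cnt <- mixtureCounts(cohort, assignment, spec$includePtvCarriers)
  if (nrow(cnt$Vcase) == 0L && cnt$nPtvCarriers == 0L)
    stopf("no carriers at all for gene '%s'", spec$gene)
  cats <- names(assignment@scheme@categories)
  inits <- if (is.null(init)) emInits(cnt, spec$mode, cats) else list(init)
  runs <- lapply(inits, function(ini)
    runEM(cnt, spec$mode, ini, spec$tol, spec$maxIter,
          fixedAlpha = fixedAlpha))
  best <- runs[[which.max(vapply(runs, function(r) max(r$trace), numeric(1L)))]]
  if (!best$converged)
    warnf("EM did not converge in %d iterations for gene '%s'",
          spec$maxIter, spec$gene)
  # posteriors for every assigned variant: uncarried variants have
  # L1 = L0 = 1, so their posterior equals alpha of their category
  states <- rownames(best$alpha)
  postAll <- matrix(NA_real_, length(cnt$allIds), length(states),
                    dimnames = list(cnt$allIds, states))
  for (st in states)
    postAll[, st] <- best$alpha[st, match(cnt$allCats, colnames(best$alpha))]
  postAll[cnt$carriedIds, ] <- best$post[, states, drop = FALSE]
  new("MixtureFit",
      alpha = best$alpha,
      betaMis = if (spec$mode == "constrained") best$betaPtv else best$betaMis,
      betaPtv = best$betaPtv,
      nuisance = best$nuis,
      posteriors = pmin(pmax(postAll, 0), 1),
      loglikTrace = best$trace,
      converged = best$converged,
      mode = spec$mode, gene = spec$gene,
      details = list(fingerprint = cnt$fingerprint,
                     excluded_multi = cnt$excludedMulti,
                     n_ptv_carriers = cnt$nPtvCarriers,
                     carried_ids = cnt$carriedIds,
                     category = setNames(cnt$allCats, cnt$allIds),
                     control_carried = rownames(cnt$Vctl)[rowSums(cnt$Vctl) > 0],
                     case_carried = rownames(cnt$Vcase)[rowSums(cnt$Vcase) > 0],
                     counts = cnt))
}

#' Control-only alpha
#'
#' Recomputes the per-category proportion of risk-associated variants using
#' only variants observed in at least one control, correcting the
#' case-ascertainment bias of the naive alpha (risk-associated variants are
#' more likely to be found in cases).
#'
#' @param fit a [MixtureFit-class].
#' @param cohort,assignment the data the fit was produced from (used to
#'   locate control-carried variants; may be omitted, in which case the
#'   fit's stored counts are used).
#' @return named numeric (or states x categories matrix for the two-level
#'   model); NA with a warning for categories without control-carried
#'   variants.
#' @export
controlOnlyAlpha <- function(fit, cohort = NULL, assignment = NULL) {
  ids <- fit@details$control_carried
  cats <- colnames(fit@alpha)
  catOf <- fit@details$category
  post <- fit@posteriors[ids, , drop = FALSE]
  out <- fit@alpha
  for (st in rownames(out)) {
    m <- tapply(post[, st], factor(catOf[ids], levels = cats), mean)
    out[st, ] <- as.numeric(m)
  }
  if (anyNA(out))
    warnf("categories without control-carried variants: %s",
          paste(cats[colSums(is.na(out)) > 0], collapse = ", "))
  if (nrow(out) == 1L) setNames(out[1L, ], cats) else out
}

#' Profile-likelihood confidence interval for alpha
#'
#' Fixes the category's alpha on a grid, re-maximizes all other parameters
#' by EM at each grid value, and returns the set where twice the
#' log-likelihood drop from the maximum is within the chi-squared(1)
#' quantile, clipped to [0, 1]. Grid crossings are refined by linear
#' interpolation.
#'
#' @param cohort,assignment,spec as in [fitMixture()].
#' @param fit the converged [MixtureFit-class].
#' @param category category label.
#' @param level confidence level (default 0.95).
#' @param gridN number of grid points (default 41).
#' @return c(lower, upper).
#' @export
alphaProfileCi <- function(cohort, assignment, spec, fit, category,
                           level = 0.95, gridN = 41L) {
  cats <- colnames(fit@alpha)
  if (!category %in% cats) stopf("unknown category '%s'", category)
  if (fit@mode == "two_level")
    stopf("profile CI supported for single-state mixtures")
  cnt <- fit@details$counts
  grid <- seq(0, 1, length.out = gridN)
  init <- list(alpha = fit@alpha, betaMis = fit@betaMis,
               betaPtv = fit@betaPtv, nuis = fit@nuisance)
  ll <- vapply(grid, function(a) {
    fx <- setNames(list(a), category)
    r <- runEM(cnt, fit@mode, init, spec$tol, spec$maxIter, fixedAlpha = fx)
    max(r$trace)
  }, numeric(1L))
  llMax <- max(c(ll, max(fit@loglikTrace)))
  crit <- qchisq(level, 1L)
  inside <- 2 * (llMax - ll) <= crit
  if (all(inside)) {
    warnf("flat likelihood in alpha for '%s'; returning [0, 1]", category)
    return(c(lower = 0, upper = 1))
  }
  if (!any(inside)) return(c(lower = NA_real_, upper = NA_real_))
  lo <- grid[which(inside)[1L]]
  hi <- grid[rev(which(inside))[1L]]
  interp <- function(i0, i1) {
    # linear interpolation of 2*(llMax - ll) crossing `crit`
    d0 <- 2 * (llMax - ll[i0]); d1 <- 2 * (llMax - ll[i1])
    grid[i0] + (crit - d0) / (d1 - d0) * (grid[i1] - grid[i0])
  }
  iLo <- which(inside)[1L]
  if (iLo > 1L) lo <- interp(iLo - 1L, iLo)
  iHi <- rev(which(inside))[1L]
  if (iHi < gridN) hi <- interp(iHi + 1L, iHi)
  c(lower = max(0, min(lo, hi)), upper = min(1, max(lo, hi)))
}

#' Twice the log-likelihood difference of two mixture fits
#'
#' @param fitA,fitB [MixtureFit-class] objects fitted on identical data.
#' @return 2 * (loglik A - loglik B); signed, interpretation (nested LRT vs
#'   descriptive comparison) is up to the caller.
#' @export
compareLoglik <- function(fitA, fitB) {
  if (!identical(fitA@details$fingerprint, fitB@details$fingerprint))
    stopf("fits are not on identical subject sets")
  2 * (max(fitA@loglikTrace) - max(fitB@loglikTrace))
}
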
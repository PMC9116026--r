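#' Maximum-likelihood stratified logistic regression
#'
#' Thin, strict wrapper around iteratively reweighted least squares
#' (`glm.fit`) returning a [LogisticFit-class]. Honours fractional
#' observation weights (required by the mixture model's weighted
#' maximization step) and a fixed offset (required by the validation refits
#' with fixed effect sizes). Wald 95% confidence intervals and p-values are
#' available through [orTable()].
#'
#' Errors rather than degrading silently: rank-deficient designs (e.g. a
#' duplicated covariate) raise a design error, and complete separation
#' (diverging coefficients) raises a separation error.
#'
#' @param outcome binary vector: 0/1, logical, or "case"/"control".
#' @param design numeric matrix of covariate columns (no intercept column;
#'   one is added), or NULL for an intercept-only model.
#' @param weights optional non-negative observation weights.
#' @param offset optional fixed linear-predictor component.
#' @return a [LogisticFit-class].
#' @export
fitLogistic <- function(outcome, design = NULL, weights = NULL, offset = NULL) {
  y <- normalizeOutcome(outcome)
  n <- length(y)
  if (is.null(design)) {
    X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    design <- as.matrix(design)
    if (nrow(design) != n) stopf("design rows do not match outcome length")
    if (ncol(design) > 0L && is.null(colnames(design)))
      colnames(design) <- paste0("x", seq_len(ncol(design)))
    X <- cbind("(Intercept)" = 1, design)
  }
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(is.na(w)) || any(w < 0))
    stopf("weights must be non-negative and match the outcome length")
  off <- if (is.null(offset)) rep(0, n) else as.numeric(offset)
  active <- w > 0
  if (length(unique(y[active])) < 2L)
    stopf("both outcome classes must be present")
  if (qr(X * sqrt(pmax(w, 1e-12)))$rank < ncol(X))
    stopf("design error: rank-deficient design (collinear or duplicated covariates)")
  fit <- suppressWarnings(
    glm.fit(x = X, y = y, weights = w, offset = off, family = binomial(),
            control = list(epsilon = 1e-10, maxit = 100L)))
  beta <- fit$coefficients
  if (anyNA(beta))
    stopf("design error: coefficients not estimable")
  # scale-aware separation check: a coefficient whose contribution to the
  # linear predictor spans > 30 logits over the data (or a diverging
  # intercept) indicates (quasi-)complete separation
  colSpan <- apply(X[active, -1L, drop = FALSE], 2L, function(z)
    diff(range(z)))
  if (abs(beta[1L]) > 30 ||
      (ncol(X) > 1L && any(abs(beta[-1L]) * colSpan > 30)))
    stopf("separation error: diverging coefficient estimates")
  p <- fit$fitted.values
  eps <- 1e-12
  ll <- sum(w * (y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps))))
  # unscaled covariance from the final IRLS weighted QR (inverse information)
  Qr <- fit$qr
  rank <- fit$rank
  p1 <- seq_len(rank)
  covUn <- chol2inv(Qr$qr[p1, p1, drop = FALSE])
  cov <- matrix(NA_real_, ncol(X), ncol(X),
                dimnames = list(colnames(X), colnames(X)))
  piv <- Qr$pivot[p1]
  cov[piv, piv] <- covUn
  new("LogisticFit", coefficients = beta, covariance = cov,
      loglik = ll, n = sum(w), converged = fit$converged)
}

normalizeOutcome <- function(outcome) {
  if (is.character(outcome) || is.factor(outcome)) {
    outcome <- as.character(outcome)
    if (!all(outcome %in% c("case", "control")))
      stopf("character outcome must be 'case'/'control'")
    return(as.numeric(outcome == "case"))
  }
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1))) stopf("outcome must be binary")
  y
}

# dummy-coded stratum design; reference = largest stratum by subject count
stratumDesign <- function(stratum, levels = NULL) {
  f <- factor(stratum, levels = levels %||%
                names(sort(table(stratum), decreasing = TRUE)))
  if (nlevels(f) < 2L)
    return(matrix(numeric(0), length(stratum), 0L))
  X <- outer(as.character(f), levels(f)[-1L], `==`) * 1
  colnames(X) <- paste0("stratum", levels(f)[-1L])
  X
}
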
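#' @import methods
#' @importFrom stats plogis qlogis glm.fit binomial pchisq pnorm qchisq
#'   quantile rbinom runif rnorm qnorm setNames aggregate coef vcov logLik
#' @importFrom utils read.delim write.table packageVersion head
NULL

# log(exp(a) + exp(b)) without overflow, elementwise
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

logsumexp3 <- function(a, b, d) {
  m <- pmax(a, pmax(b, d))
  m + log(exp(a - m) + exp(b - m) + exp(d - m))
}

# run `expr` under a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(x, y) if (is.null(x)) y else x

# sentinel-aware column coercions used by the TSV readers
naChr <- function(x) {
  x <- as.character(x)
  x[x %in% c("NA", "")] <- NA_character_
  x
}
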
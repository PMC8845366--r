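# internal helpers

logit <- function(p) stats::qlogis(p)
expit <- function(x) stats::plogis(x)

# clamp betas away from {0,1} so logit-space operations stay finite
clampBeta <- function(x, eps = 1e-4) pmin(pmax(x, eps), 1 - eps)

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

checkNumericMatrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("%s must be a numeric matrix", what)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stopf("%s must have row and column names", what)
  invisible(x)
}

# open a connection that transparently handles gzip by file extension
openInput <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

# derive a child RNG seed from a parent seed and a stage name, stable across
# runs and below 2^31
childSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}
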
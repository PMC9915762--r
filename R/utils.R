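## Internal helpers shared across modules.

#' Cosine similarity between two population vectors
#'
#' The subspace correlation statistic: the unit-vector dot product
#' v1 . v2 / (|v1| |v2|).
#'
#' @param v1,v2 numeric vectors of equal length >= 2 with nonzero norm.
#' @return a number in \[-1, 1\].
#' @examples
#' cosineSimilarity(c(1, 0), c(0, 1))
#' @export
cosineSimilarity <- function(v1, v2) {
  if (length(v1) != length(v2) || length(v1) < 2)
    stop("v1 and v2 must have equal length >= 2")
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0)
    stop("cosine similarity is undefined for a zero vector")
  s <- sum(v1 * v2) / (n1 * n2)
  max(-1, min(1, s))
}

## Evaluate expr under a local RNG state seeded with `seed`, restoring the
## caller's stream afterwards. All stochastic operations route through this.
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) stop("an explicit integer seed is required")
  withr::with_seed(as.integer(seed), expr)
}

## Derive a distinct child seed from a parent seed and a stream label,
## keeping the result well inside 32-bit integer range.
childSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * 131L^(seq_along(
    utf8ToInt(as.character(stream))) %% 5L))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483597) + 1L
}

## Column-wise z-score; returns list(x, keep) where columns with zero
## variance are dropped and reported.
zscoreColumns <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  keep <- is.finite(s) & s > 0
  z <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, s[keep], "/")
  list(z = z, keep = keep, mean = mu, sd = s)
}

## Sign-preserving square root (for reporting signed squared distances).
signedSqrt <- function(x) sign(x) * sqrt(abs(x))

## The four condition codes of the 2 x 2 (value x context) stimulus grid,
## in the canonical column order of the M matrix.
condCodes <- function() c("11", "21", "12", "22")

condToValue <- function(cond) as.integer(substr(cond, 1, 1))
condToContext <- function(cond) as.integer(substr(cond, 2, 2))
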
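## Hartigan's dip statistic and a bootstrap dip test of unimodality.
## The statistic is computed in C++ (src/dip.cpp) from its definition: the
## minimal sup-distance between the empirical CDF and the class of
## unimodal CDFs (convex below the mode, concave above it, with at most
## one jump, at the mode), found by bisection on the tolerance with exact
## band-feasibility checks for every mode position.

#' Hartigan's dip statistic
#'
#' The maximum difference, over all x, between the empirical CDF and the
#' closest unimodal CDF. Bounded below by 1/(2n); equals 1/4 for two
#' equally sized point masses and 1/(2k) for k well-separated equal
#' spikes.
#'
#' @param x numeric sample (n >= 2 for a nonzero statistic).
#' @return the dip statistic.
#' @examples
#' dipStatistic(c(0, 1))          # 0.25
#' dipStatistic(rep(c(0, 1), 50)) # 0.25, two point masses
#' @export
dipStatistic <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(0)
  .dipCpp(as.numeric(x))
}

#' Dip test of unimodality with a bootstrap uniform null
#'
#' p value from `nBoot` uniform samples of the same size (the least
#' favorable unimodal null): p = (#(dip_null >= dip_obs) + 1) /
#' (nBoot + 1). A constant sample returns statistic 0 and p = 1.
#'
#' @param values numeric sample (n >= 10).
#' @param nBoot bootstrap null draws (default 1000).
#' @param seed integer seed.
#' @param nullDips optional precomputed null dips (see [dipNull()]),
#'   overriding `nBoot`/`seed`; the null must have been drawn at the same
#'   sample size.
#' @return list(statistic, p, n).
#' @export
dipTest <- function(values, nBoot = 1000, seed = 1, nullDips = NULL) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 10) stop("dip test needs a sample of size >= 10")
  d <- dipStatistic(values)
  if (d == 0) return(list(statistic = 0, p = 1, n = n))
  if (is.null(nullDips)) nullDips <- dipNull(n, nBoot, seed)
  p <- (sum(nullDips >= d) + 1) / (length(nullDips) + 1)
  list(statistic = d, p = p, n = n)
}

#' Null distribution of the dip statistic under uniformity
#'
#' @param n sample size.
#' @param nBoot number of draws.
#' @param seed integer seed.
#' @return numeric vector of null dip statistics.
#' @export
dipNull <- function(n, nBoot = 1000, seed = 1) {
  withSeed(seed, vapply(seq_len(nBoot),
                        function(b) dipStatistic(runif(n)), numeric(1)))
}
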
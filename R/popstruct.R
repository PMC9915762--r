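## Population structure: the value-space firing-rate sensitivity index and
## its bimodality (dip) test, participation-ratio subspace contributions,
## and the gain-vs-heterogeneous neuron classification.

#' Value-space firing-rate sensitivity index
#'
#' For each neuron, the difference between its left- and right-side value
#' tuning coefficients after z-scoring each side's coefficient vector
#' across the population: index(n) = z(coef_left)(n) - z(coef_right)(n).
#' Two side-specialized subpopulations produce a bimodal index
#' distribution; a shared heterogeneous population produces a unimodal
#' one. The index is invariant to population-level per-side affine
#' transforms of the coefficients (a common gain or offset on one side is
#' removed by that side's z-scoring).
#'
#' Inputs may be the per-side value coefficients directly, or per-side
#' value-binned rate matrices (neurons x bins), from which the coefficient
#' is the OLS slope of rate on (centered) bin level. Neurons with zero
#' rate variance on either side are excluded and reported.
#'
#' @param left,right numeric coefficient vectors (length N), or neurons x
#'   bins matrices of value-binned mean rates.
#' @return numeric vector of indices (NA for excluded neurons) with
#'   attribute `excluded`.
#' @export
sensitivityIndex <- function(left, right) {
  toCoef <- function(m) {
    if (is.null(dim(m))) return(list(coef = m, bad = rep(FALSE, length(m))))
    lv <- seq_len(ncol(m)) - (ncol(m) + 1) / 2
    bad <- apply(m, 1, function(r) var(r) == 0)
    list(coef = as.numeric(m %*% lv) / sum(lv^2), bad = bad)
  }
  L <- toCoef(left); R <- toCoef(right)
  if (length(L$coef) != length(R$coef))
    stop("left and right must describe the same neurons")
  bad <- L$bad | R$bad
  z <- function(v) (v - mean(v[!bad])) / sd(v[!bad])
  idx <- z(L$coef) - z(R$coef)
  idx[bad] <- NA_real_
  attr(idx, "excluded") <- which(bad)
  idx
}

#' Participation-ratio subspace contribution
#'
#' Each neuron's fractional contribution to a subspace vector:
#' contribution(n) = v(n)^4 / sum_j v(j)^4 (the normalized fourth-power
#' share, an approximation to the neuron's variance share of the
#' subspace). The retained set is the smallest set of top-ranked neurons
#' whose cumulative contribution reaches `retain` (0.95 by default); a
#' count-percentile alternative is available via `mode = "count"`.
#'
#' @param v a value-subspace vector (length N, nonzero).
#' @param retain retention level (0.95).
#' @param mode "cumulative" (default) or "count" (top `retain` fraction of
#'   neurons by contribution).
#' @return list with `contribution` (sums to 1) and `retained` (neuron
#'   indices).
#' @export
subspaceContribution <- function(v, retain = 0.95,
                                 mode = c("cumulative", "count")) {
  mode <- match.arg(mode)
  if (all(v == 0)) stop("subspace contribution undefined for a zero vector")
  contrib <- v^4 / sum(v^4)
  ord <- order(contrib, decreasing = TRUE)
  retained <- if (mode == "cumulative") {
    kk <- which(cumsum(contrib[ord]) >= retain)[1]
    ord[seq_len(kk)]
  } else ord[seq_len(ceiling(retain * length(v)))]
  list(contribution = contrib, retained = sort(retained))
}

#' Classify a neuron as gain-modulated or heterogeneous
#'
#' Bootstrap test of whether a neuron's preferred value (the arg-peak of
#' its mean rate over 7 equally distributed value levels) shifts between
#' the two sides. Trials are resampled `nBoot` times; per resample the
#' peak level is found per side; the observed mean peak difference is
#' referenced to a permutation null built by shuffling the pooled peak
#' vectors. Neurons that pass the multi-subspace retention criterion on
#' only one side are labeled "single_subspace"; flat tuning on either side
#' excludes the neuron.
#'
#' @param ratesLeft,ratesRight trials x 1 rate vectors (the neuron's
#'   window rates) for left and right offers.
#' @param valueLeft,valueRight per-trial values on each side.
#' @param inBoth logical: does the neuron meet the retention criterion in
#'   both subspaces? (FALSE returns class "single_subspace".)
#' @param nBoot bootstrap resamples (1000).
#' @param seed integer seed.
#' @param nLevels value levels (7).
#' @param alpha significance level for the shift test (0.05).
#' @return list with `class` ("gain", "heterogeneous", "single_subspace"
#'   or "excluded"), `p`, and the per-side mean peaks.
#' @export
classifyGainVsHeterogeneous <- function(ratesLeft, ratesRight, valueLeft,
                                        valueRight, inBoth = TRUE,
                                        nBoot = 1000, seed = 1,
                                        nLevels = 7, alpha = 0.05) {
  if (!inBoth)
    return(list(class = "single_subspace", p = NA_real_,
                peakLeft = NA_real_, peakRight = NA_real_))
  binIt <- function(v) {
    br <- quantile(v, seq(0, 1, length.out = nLevels + 1))
    br <- unique(br)
    as.integer(cut(v, br, include.lowest = TRUE))
  }
  bl <- binIt(valueLeft); br <- binIt(valueRight)
  tune <- function(r, b) vapply(seq_len(max(b)), function(k)
    mean(r[b == k]), numeric(1))
  if (var(tune(ratesLeft, bl)) == 0 || var(tune(ratesRight, br)) == 0)
    return(list(class = "excluded", p = NA_real_, peakLeft = NA_real_,
                peakRight = NA_real_))
  withSeed(seed, {
    peak <- function(r, b) {
      i <- sample(length(r), replace = TRUE)
      which.max(tune(r[i], b[i]))
    }
    pkL <- vapply(seq_len(nBoot), function(s) peak(ratesLeft, bl),
                  integer(1))
    pkR <- vapply(seq_len(nBoot), function(s) peak(ratesRight, br),
                  integer(1))
    obs <- abs(mean(pkL) - mean(pkR))
    pool <- c(pkL, pkR)
    nullD <- vapply(seq_len(nBoot), function(s) {
      i <- sample(pool, nBoot, replace = TRUE)
      j <- sample(pool, nBoot, replace = TRUE)
      abs(mean(i) - mean(j))
    }, numeric(1))
    p <- (sum(nullD >= obs) + 1) / (nBoot + 1)
    list(class = if (p < alpha) "heterogeneous" else "gain", p = p,
         peakLeft = mean(pkL), peakRight = mean(pkR))
  })
}
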
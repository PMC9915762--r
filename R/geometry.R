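## Linear-nonlinear geometry: cross-validated (crossnobis) distance
## estimation, decomposition of the 4 x 4 distance matrix into
## (dLV, dLA, dN), noise and standard-error-distance estimation, and the
## closed-form binding / CCGP error rates with Monte-Carlo decoder oracles.

#' Cross-validated squared Euclidean distance matrix (crossnobis)
#'
#' For each condition pair, trials are split into `nFolds` folds; the
#' estimate is the average over ordered fold pairs (a != b) of the inner
#' product between the fold-a and fold-b mean-difference vectors. The
#' estimator is unbiased for the squared centroid distance (expected 0 for
#' identical distributions, so single estimates can be negative). No
#' noise-whitening is applied.
#'
#' @param data named list of trials x neurons matrices, one per condition.
#' @param nFolds folds per condition (>= 2; 5 by default).
#' @param seed integer seed for the fold partition.
#' @return list with `D2` (signed squared-distance matrix), `D`
#'   (sign-preserving square root, for reporting) and `folds` metadata.
#' @export
crossnobisMatrix <- function(data, nFolds = 5, seed = 1) {
  conds <- names(data)
  if (is.null(conds)) stop("data must be a named list of condition matrices")
  if (nFolds < 2) stop("nFolds must be >= 2")
  short <- conds[vapply(data, nrow, integer(1)) < nFolds]
  if (length(short))
    stop("conditions with fewer trials than folds: ",
         paste(short, collapse = ", "))
  withSeed(seed, {
    foldMeans <- lapply(data, function(X) {
      n <- nrow(X)
      f <- sample(rep_len(seq_len(nFolds), n))
      t(vapply(seq_len(nFolds), function(k)
        colMeans(X[f == k, , drop = FALSE]), numeric(ncol(X))))
    })
    K <- length(conds)
    D2 <- matrix(0, K, K, dimnames = list(conds, conds))
    for (i in seq_len(K - 1)) for (j in (i + 1):K) {
      ip <- 0; np <- 0
      for (a in seq_len(nFolds)) for (b in seq_len(nFolds)) if (a != b) {
        da <- foldMeans[[i]][a, ] - foldMeans[[j]][a, ]
        db <- foldMeans[[i]][b, ] - foldMeans[[j]][b, ]
        ip <- ip + sum(da * db); np <- np + 1
      }
      D2[i, j] <- D2[j, i] <- ip / np
    }
    list(D2 = D2, D = signedSqrt(D2),
         folds = list(nFolds = nFolds, seed = as.integer(seed)))
  })
}

## Split a single-epoch NeuralSession into per-condition window-mean
## matrices.
conditionMatrices <- function(neural, window = NULL) {
  Y <- windowMeans(neural, window)
  lab <- conditionLabels(neural)
  split.data.frame(Y, factor(lab$cond, levels = condCodes()))
}

## Model squared-distance matrix for parameters (a, b, c) =
## (dLV^2, dLA^2, dN^2) over conditions 11, 21, 12, 22.
.modelD2 <- function(a, b, c) {
  conds <- condCodes()
  K <- length(conds)
  D <- matrix(0, K, K, dimnames = list(conds, conds))
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    dv <- condToValue(conds[i]) != condToValue(conds[j])
    dc <- condToContext(conds[i]) != condToContext(conds[j])
    D[i, j] <- D[j, i] <- a * dv + b * dc + c * (dv || dc)
  }
  D
}

#' Decompose a distance matrix into linear and nonlinear distances
#'
#' Least-squares fit of the linear-nonlinear model to the six squared
#' distances: value-differing pairs dLV^2 + dN^2, context-differing pairs
#' dLA^2 + dN^2, diagonal pairs dLV^2 + dLA^2 + dN^2 (equal nonlinear
#' perturbation lengths assumed). The fit is a nonnegatively-constrained
#' linear least-squares problem in (dLV^2, dLA^2, dN^2), solved from
#' `nStarts` initializations; the spread across solutions is reported as a
#' stability check.
#'
#' @param D2 symmetric 4 x 4 matrix of (possibly signed) squared distances
#'   with rows/columns ordered 11, 21, 12, 22, or the list returned by
#'   [crossnobisMatrix()].
#' @param nStarts multi-start initializations (10 by default).
#' @param seed integer seed for the starts.
#' @return a [GeometryEstimate-class] (sigma/epsilon NA; see
#'   [estimateNoiseSigma()] and [estimateSemDistance()]).
#' @export
decomposeDistances <- function(D2, nStarts = 10, seed = 1) {
  if (is.list(D2)) D2 <- D2$D2
  if (any(!is.finite(D2))) stop("distance matrix has non-finite entries")
  if (!isTRUE(all.equal(D2, t(D2), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  conds <- condCodes()
  D2 <- D2[conds, conds]
  up <- which(upper.tri(D2))
  y <- D2[up]
  dv <- outer(condToValue(conds), condToValue(conds), "!=")[up]
  dc <- outer(condToContext(conds), condToContext(conds), "!=")[up]
  X <- cbind(a = as.numeric(dv), b = as.numeric(dc),
             c = as.numeric(dv | dc))
  obj <- function(p) sum((y - X %*% p)^2)
  gr <- function(p) as.numeric(-2 * crossprod(X, y - X %*% p))
  sols <- withSeed(seed, lapply(seq_len(nStarts), function(s) {
    p0 <- abs(rnorm(3, sd = max(abs(y), 1)))
    optim(p0, obj, gr, method = "L-BFGS-B", lower = 0)$par
  }))
  S <- do.call(rbind, sols)
  best <- S[which.min(apply(S, 1, obj)), ]
  spread <- max(apply(S, 2, function(x) diff(range(x))))
  d <- sqrt(pmax(best, 0))
  rho <- if (d[1] == 0 && d[3] == 0) NA_real_
         else d[1]^2 / (d[1]^2 + d[3]^2)
  new("GeometryEstimate", dLV = d[1], dLA = d[2], dN = d[3],
      rho = rho, residual = sqrt(obj(best) / length(y)),
      details = list(D2 = D2, multistartSpread = spread))
}

#' Noise SD along the value decoding dimension
#'
#' The decoder axis is the (unit-normalized) difference between the
#' training-pair centroids (x21 - x11 by default); sigma^2 is the mean over
#' all conditions and trials of the squared projection of the
#' trial-minus-condition-mean residual onto that axis.
#'
#' @param data named list of trials x neurons matrices per condition.
#' @param trainPair the two conditions defining the axis.
#' @return sigma (>= 0).
#' @export
estimateNoiseSigma <- function(data, trainPair = c("11", "21")) {
  if (any(vapply(data, nrow, integer(1)) < 2))
    stop("each condition needs >= 2 trials")
  v <- colMeans(data[[trainPair[2]]]) - colMeans(data[[trainPair[1]]])
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("decoder axis has zero norm")
  u <- v / nv
  pr <- unlist(lapply(data, function(X)
    as.numeric(scale(X, center = TRUE, scale = FALSE) %*% u)))
  sqrt(mean(pr^2))
}

#' Standard-error distance of the condition centroids
#'
#' Combines the per-condition centroid standard errors into the single
#' distance epsilon that enters dNeps = sqrt(dN^2 + eps^2): per condition
#' eps_c^2 = sum_j s_jc^2 / n_c (squared SEM distance of the centroid), and
#' eps^2 = 2 * mean_c eps_c^2, the factor 2 reflecting that a centroid
#' *difference* carries the estimation error of two centroids. For
#' isotropic noise this scales as sigma * sqrt(2 N / n).
#'
#' @param data named list of trials x neurons matrices per condition.
#' @return epsilon (>= 0).
#' @export
estimateSemDistance <- function(data) {
  if (any(vapply(data, nrow, integer(1)) < 2))
    stop("each condition needs >= 2 trials")
  e2 <- vapply(data, function(X) sum(apply(X, 2, var)) / nrow(X),
               numeric(1))
  sqrt(2 * mean(e2))
}

#' Implied subspace correlation from the code distances
#'
#' rho = dLV^2 / (dLV^2 + dN^2).
#'
#' @param dLV,dN nonnegative distances, not both zero.
#' @return rho in \[0, 1\].
#' @export
impliedSubspaceCorrelation <- function(dLV, dN) {
  if (dLV < 0 || dN < 0) stop("distances must be nonnegative")
  if (dLV == 0 && dN == 0)
    stop("subspace correlation undefined when dLV = dN = 0")
  dLV^2 / (dLV^2 + dN^2)
}

#' Enumerate linearly confusable stimulus sets
#'
#' For stimuli with `K` features of `nLevels` levels each, enumerates all
#' ordered presented pairs of stimuli and, for each, the distinct *other*
#' unordered stimulus multisets whose feature-wise (linear) sums are equal
#' - the chimeric sets a purely linear code cannot distinguish from the
#' presented one. N_S is the average count across all ordered pairs; for
#' the 2 x 2 two-stimulus case N_S = 1/4.
#'
#' @param K number of features (2 by default).
#' @param nLevels levels per feature (2 by default).
#' @return list with `NS` and a data.frame of confusable pairs.
#' @export
confusableSets <- function(K = 2, nLevels = 2) {
  stim <- as.matrix(expand.grid(rep(list(seq_len(nLevels)), K)))
  ns <- nrow(stim)
  key <- function(i, j) paste(sort(c(i, j)), collapse = "+")
  sumKey <- function(i, j) paste(stim[i, ] + stim[j, ], collapse = ",")
  pairs <- expand.grid(i = seq_len(ns), j = seq_len(ns))
  counts <- integer(nrow(pairs))
  rows <- list()
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    own <- key(i, j); s <- sumKey(i, j)
    alts <- character()
    for (a in seq_len(ns)) for (b in a:ns)
      if (sumKey(a, b) == s && key(a, b) != own)
        alts <- c(alts, key(a, b))
    alts <- unique(alts)
    counts[r] <- length(alts)
    if (length(alts))
      rows[[length(rows) + 1]] <-
        data.frame(presented = own, chimeric = alts)
  }
  list(NS = mean(counts),
       confusable = if (length(rows)) unique(do.call(rbind, rows))
                    else data.frame(presented = character(),
                                    chimeric = character()))
}

#' Closed-form binding error rate
#'
#' Union-bound approximation N_S * Q(-d_S / (2 sigma)) with
#' d_S = sqrt(2) dN (the distance between the summed representations of a
#' presented stimulus set and its chimeric counterpart) and N_S the average
#' number of confusable sets (1/4 for the 2 x 2, two-stimulus case,
#' computed by enumeration). Q is the standard normal CDF, oriented so the
#' rate decreases in dN / sigma. At sigma = 0 the rate is 0 for dN > 0 and
#' N_S / 2 (chance among confusable sets) for dN = 0.
#'
#' @param dN nonlinear distance (>= 0).
#' @param sigma noise SD (>= 0).
#' @return misbinding probability.
#' @export
predictedBindingError <- function(dN, sigma) {
  if (dN < 0 || sigma < 0) stop("dN and sigma must be nonnegative")
  NS <- 1 / 4  # enumeration over the 2x2 grid; see confusableSets()
  dS <- sqrt(2) * dN
  if (sigma == 0) return(if (dN > 0) 0 else NS / 2)
  NS * pnorm(-dS / (2 * sigma))
}

#' Monte-Carlo oracle for the binding error rate
#'
#' Simulates presented two-stimulus sets drawn uniformly from all ordered
#' stimulus pairs of the 2 x 2 grid, generates the summed population
#' response under `spec` plus isotropic noise, and decodes the stimulus
#' multiset with a maximum-likelihood (nearest summed-centroid) decoder
#' over all candidate multisets, breaking ties uniformly at random. The
#' oracle rate is the fraction of presentations decoded as a chimeric
#' (linearly confusable, non-identical) multiset.
#'
#' @param spec a [PopulationCodeSpec-class].
#' @param nMC Monte-Carlo presentations (>= 1000 recommended).
#' @param seed integer seed.
#' @return rate with attribute `se`.
#' @export
bindingErrorOracle <- function(spec, nMC = 100000, seed = 1) {
  if (nMC < 1000)
    warning("nMC < 1000: Monte-Carlo SE will be large")
  C <- conditionCentroids(spec)       # 4 x N single-stimulus responses
  conds <- rownames(C)
  ## candidate multisets {a, b} (a <= b) and their summed responses
  cand <- which(upper.tri(matrix(0, 4, 4), diag = TRUE), arr.ind = TRUE)
  sums <- C[cand[, 1], , drop = FALSE] + C[cand[, 2], , drop = FALSE]
  candKey <- paste(pmin(cand[, 1], cand[, 2]),
                   pmax(cand[, 1], cand[, 2]), sep = "+")
  ## chimeric partner of each multiset: equal linear sum, different set
  zv <- ifelse(condToValue(conds) == 2, 1, 0)
  za <- ifelse(condToContext(conds) == 2, 1, 0)
  linKey <- paste(zv[cand[, 1]] + zv[cand[, 2]],
                  za[cand[, 1]] + za[cand[, 2]], sep = ",")
  chim <- lapply(seq_along(candKey), function(r)
    which(linKey == linKey[r] & candKey != candKey[r]))
  sum2 <- rowSums(sums^2)
  withSeed(seed, {
    pres <- cbind(sample.int(4, nMC, replace = TRUE),
                  sample.int(4, nMC, replace = TRUE))
    presIdx <- match(paste(pmin(pres[, 1], pres[, 2]),
                           pmax(pres[, 1], pres[, 2]), sep = "+"),
                     candKey)
    err <- 0L
    block <- 20000L
    for (s0 in seq(1L, nMC, by = block)) {
      sel <- s0:min(s0 + block - 1L, nMC)
      R <- C[pres[sel, 1], , drop = FALSE] +
           C[pres[sel, 2], , drop = FALSE] +
           matrix(rnorm(length(sel) * ncol(C), sd = spec@sigma),
                  length(sel), ncol(C))
      ## nearest summed centroid: argmax of 2 R.mu - |mu|^2; exact ties
      ## (identical candidate centroids) broken uniformly at random
      score <- 2 * R %*% t(sums) -
        matrix(sum2, length(sel), length(candKey), byrow = TRUE)
      dec <- max.col(score, ties.method = "random")
      chimOf <- chim[presIdx[sel]]
      err <- err + sum(mapply(function(d, ch) d %in% ch, dec, chimOf))
    }
    rate <- err / nMC
    attr(rate, "se") <- sqrt(rate * (1 - rate) / nMC)
    rate
  })
}

#' Closed-form cross-condition generalization (CCGP) error rate
#'
#' Q(-(1 / sigma) * (1/2) * dLV^2 / sqrt(dLV^2 + dNeps^2)) with
#' dNeps^2 = dN^2 + epsilon^2; Q the standard normal CDF, oriented so the
#' error decreases in dLV. At sigma = 0 the limit is 0 for dLV > 0 and 1/2
#' (chance) for dLV = 0.
#'
#' @param dLV,dN nonnegative distances.
#' @param sigma noise SD (> 0, or 0 for the limit).
#' @param epsilon standard-error distance (0 by default).
#' @return generalization error probability.
#' @export
predictedCcgpError <- function(dLV, dN, sigma, epsilon = 0) {
  if (any(c(dLV, dN, sigma, epsilon) < 0))
    stop("all inputs must be nonnegative")
  if (sigma == 0) return(if (dLV > 0) 0 else 0.5)
  dNe2 <- dN^2 + epsilon^2
  pnorm(-(1 / sigma) * 0.5 * dLV^2 / sqrt(dLV^2 + dNe2))
}

#' Monte-Carlo prototype-decoder oracle for the CCGP error rate
#'
#' Trains a prototype (nearest-class-centroid) decoder on simulated trials
#' of x11 vs x21, then tests it on fresh trials of x12 vs x22; the oracle
#' rate is the misclassification fraction on the test conditions. With
#' many training trials the centroid-estimation error epsilon vanishes and
#' the closed form [predictedCcgpError()] is exact for this decoder.
#'
#' @param spec a [PopulationCodeSpec-class].
#' @param nTest Monte-Carlo test trials (total across the two conditions).
#' @param nTrain training trials per training condition.
#' @param seed integer seed.
#' @return rate with attributes `se` and `epsilonTrain` (the implied
#'   standard-error distance of the training centroids).
#' @export
ccgpOracle <- function(spec, nTest = 50000, nTrain = 5000, seed = 1) {
  C <- conditionCentroids(spec)
  N <- ncol(C)
  withSeed(seed, {
    noise <- function(n) matrix(rnorm(n * N, sd = spec@sigma), n, N)
    mu11 <- colMeans(C[rep("11", nTrain), , drop = FALSE] + noise(nTrain))
    mu21 <- colMeans(C[rep("21", nTrain), , drop = FALSE] + noise(nTrain))
    w <- mu21 - mu11
    thr <- sum(w * (mu11 + mu21)) / 2
    nHalf <- ceiling(nTest / 2)
    err <- 0L
    for (cond in c("12", "22")) {
      R <- C[rep(cond, nHalf), , drop = FALSE] + noise(nHalf)
      s <- as.numeric(R %*% w) - thr
      ## x12 is low value (negative side), x22 high value
      err <- err + if (cond == "12") sum(s > 0) else sum(s <= 0)
    }
    rate <- err / (2 * nHalf)
    attr(rate, "se") <- sqrt(rate * (1 - rate) / (2 * nHalf))
    attr(rate, "epsilonTrain") <- spec@sigma * sqrt(2 * N / nTrain)
    rate
  })
}

#' Full geometry estimate from a single-epoch session
#'
#' Convenience wrapper: crossnobis distances, decomposition, noise sigma
#' along the value axis and the standard-error distance, plus the implied
#' subspace correlation.
#'
#' @param neural a single-epoch [NeuralSession-class].
#' @param window analysis window in ms (full epoch by default).
#' @param nFolds crossnobis folds.
#' @param seed integer seed.
#' @return a [GeometryEstimate-class].
#' @export
estimateGeometry <- function(neural, window = NULL, nFolds = 5, seed = 1) {
  data <- conditionMatrices(neural, window)
  cn <- crossnobisMatrix(data, nFolds = nFolds, seed = seed)
  g <- decomposeDistances(cn, seed = childSeed(seed, "decomp"))
  g@sigma <- estimateNoiseSigma(data)
  g@epsilon <- estimateSemDistance(data)
  g
}

#' Predicted and oracle error rates for a population code
#'
#' @param spec a [PopulationCodeSpec-class].
#' @param epsilon standard-error distance entering the CCGP prediction.
#' @param nMC oracle Monte-Carlo size (0 skips the oracles).
#' @param seed integer seed.
#' @return an [ErrorRatePrediction-class].
#' @export
predictErrorRates <- function(spec, epsilon = 0, nMC = 0, seed = 1) {
  pred <- new("ErrorRatePrediction",
              bindingError = predictedBindingError(spec@dN, spec@sigma),
              ccgpError = predictedCcgpError(spec@dLV, spec@dN,
                                             spec@sigma, epsilon))
  if (nMC > 0) {
    b <- bindingErrorOracle(spec, nMC = nMC, seed = childSeed(seed, "bind"))
    g <- ccgpOracle(spec, nTest = nMC, seed = childSeed(seed, "ccgp"))
    pred@bindingMC <- as.numeric(b); pred@bindingMCSE <- attr(b, "se")
    pred@ccgpMC <- as.numeric(g); pred@ccgpMCSE <- attr(g, "se")
  }
  pred
}
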
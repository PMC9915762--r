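## Population value subspaces: value vectors built from regression
## coefficients, their correlation against a bootstrap noise ceiling, the
## alignment index, the effective minimum population size, and the link
## between subspace correlation and suboptimal choice.

#' Value-subspace vector for one side and window
#'
#' The population vector pointing from the model-predicted response at
#' value = 0 to the response at value = 1 for offers on the stated side:
#' v(n) = beta_value(n) + side * beta_interaction(n). The intercept and
#' side main effect cancel in the subtraction. Requires the
#' interaction-lin model.
#'
#' @param fits a `neuronFits` object from [fitNeuronModels()].
#' @param side "left" (+1) or "right" (-1).
#' @return numeric vector of length nNeurons.
#' @export
valueSubspaceVector <- function(fits, side = c("left", "right")) {
  side <- match.arg(side)
  cf <- fits$models[["interaction-lin"]]$coef
  if (is.null(cf)) stop("interaction-lin coefficients are required")
  sc <- if (side == "left") 1 else -1
  v <- cf["value", ] + sc * cf["value:side", ]
  unname(v)
}

#' Subspace correlation between two value vectors
#'
#' Cosine similarity (unit-vector dot product) between the two population
#' value vectors; Pearson correlation is reported alongside as an
#' attribute.
#'
#' @param v1,v2 value vectors of equal length >= 2, nonzero norm.
#' @return correlation in \[-1, 1\] with attribute `pearson`.
#' @export
subspaceCorrelation <- function(v1, v2) {
  r <- cosineSimilarity(v1, v2)
  attr(r, "pearson") <- if (sd(v1) > 0 && sd(v2) > 0) cor(v1, v2)
                        else NA_real_
  r
}

## Refit the interaction-lin model for all neurons on a trial subset and
## return the left/right value vectors. Y: trials x neurons; design has
## value in [0,1] and side in {-1, +1}.
.refitValueVectors <- function(Y, design, idx = seq_len(nrow(Y))) {
  X <- cbind(1, design$value[idx], design$side[idx],
             design$value[idx] * design$side[idx])
  B <- qr.coef(qr(X), Y[idx, , drop = FALSE])
  list(left = B[2, ] + B[4, ], right = B[2, ] - B[4, ])
}

#' Bootstrap noise-ceiling test of subspace separability
#'
#' For each of `nBoot` bootstrap iterations the trials are split into two
#' disjoint random halves and the interaction model is refitted on each
#' half. The observed draw is the correlation between the left value
#' vector from one half and the right value vector from the other; the
#' ceiling draw is the correlation between the same-side value vectors
#' across the two halves (left for the first nBoot/2 iterations, right
#' for the rest) - the correlation expected if the two sides shared one
#' value code and disagreement arose only from firing-rate noise. Because
#' the two vectors entering every correlation come from disjoint trials,
#' observed and ceiling draws carry the same noise attenuation, which
#' calibrates the comparison (see the methods vignette). The bootstrap
#' p value is the fraction of iterations with observed >= ceiling (+1
#' correction); small p flags separable (semi-orthogonal) subspaces.
#'
#' @param neural a single-epoch [NeuralSession-class] with value/side
#'   labels, or NULL if `Y` and `design` are given.
#' @param nBoot number of bootstrap iterations (even; 1000 by default).
#' @param seed integer seed.
#' @param Y,design optional trials x neurons matrix and design data.frame
#'   (value in \[0,1\], side -1/+1) overriding `neural`.
#' @param window window to average when `neural` is given.
#' @return a [SubspaceCorrelationResult-class].
#' @export
noiseCeilingTest <- function(neural = NULL, nBoot = 1000, seed = 1,
                             Y = NULL, design = NULL, window = c(0, 400)) {
  if (nBoot %% 2 != 0) stop("nBoot must be even (ceiling uses two halves)")
  if (is.null(Y)) {
    Y <- windowMeans(neural, window)
    lab <- conditionLabels(neural)
    design <- data.frame(value = lab$value - min(lab$value),
                         side = ifelse(lab$side == 1, 1, -1))
    design$value <- design$value / max(design$value)
  }
  n <- nrow(Y)
  half <- nBoot / 2
  withSeed(seed, {
    obs <- numeric(nBoot); ceil <- numeric(nBoot)
    for (b in seq_len(nBoot)) {
      idx <- sample.int(n)
      ia <- idx[seq_len(n %/% 2)]
      ib <- idx[(n %/% 2 + 1):n]
      va <- .refitValueVectors(Y, design, sample(ia, replace = TRUE))
      vb <- .refitValueVectors(Y, design, sample(ib, replace = TRUE))
      obs[b] <- cosineSimilarity(va$left, vb$right)
      ceil[b] <- if (b <= half) cosineSimilarity(va$left, vb$left)
                 else cosineSimilarity(va$right, vb$right)
    }
    p <- (sum(obs >= ceil) + 1) / (nBoot + 1)
    new("SubspaceCorrelationResult", observed = obs, ceiling = ceil,
        p = p)
  })
}

#' The six task-functional subspace comparisons
#'
#' Computes the left-vs-right value-vector correlations within each offer
#' epoch, across epochs, and the same-side across-epoch correlations, all
#' from the fitted interaction-model coefficients of the four analysis
#' windows.
#'
#' @param fitsByWindow named list of `neuronFits` objects (names are
#'   windows, e.g. offer1/offer2 or delay1/delay2 for a matched epoch
#'   pair).
#' @return data.frame of comparisons and correlations.
#' @export
subspaceComparisons <- function(fitsByWindow) {
  ws <- names(fitsByWindow)
  if (length(ws) < 2) stop("need two windows for cross-epoch comparisons")
  v <- list()
  for (w in ws) {
    v[[paste0(w, ".left")]] <- valueSubspaceVector(fitsByWindow[[w]], "left")
    v[[paste0(w, ".right")]] <- valueSubspaceVector(fitsByWindow[[w]],
                                                    "right")
  }
  w1 <- ws[1]; w2 <- ws[2]
  cmp <- rbind(
    c(paste0(w1, ".left"), paste0(w1, ".right")),
    c(paste0(w2, ".left"), paste0(w2, ".right")),
    c(paste0(w1, ".left"), paste0(w2, ".right")),
    c(paste0(w1, ".right"), paste0(w2, ".left")),
    c(paste0(w1, ".left"), paste0(w2, ".left")),
    c(paste0(w1, ".right"), paste0(w2, ".right")))
  data.frame(a = cmp[, 1], b = cmp[, 2],
             correlation = apply(cmp, 1, function(r)
               as.numeric(subspaceCorrelation(v[[r[1]]], v[[r[2]]]))))
}

#' Alignment index of data onto a subspace
#'
#' Fraction of the data's variance captured by projection onto the given
#' subspace. With `normalize = "top"` (the canonical form) the captured
#' variance is divided by the variance captured by the data's own top
#' subspace of the same dimension, so a perfectly aligned subspace scores
#' 1; with `normalize = "total"` it is divided by the total variance, so
#' a random k-dimensional subspace against isotropic data scores k/N in
#' expectation.
#'
#' @param subspaceA numeric matrix (neurons x k) whose columns span the
#'   reference subspace (orthonormalized internally).
#' @param dataB trials x neurons matrix.
#' @param normalize "top" (default) or "total".
#' @return scalar alignment index in \[0, 1\].
#' @export
alignmentIndex <- function(subspaceA, dataB,
                           normalize = c("top", "total")) {
  normalize <- match.arg(normalize)
  A <- as.matrix(subspaceA)
  if (ncol(A) > ncol(dataB))
    stop("subspace dimension exceeds the neuron count")
  Q <- qr.Q(qr(A))
  Xc <- scale(dataB, center = TRUE, scale = FALSE)
  C <- crossprod(Xc) / (nrow(Xc) - 1)
  tot <- sum(diag(C))
  if (tot <= 0) stop("dataB has zero variance")
  capt <- sum(diag(crossprod(Q, C %*% Q)))
  denom <- if (normalize == "top") {
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    sum(ev[seq_len(ncol(Q))])
  } else tot
  max(0, min(1, capt / denom))
}

#' Effective minimum population size from coefficient-variance stability
#'
#' For each candidate size, draws `nDraws` random subpopulations and
#' computes the variance of the coefficient distribution within each. The
#' stability statistic per size is the spread (SD across draws) of those
#' variance estimates: it shrinks as subpopulations grow and the variance
#' estimate stabilizes. The returned size is the plateau point - the
#' first size at which the spread changes by less than `tol` (relative)
#' from the previous size. Zero spread everywhere (identical
#' coefficients) returns the smallest size.
#'
#' @param coefs numeric vector of per-neuron regression coefficients.
#' @param sizes increasing grid of subpopulation sizes (default 5..55 by 5).
#' @param nDraws subpopulations per size (500 by default).
#' @param seed integer seed.
#' @param tol relative-change plateau tolerance (0.05 by default).
#' @return the plateau size (with attribute `profile`: per-size mean and
#'   SD of the variance estimates); the largest size with a warning when
#'   no plateau is reached.
#' @export
estimateMinPopulationSize <- function(coefs, sizes = seq(5, 55, by = 5),
                                      nDraws = 500, seed = 1, tol = 0.05) {
  N <- length(coefs)
  if (max(sizes) > N) stop("largest size exceeds the number of neurons")
  withSeed(seed, {
    vmat <- vapply(sizes, function(k)
      vapply(seq_len(nDraws), function(d)
        var(coefs[sample.int(N, k)]), numeric(1)),
      numeric(nDraws))
    mv <- colMeans(vmat)
    sv <- apply(vmat, 2, sd)
    if (all(sv == 0)) {
      out <- sizes[1]
    } else {
      rel <- abs(diff(sv)) / pmax(sv[-length(sv)], .Machine$double.eps)
      hit <- which(rel < tol)
      if (!length(hit)) {
        warning("no plateau within the size grid; returning the largest size")
        out <- sizes[length(sizes)]
      } else out <- sizes[hit[1] + 1]
    }
    attr(out, "profile") <- data.frame(size = sizes, variance = mv,
                                       spread = sv)
    out
  })
}

#' Link subspace correlation to suboptimal choice within a session
#'
#' For each of `nBoot` bootstrap trial resamples, refits the interaction
#' model on the resampled trials (subspace correlation) and recomputes the
#' suboptimal-choice rate on the same resample. The empirical correlation
#' across bootstraps is referenced to a permutation null (shuffling the
#' subspace-correlation vector): p = 1 - pnorm((r - mu) / sd).
#'
#' @param neural a single-epoch [NeuralSession-class] whose labels include
#'   `sv1`/`sv2` per-trial subjective values.
#' @param behavioral the paired [BehavioralSession-class] (choices).
#' @param nBoot bootstrap resamples (500 by default).
#' @param nPerm permutations for the null (1000 by default).
#' @param seed integer seed.
#' @param minNeurons required simultaneous population size (30 by default).
#' @param window analysis window in ms.
#' @return a [BehaviorLinkResult-class].
#' @export
behaviorLink <- function(neural, behavioral, nBoot = 500, nPerm = 1000,
                         seed = 1, minNeurons = 30, window = c(0, 400)) {
  if (nNeurons(neural) < minNeurons)
    stop("need at least ", minNeurons, " simultaneous neurons")
  if (nBoot < 2) stop("need at least 2 bootstrap resamples")
  Y <- windowMeans(neural, window)
  lab <- conditionLabels(neural)
  tr <- trials(behavioral)
  sv <- cbind(lab$sv1, lab$sv2)
  if (is.null(lab$sv1)) stop("labels must carry sv1/sv2 subjective values")
  design <- data.frame(value = lab$value - min(lab$value),
                       side = ifelse(lab$side == 1, 1, -1))
  design$value <- design$value / max(design$value)
  n <- nrow(Y)
  withSeed(seed, {
    corrs <- numeric(nBoot); rates <- numeric(nBoot)
    for (b in seq_len(nBoot)) {
      idx <- sample.int(n, replace = TRUE)
      vv <- .refitValueVectors(Y, design, idx)
      corrs[b] <- cosineSimilarity(vv$left, vv$right)
      sub <- behavioral
      sub@trials <- tr[idx, , drop = FALSE]
      rates[b] <- suboptimalChoiceRate(sub, sv[idx, , drop = FALSE])
    }
    r <- cor(corrs, rates)
    nullR <- vapply(seq_len(nPerm), function(k)
      cor(corrs[sample.int(nBoot)], rates), numeric(1))
    mu <- mean(nullR); s <- sd(nullR)
    p <- 1 - pnorm((r - mu) / s)
    new("BehaviorLinkResult",
        pairs = data.frame(corr = corrs, suboptRate = rates),
        rEmpirical = r, nullMean = mu, nullSd = s, p = p)
  })
}
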
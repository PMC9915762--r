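## Decoding: value binarization, pseudopopulation construction from
## (possibly non-simultaneous) sessions, and linear decoding with
## cross-condition generalization, with all preprocessing learned on the
## training set only.

#' Binarize continuous values, dropping the middle 30 percentile
#'
#' Inclusive rank percentiles with midpoint ties: p_i = (rank_i - 0.5) / n.
#' Trials below the 35th percentile are "low", above the 65th "high", and
#' the middle 30-percentile band is "excluded".
#'
#' @param values numeric vector with >= 10 distinct values.
#' @param lower,upper percentile cutoffs (0.35 / 0.65 by default).
#' @return factor with levels low / high / excluded.
#' @export
binarizeValue <- function(values, lower = 0.35, upper = 0.65) {
  if (length(unique(values)) < 10)
    stop("need at least 10 distinct values to binarize")
  p <- (rank(values, ties.method = "average") - 0.5) / length(values)
  factor(ifelse(p < lower, "low", ifelse(p > upper, "high", "excluded")),
         levels = c("low", "high", "excluded"))
}

## Per-trial features from three non-overlapping 300-ms bins starting
## 100 ms after the offer onset: trials x (neurons * 3).
.decodeFeatures <- function(neural, onset = 0) {
  f <- lapply(0:2, function(k)
    windowMeans(neural, onset + 100 + c(300 * k, 300 * (k + 1))))
  do.call(cbind, f)
}

#' Build a pseudopopulation dataset for decoding
#'
#' Pools neurons across sessions. Each neuron must have at least
#' `minTrials` trials in each of the four conditions (160 for broad data
#' splits, 80 for narrow splits); failing neurons are excluded and logged.
#' For each condition, `nPseudo` pseudotrials are assembled by seeded
#' sampling without replacement within condition, independently per neuron;
#' the three 300-ms-bin features of one sampled trial stay together, so all
#' bins of a trial land on the same side of any later train/test split.
#'
#' @param sessions list of single-epoch [NeuralSession-class] objects with
#'   `cond` labels.
#' @param minTrials per-condition inclusion threshold (160 broad / 80
#'   narrow).
#' @param nPseudo pseudotrials per condition (defaults to `minTrials`).
#' @param seed integer seed.
#' @param replace sample trials with replacement (FALSE by default).
#' @return list with `X` (pseudotrials x features), `cond` labels,
#'   `neurons` (session, neuron index), `excluded` log.
#' @export
buildPseudopopulation <- function(sessions, minTrials = 160,
                                  nPseudo = minTrials, seed = 1,
                                  replace = FALSE) {
  if (!replace && nPseudo > minTrials)
    stop("without replacement, nPseudo cannot exceed minTrials")
  conds <- condCodes()
  blocks <- list(); neurons <- list(); excluded <- list()
  withSeed(seed, {
    for (s in seq_along(sessions)) {
      ns <- sessions[[s]]
      F <- .decodeFeatures(ns, onset = ns@offerOnsets[1])
      lab <- conditionLabels(ns)$cond
      counts <- table(factor(lab, levels = conds))
      N <- nNeurons(ns)
      if (any(counts < minTrials)) {
        excluded[[length(excluded) + 1]] <- data.frame(
          session = s, neuron = seq_len(N),
          reason = sprintf("condition %s has %d trials (< %d)",
                           names(which.min(counts)), min(counts),
                           minTrials))
        next
      }
      ## per neuron, per condition: sample pseudotrials
      nFeat <- 3L
      out <- matrix(NA_real_, nPseudo * length(conds), N * nFeat)
      for (j in seq_len(N)) {
        colsJ <- j + (0:(nFeat - 1)) * N
        for (ci in seq_along(conds)) {
          idx <- which(lab == conds[ci])
          pick <- sample(idx, nPseudo, replace = replace)
          out[(ci - 1) * nPseudo + seq_len(nPseudo), (j - 1) * nFeat +
                seq_len(nFeat)] <- F[pick, colsJ]
        }
      }
      blocks[[length(blocks) + 1]] <- out
      neurons[[length(neurons) + 1]] <-
        data.frame(session = s, neuron = seq_len(N))
    }
  })
  if (!length(blocks)) stop("no eligible neurons after the trial threshold")
  list(X = do.call(cbind, blocks),
       cond = rep(conds, each = nPseudo),
       neurons = do.call(rbind, neurons),
       excluded = if (length(excluded)) do.call(rbind, excluded)
                  else data.frame())
}

#' Linear decoding with cross-condition generalization
#'
#' Trains a soft-margin linear SVM to discriminate the two `trainPair`
#' conditions (a value contrast in one context) and evaluates (i) standard
#' accuracy on a 10% held-out subset of training-context pseudotrials and
#' (ii) CCGP accuracy on all `testPair` pseudotrials (the same value
#' contrast in the other context). Preprocessing - per-feature z-scoring
#' followed by PCA retaining >= `pcaVar` of the variance - is learned on
#' the training split only and then applied to both evaluation sets.
#'
#' @param pseudo a pseudopopulation from [buildPseudopopulation()], or any
#'   list with `X` and `cond`.
#' @param trainPair,testPair condition code pairs, low-value condition
#'   first (default: train "11" vs "21", test "12" vs "22").
#' @param seed integer seed (holdout split).
#' @param holdout held-out fraction of training trials (0.10).
#' @param pcaVar variance fraction the retained components must reach
#'   (0.99).
#' @param cost SVM soft-margin cost (1).
#' @return list: `standardAccuracy`, `ccgpAccuracy`, `nComponents`,
#'   `varianceRetained`, `nTrain`, `nHeldout`, `nTest`.
#' @export
decodeAndGeneralize <- function(pseudo, trainPair = c("11", "21"),
                                testPair = c("12", "22"), seed = 1,
                                holdout = 0.10, pcaVar = 0.99, cost = 1) {
  X <- pseudo$X; cond <- pseudo$cond
  trIdx <- which(cond %in% trainPair)
  teIdx <- which(cond %in% testPair)
  yAll <- ifelse(cond %in% c(trainPair[2], testPair[2]), "high", "low")
  withSeed(seed, {
    held <- sample(trIdx, max(1, round(holdout * length(trIdx))))
    fit <- setdiff(trIdx, held)
    if (length(unique(yAll[fit])) < 2)
      stop("training set is degenerate: a single class remains")
    ## transforms learned on the fitting split only
    mu <- colMeans(X[fit, , drop = FALSE])
    s <- apply(X[fit, , drop = FALSE], 2, sd)
    s[s == 0] <- 1
    zs <- function(M) sweep(sweep(M, 2, mu), 2, s, "/")
    pc <- prcomp(zs(X[fit, , drop = FALSE]), center = FALSE, scale. = FALSE)
    cumVar <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    k <- which(cumVar >= pcaVar)[1]
    proj <- function(M) zs(M) %*% pc$rotation[, seq_len(k), drop = FALSE]
    yf <- factor(yAll[fit], levels = c("low", "high"))
    svmFit <- e1071::svm(proj(X[fit, , drop = FALSE]), yf,
                         kernel = "linear", cost = cost, scale = FALSE)
    acc <- function(idx) mean(predict(svmFit,
                                      proj(X[idx, , drop = FALSE])) ==
                              yAll[idx])
    list(standardAccuracy = acc(held), ccgpAccuracy = acc(teIdx),
         nComponents = k, varianceRetained = cumVar[k],
         nTrain = length(fit), nHeldout = length(held),
         nTest = length(teIdx))
  })
}

#' Prototype (nearest-centroid) decoder
#'
#' The decoder the analytic theory describes: classifies a point by which
#' training-class centroid it is closer to. Used for direct comparison
#' with the closed-form error rates alongside the max-margin decoder.
#'
#' @param Xtrain training matrix, `ytrain` two-level labels.
#' @param Xtest test matrix.
#' @return predicted labels for `Xtest`.
#' @export
prototypeDecode <- function(Xtrain, ytrain, Xtest) {
  ytrain <- factor(ytrain)
  if (nlevels(ytrain) != 2) stop("prototype decoder needs two classes")
  mu1 <- colMeans(Xtrain[ytrain == levels(ytrain)[1], , drop = FALSE])
  mu2 <- colMeans(Xtrain[ytrain == levels(ytrain)[2], , drop = FALSE])
  w <- mu2 - mu1
  thr <- sum(w * (mu1 + mu2)) / 2
  s <- as.numeric(as.matrix(Xtest) %*% w) - thr
  factor(ifelse(s > 0, levels(ytrain)[2], levels(ytrain)[1]),
         levels = levels(ytrain))
}
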
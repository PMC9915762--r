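## Per-neuron regression: window-averaged z-scored rates, five candidate
## models (noise-only; value + side with linear or B-spline value; the same
## plus side x value interaction), exact leave-one-out predictive densities
## for Bayesian model stacking, WAIC, and a permutation ANOVA of selectivity.

.windowDefs <- function(nOffers) {
  w <- data.frame(window = c("offer1", "delay1"),
                  offer = c(1L, 1L), start = c(0, 450), end = c(400, 850))
  if (nOffers > 1)
    w <- rbind(w, data.frame(window = c("offer2", "delay2"),
                             offer = c(2L, 2L), start = c(0, 450),
                             end = c(400, 850)))
  w
}

#' Window-averaged, z-scored rates for the four analysis windows
#'
#' Averages the 20-ms bins inside each analysis window (offer: 0-400 ms,
#' delay: 450-850 ms after each offer onset), then z-scores per neuron and
#' window. Neurons with fewer than `minTrials` recorded (non-NA) trials are
#' excluded, as are zero-variance neuron-windows; exclusions are logged in
#' the `excluded` slot.
#'
#' The per-window design holds `value` (continuous subjective value when the
#' session's labels carry one, otherwise the binary value level), min-max
#' normalized to \[0, 1\], and `side` effects-coded +1 (left) / -1 (right).
#'
#' @param neural a [NeuralSession-class].
#' @param minTrials neuron inclusion threshold (300 by default).
#' @return a [WindowRates-class].
#' @export
computeWindowRates <- function(neural, minTrials = 300) {
  lab <- conditionLabels(neural)
  nOffers <- length(neural@offerOnsets)
  wdef <- .windowDefs(nOffers)
  nTr <- nTrials(neural)
  N <- nNeurons(neural)
  ## inclusion by trial count (non-NA in the first bin)
  nObs <- colSums(!is.na(matrix(neural@rates[, , 1], nTr, N)))
  keep <- nObs >= minTrials
  excluded <- if (any(!keep))
    data.frame(neuron = which(!keep), window = "all",
               reason = sprintf("only %d trials (< %d)", nObs[!keep],
                                minTrials))
  else data.frame(neuron = integer(), window = character(),
                  reason = character())
  ratesList <- list(); designList <- list()
  for (i in seq_len(nrow(wdef))) {
    onset <- neural@offerOnsets[wdef$offer[i]]
    m <- windowMeans(neural, onset + c(wdef$start[i], wdef$end[i]))
    ## z-score per neuron; flag zero-variance neuron-windows
    s <- apply(m, 2, sd, na.rm = TRUE)
    zv <- which(keep & (!is.finite(s) | s == 0))
    if (length(zv)) {
      excluded <- rbind(excluded,
        data.frame(neuron = zv, window = wdef$window[i],
                   reason = "zero variance"))
      keep[zv] <- FALSE
    }
    ratesList[[wdef$window[i]]] <- m
    k <- wdef$offer[i]
    svCol <- paste0("sv", k)
    if (svCol %in% names(lab)) v <- lab[[svCol]]
    else if (paste0("value", k) %in% names(lab)) v <- lab[[paste0("value", k)]]
    else v <- lab$value
    v <- (v - min(v)) / (max(v) - min(v))
    sCol <- if (paste0("side", k) %in% names(lab)) lab[[paste0("side", k)]]
            else lab$side
    designList[[wdef$window[i]]] <-
      data.frame(value = v, side = ifelse(sCol == 1, 1, -1))
  }
  if (!any(keep)) stop("all neurons excluded")
  for (w in names(ratesList)) {
    m <- ratesList[[w]][, keep, drop = FALSE]
    mu <- colMeans(m, na.rm = TRUE)
    s <- apply(m, 2, sd, na.rm = TRUE)
    ratesList[[w]] <- sweep(sweep(m, 2, mu), 2, s, "/")
  }
  new("WindowRates", rates = ratesList, design = designList,
      windows = wdef, excluded = excluded)
}

.splineBasis <- function(value) {
  kn <- unique(quantile(value, c(0.25, 0.5, 0.75)))
  splines::bs(value, knots = kn, degree = 3,
              Boundary.knots = range(value))
}

.neuronModelIds <- c("noise", "linear-lin", "linear-spline",
                     "interaction-lin", "interaction-spline")

.designMatrices <- function(design) {
  v <- design$value; s <- design$side
  B <- .splineBasis(v)
  colnames(B) <- paste0("spl", seq_len(ncol(B)))
  Bint <- B * s
  colnames(Bint) <- paste0("spl", seq_len(ncol(B)), ":side")
  list(
    "noise" = cbind(`(Intercept)` = rep(1, length(v))),
    "linear-lin" = cbind(`(Intercept)` = 1, value = v, side = s),
    "linear-spline" = cbind(`(Intercept)` = 1, B, side = s),
    "interaction-lin" = cbind(`(Intercept)` = 1, value = v, side = s,
                              `value:side` = v * s),
    "interaction-spline" = cbind(`(Intercept)` = 1, B, side = s, Bint))
}

## Exact leave-one-out log predictive densities for a Gaussian OLS fit with
## shared design X and multi-neuron response Y (case-deletion identities).
.olsLoo <- function(X, Y) {
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1) stop("too few trials for leave-one-out with ", p,
                       " coefficients")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  Q <- qr.Q(qrX)
  h <- rowSums(Q^2)
  B <- qr.coef(qrX, Y)
  E <- Y - X %*% B
  rss <- colSums(E^2)
  s2 <- rss / (n - p)
  ## per-trial deletion: s2_{-i} and predictive variance s2_{-i} / (1 - h_i)
  looRes <- sweep(E, 1, 1 - h, "/")          # e_i / (1 - h_i)
  s2mi <- (matrix(rss, n, ncol(Y), byrow = TRUE) - E * looRes) / (n - p - 1)
  predVar <- sweep(s2mi, 1, 1 - h, "/")
  ## (y_i - yhat_{-i}) = e_i / (1 - h_i) = looRes
  lpd <- -0.5 * log(2 * pi * predVar) - 0.5 * looRes^2 / predVar
  R <- qr.R(qrX)
  XtXinvDiag <- rowSums(backsolve(R, diag(p))^2)
  se <- sqrt(outer(XtXinvDiag, s2))
  dimnames(se) <- dimnames(B)
  list(coef = B, sigma = sqrt(s2), se = se, loo = lpd, hat = h, qr = qrX,
       resid = E)
}

## WAIC from analytic normal-inverse-gamma posterior draws (flat prior).
.olsWaic <- function(X, y, qrX, beta, rss, nDraws = 200) {
  n <- nrow(X); p <- ncol(X)
  R <- qr.R(qrX)
  s2draw <- rss / rchisq(nDraws, df = n - p)
  Z <- matrix(rnorm(p * nDraws), p, nDraws)
  Bdraw <- as.numeric(beta) + backsolve(R, Z) * rep(sqrt(s2draw), each = p)
  Mu <- X %*% Bdraw
  LL <- dnorm(y, Mu, rep(sqrt(s2draw), each = n), log = TRUE)
  lppd <- sum(log(rowMeans(exp(LL - apply(LL, 1, max)))) +
              apply(LL, 1, max))
  pWaic <- sum(apply(LL, 1, var))
  -2 * (lppd - pWaic)
}

#' Fit the five candidate single-neuron models in one window
#'
#' Ordinary least squares (Gaussian likelihood on z-scored rates) for:
#' intercept-only noise; value + side with linear or cubic B-spline value
#' (3 interior knots at value quartiles); and the same plus side x value
#' interaction terms. Exact leave-one-out log predictive densities (from the
#' OLS case-deletion identities) and WAIC are retained per model for
#' [stackModels()].
#'
#' @param wr a [WindowRates-class].
#' @param window which window to fit ("offer1", "delay1", ...).
#' @param nWaicDraws posterior draws for WAIC (0 skips WAIC).
#' @param seed seed for the WAIC posterior draws.
#' @return an object of class `neuronFits`: per-model coefficient matrices
#'   (coefficients x neurons), residual SDs, LOO matrices (trials x
#'   neurons) and WAIC; plus the design used.
#' @export
fitNeuronModels <- function(wr, window = "offer1", nWaicDraws = 200,
                            seed = 1) {
  if (!window %in% names(wr@rates)) stop("unknown window: ", window)
  Y <- wr@rates[[window]]
  design <- wr@design[[window]]
  Xs <- .designMatrices(design)
  fits <- withSeed(seed, lapply(names(Xs), function(mid) {
    X <- Xs[[mid]]
    f <- .olsLoo(X, Y)
    waic <- if (nWaicDraws > 0)
      vapply(seq_len(ncol(Y)), function(j)
        .olsWaic(X, Y[, j], f$qr, f$coef[, j, drop = FALSE],
                 sum(f$resid[, j]^2), nWaicDraws), numeric(1))
    else rep(NA_real_, ncol(Y))
    list(modelId = mid, coef = f$coef, se = f$se, sigma = f$sigma,
         loo = f$loo, waic = waic)
  }))
  names(fits) <- names(Xs)
  structure(list(window = window, design = design, models = fits,
                 nNeurons = ncol(Y), nTrials = nrow(Y)),
            class = "neuronFits")
}

#' @export
print.neuronFits <- function(x, ...) {
  cat("neuronFits:", x$nNeurons, "neurons,", x$nTrials, "trials, window",
      x$window, "\n  models:", paste(names(x$models), collapse = ", "),
      "\n")
  invisible(x)
}

#' Bayesian model stacking weights from leave-one-out densities
#'
#' Finds simplex weights maximizing the leave-one-out log score of the
#' mixture predictive density, sum_i log sum_k w_k p_k(y_i | y_-i), by EM
#' (the objective is concave in w). Weights are invariant to adding a
#' per-trial constant to all models' log densities.
#'
#' @param fits a `neuronFits` object from [fitNeuronModels()].
#' @param neuron neuron index to stack.
#' @param maxIter,tol EM controls.
#' @return list with `weights` (per model), `familyWeights` (noise /
#'   linear / interaction, pooling the spline and linear value variants),
#'   `looScore` of the mixture, and per-model `waic`.
#' @export
stackModels <- function(fits, neuron = 1, maxIter = 5000, tol = 1e-12) {
  lpd <- vapply(fits$models, function(m) m$loo[, neuron],
                numeric(fits$nTrials))
  shift <- apply(lpd, 1, max)
  P <- exp(lpd - shift)               # trials x models, scaled
  K <- ncol(P)
  w <- rep(1 / K, K)
  obj <- -Inf
  for (it in seq_len(maxIter)) {
    mix <- as.vector(P %*% w)
    newObj <- sum(log(mix) + shift)
    R <- sweep(P, 2, w, "*") / mix    # responsibilities
    w <- colMeans(R)
    if (newObj - obj < tol && it > 10) { obj <- newObj; break }
    obj <- newObj
  }
  w <- w / sum(w)
  names(w) <- names(fits$models)
  fam <- c(noise = unname(w["noise"]),
           linear = sum(w[c("linear-lin", "linear-spline")]),
           interaction = sum(w[c("interaction-lin", "interaction-spline")]))
  waic <- vapply(fits$models, function(m) m$waic[neuron], numeric(1))
  list(weights = w, familyWeights = fam, looScore = obj, waic = waic)
}

#' Stack all neurons of a window fit
#'
#' @param fits a `neuronFits` object.
#' @return list with `weights` (neurons x models matrix) and
#'   `familyWeights` (neurons x 3).
#' @export
stackAllNeurons <- function(fits) {
  res <- lapply(seq_len(fits$nNeurons), function(j) stackModels(fits, j))
  list(weights = t(vapply(res, `[[`, numeric(length(fits$models)),
                          "weights")),
       familyWeights = t(vapply(res, `[[`, numeric(3), "familyWeights")))
}

#' Permutation ANOVA of single-neuron selectivity
#'
#' Two-way ANOVA with value discretized into 7 equal-count levels and side
#' as factors, plus their interaction. F statistics (type-II model
#' comparisons) are referenced to a null built by permuting each neuron's
#' rates against the intact label set `nPerm` times;
#' p = (#(F_perm >= F_obs) + 1) / (nPerm + 1).
#'
#' @param ratesMat trials x neurons matrix (z-scored window rates).
#' @param value numeric per-trial value (binned into 7 levels) or a factor.
#' @param side per-trial side (+1/-1 or 1/2).
#' @param nPerm number of permutations (>= 100).
#' @param seed integer seed.
#' @param nLevels number of value bins when `value` is numeric.
#' @return data.frame per neuron: F and p for value, side, interaction.
#' @export
permutationAnova <- function(ratesMat, value, side, nPerm = 1000, seed = 1,
                             nLevels = 7) {
  if (nPerm < 100) stop("nPerm must be >= 100")
  ratesMat <- as.matrix(ratesMat)
  n <- nrow(ratesMat)
  if (!is.factor(value)) {
    br <- quantile(value, probs = seq(0, 1, length.out = nLevels + 1))
    br <- unique(br)
    if (length(br) < nLevels + 1)
      stop("cannot form ", nLevels,
           " non-empty value bins; too few distinct values")
    value <- cut(value, breaks = br, include.lowest = TRUE)
  }
  if (any(table(value) == 0)) stop("a value bin is empty; re-bin the data")
  V <- factor(value); S <- factor(side)
  mm <- function(f) model.matrix(f, data.frame(V = V, S = S))
  Qs <- lapply(list(~1, ~V, ~S, ~V + S, ~V * S),
               function(f) qr.Q(qr(mm(f))))
  names(Qs) <- c("null", "V", "S", "VS", "full")
  dfV <- nlevels(V) - 1; dfS <- nlevels(S) - 1; dfI <- dfV * dfS
  dfRes <- n - nlevels(V) * nlevels(S)
  rssFun <- function(Y) {
    tot <- colSums(Y^2)
    lapply(Qs, function(Q) tot - colSums(crossprod(Q, Y)^2))
  }
  Fstats <- function(rss) {
    ms <- rss$full / dfRes
    list(value = ((rss$S - rss$VS) / dfV) / ms,
         side = ((rss$V - rss$VS) / dfS) / ms,
         interaction = ((rss$VS - rss$full) / dfI) / ms)
  }
  Fobs <- Fstats(rssFun(ratesMat))
  withSeed(seed, {
    counts <- matrix(0, ncol(ratesMat), 3,
                     dimnames = list(NULL, c("value", "side",
                                             "interaction")))
    for (j in seq_len(ncol(ratesMat))) {
      Yp <- matrix(ratesMat[, j][vapply(seq_len(nPerm),
                                        function(k) sample.int(n),
                                        integer(n))], n, nPerm)
      Fp <- Fstats(rssFun(Yp))
      counts[j, ] <- c(sum(Fp$value >= Fobs$value[j]),
                       sum(Fp$side >= Fobs$side[j]),
                       sum(Fp$interaction >= Fobs$interaction[j]))
    }
    data.frame(neuron = seq_len(ncol(ratesMat)),
               Fvalue = Fobs$value, Fside = Fobs$side,
               Finteraction = Fobs$interaction,
               pValue = (counts[, 1] + 1) / (nPerm + 1),
               pSide = (counts[, 2] + 1) / (nPerm + 1),
               pInteraction = (counts[, 3] + 1) / (nPerm + 1))
  })
}
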
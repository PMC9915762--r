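## Subjective-value choice models: a 4-model space crossing objective vs
## power-law utility with objective vs Prelec-warped probability, combined
## with a softmax over the relative subjective value.

.svModelIds <- c("obj-obj", "obj-prelec", "pow-obj", "pow-prelec")

#' Subjective-value model parameters
#'
#' Parameters of the softmax choice model SV = w(p) * u(s):
#' u(s) = s^alpha (power utility; alpha = 1 is objective stakes) and
#' w(p) = exp(-beta * (-log p)^gamma) (two-parameter Prelec weighting;
#' gamma = beta = 1 is objective probability). `modelId` records which
#' parameters are free; the others are fixed at identity.
#'
#' @param alpha utility exponent (> 0).
#' @param gamma Prelec curvature (> 0).
#' @param beta Prelec elevation (> 0).
#' @param tau softmax temperature (> 0).
#' @param modelId one of "obj-obj", "obj-prelec", "pow-obj", "pow-prelec"
#'   (stakes treatment first, probability treatment second).
#' @return a parameter list.
#' @export
svParams <- function(alpha = 1, gamma = 1, beta = 1, tau = 0.05,
                     modelId = "pow-prelec") {
  if (any(c(alpha, gamma, beta, tau) <= 0))
    stop("all subjective-value parameters must be > 0")
  modelId <- match.arg(modelId, .svModelIds)
  if (!startsWith(modelId, "pow")) alpha <- 1
  if (!endsWith(modelId, "prelec")) { gamma <- 1; beta <- 1 }
  list(alpha = alpha, gamma = gamma, beta = beta, tau = tau,
       modelId = modelId)
}

#' Subjective value of an offer
#'
#' SV = w(p) * u(s) with u and w set by `params$modelId`. The Prelec
#' weight is continued to w(0) = 0 by its limit; SV is monotone increasing
#' in both probability and stakes.
#'
#' @param prob offer probability in \[0, 1\] (vectorized).
#' @param stakes offer stakes in mL (vectorized).
#' @param params an [svParams()] list.
#' @return numeric vector of subjective values.
#' @examples
#' subjectiveValue(0.5, 0.240, svParams(modelId = "obj-obj"))  # 0.120
#' @export
subjectiveValue <- function(prob, stakes, params) {
  if (any(prob < 0 | prob > 1)) stop("probabilities must lie in [0, 1]")
  u <- if (startsWith(params$modelId, "pow")) stakes^params$alpha else stakes
  if (endsWith(params$modelId, "prelec")) {
    w <- ifelse(prob <= 0, 0,
                exp(-params$beta * (-log(pmin(prob, 1)))^params$gamma))
  } else w <- prob
  w * u
}

#' Filter inattentive and safe-offer trials
#'
#' Removes trials with duration > 7 s (inattentive) and trials containing a
#' safe offer; removal counts are stored in `attr(, "removed")`.
#'
#' @param session a [BehavioralSession-class].
#' @return the filtered session; errors if nothing survives.
#' @export
filterTrials <- function(session) {
  tr <- trials(session)
  if (is.null(tr$duration)) stop("trial durations are required")
  slow <- tr$duration > 7
  safe <- tr$kind1 == "safe" | tr$kind2 == "safe"
  keep <- !slow & !safe
  if (!any(keep))
    stop("no trials survive filtering (", sum(slow), " slow, ",
         sum(safe), " safe-offer trials removed)")
  out <- session
  out@trials <- tr[keep, , drop = FALSE]
  attr(out@trials, "removed") <- c(slow = sum(slow), safe = sum(safe),
                                   either = sum(!keep))
  out
}

## Negative penalized log-likelihood in log-parameter space. `free` names
## the free parameters; a weak Gaussian ridge on the log scale regularizes
## the multimodal softmax likelihood.
.negPenLL <- function(logTheta, free, tr, priorSd = 2) {
  th <- svParams(tau = 1)  # placeholder, overwritten below
  th$modelId <- attr(free, "modelId")
  th$alpha <- th$gamma <- th$beta <- 1
  th$tau <- 1
  th[free] <- as.list(exp(logTheta))
  sv1 <- subjectiveValue(tr$prob1, tr$stakes1, th)
  sv2 <- subjectiveValue(tr$prob2, tr$stakes2, th)
  z <- (sv1 - sv2) / th$tau
  ll <- sum(ifelse(tr$choice == 1L, plogis(z, log.p = TRUE),
                   plogis(-z, log.p = TRUE)))
  -ll + 0.5 * sum((logTheta / priorSd)^2)
}

.freeParams <- function(modelId) {
  free <- switch(modelId,
    "obj-obj" = "tau",
    "pow-obj" = c("alpha", "tau"),
    "obj-prelec" = c("gamma", "beta", "tau"),
    "pow-prelec" = c("alpha", "gamma", "beta", "tau"))
  attr(free, "modelId") <- modelId
  free
}

#' Fit the 4-model subjective-value space to a session's choices
#'
#' Each candidate model is fitted by penalized maximum likelihood (weak
#' Gaussian ridge on log-parameters) from `nStarts` seeded starting points;
#' models are compared by a Laplace approximation to the log evidence
#' (penalized log-likelihood at the optimum plus 0.5 k log(2 pi) minus half
#' the log-determinant of the negative Hessian). A model whose Hessian is
#' not positive definite is flagged non-identifiable and cannot win the
#' comparison.
#'
#' @param session a filtered [BehavioralSession-class] with choices.
#' @param nStarts random restarts per model.
#' @param seed integer seed for the restarts.
#' @param tauLower lower bound for tau (log-scale bound; deterministic
#'   choosers drive the fitted tau to this bound).
#' @return a [BehaviorFitResult-class].
#' @export
fitChoiceModel <- function(session, nStarts = 10, seed = 1,
                           tauLower = 1e-4) {
  tr <- trials(session)
  if (length(unique(tr$choice[!is.na(tr$choice)])) < 2)
    stop("need both choice outcomes present to fit a choice model")
  tr <- tr[!is.na(tr$choice), , drop = FALSE]
  fits <- withSeed(seed, lapply(.svModelIds, function(mid) {
    free <- .freeParams(mid)
    k <- length(free)
    lower <- rep(log(1e-3), k); upper <- rep(log(1e3), k)
    lower[free == "tau"] <- log(tauLower)
    best <- NULL
    for (s in seq_len(nStarts)) {
      start <- rnorm(k, 0, 0.5)
      start[free == "tau"] <- rnorm(1, log(0.05), 1)
      opt <- try(nlminb(start, .negPenLL, free = free, tr = tr,
                        lower = lower, upper = upper), silent = TRUE)
      if (inherits(opt, "try-error")) next
      if (is.null(best) || opt$objective < best$objective) best <- opt
    }
    if (is.null(best)) stop("all starts failed for model ", mid)
    H <- optimHess(best$par, .negPenLL, free = free, tr = tr)
    eh <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    identifiable <- all(eh > 1e-8)
    logEv <- if (identifiable)
      -best$objective + 0.5 * k * log(2 * pi) - 0.5 * sum(log(eh))
    else -Inf
    params <- svParams(modelId = mid, tau = 1)
    params[free] <- as.list(exp(best$par))
    vc <- if (identifiable) solve(H) else matrix(NA_real_, k, k)
    dimnames(vc) <- list(free, free)
    list(modelId = mid, params = params, logPar = setNames(best$par, free),
         vcovLog = vc, logEvidence = logEv, negPenLL = best$objective,
         identifiable = identifiable)
  }))
  names(fits) <- .svModelIds
  ev <- vapply(fits, function(f) f$logEvidence, numeric(1))
  if (all(!is.finite(ev)))
    stop("no candidate model was identifiable on these data")
  selected <- names(which.max(ev))
  par <- fits[[selected]]$params
  sv <- cbind(subjectiveValue(tr$prob1, tr$stakes1, par),
              subjectiveValue(tr$prob2, tr$stakes2, par))
  predicted <- ifelse(sv[, 1] >= sv[, 2], 1L, 2L)
  accuracy <- mean(predicted == tr$choice)
  new("BehaviorFitResult", models = fits, selected = selected, sv = sv,
      accuracy = accuracy)
}

#' Suboptimal-choice rate
#'
#' Fraction of trials on which the chosen offer had the lower subjective
#' value. Ties (|SV1 - SV2| < 1e-9) are excluded; an error is raised if all
#' trials are ties.
#'
#' @param session a [BehavioralSession-class] with choices.
#' @param sv n x 2 matrix of per-trial subjective values.
#' @return fraction in \[0, 1\].
#' @export
suboptimalChoiceRate <- function(session, sv) {
  tr <- trials(session)
  if (nrow(sv) != nrow(tr)) stop("sv must have one row per trial")
  d <- sv[, 1] - sv[, 2]
  use <- abs(d) >= 1e-9 & !is.na(tr$choice)
  if (!any(use)) stop("suboptimal-choice rate undefined: all trials tied")
  chosenLower <- ifelse(tr$choice[use] == 1L, d[use] < 0, d[use] > 0)
  mean(chosenLower)
}
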
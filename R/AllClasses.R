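#' @import methods
#' @importFrom stats cor dnorm median model.matrix optim optimHess nlminb
#'   plogis pnorm prcomp predict qnorm quantile rchisq rlnorm rnorm runif
#'   sd setNames var
#' @importFrom utils head tail read.csv write.csv
#' @importFrom Rcpp evalCpp
#' @useDynLib subspaceBind, .registration = TRUE
NULL

## Central S4 containers. Conventions follow Bioconductor practice:
## validity methods on the classes, accessors instead of @, show() methods.

#' BehavioralSession: a table of risky-choice trials
#'
#' One row per trial of the two-offer gambling task. Each trial carries two
#' offers (probability, stakes, kind, side), presentation order, the choice
#' (if made), reward, trial duration and event times in ms.
#'
#' @slot trials data.frame with one row per trial (see [generateTaskSession()]
#'   for the column dictionary).
#' @slot subjectId character scalar.
#' @slot seed integer seed the session was generated from (NA if external).
#' @export
setClass("BehavioralSession",
  representation(trials = "data.frame", subjectId = "character",
                 seed = "integer"),
  prototype(trials = data.frame(), subjectId = "synthetic",
            seed = NA_integer_))

.validBehavioralSession <- function(object) {
  tr <- object@trials
  msgs <- character()
  if (nrow(tr) > 0) {
    need <- c("prob1", "prob2", "stakes1", "stakes2", "side1", "side2",
              "tOffer1", "tOffer2", "duration")
    miss <- setdiff(need, names(tr))
    if (length(miss))
      msgs <- c(msgs, paste("missing trial columns:",
                            paste(miss, collapse = ", ")))
    if (!length(miss)) {
      if (any(tr$prob1 < 0 | tr$prob1 > 1 | tr$prob2 < 0 | tr$prob2 > 1))
        msgs <- c(msgs, "offer probabilities must lie in [0, 1]")
      if (any(tr$side1 == tr$side2))
        msgs <- c(msgs, "the two offers must be on opposite sides")
      if (any(tr$tOffer2 - tr$tOffer1 != 1000))
        msgs <- c(msgs, "stimulus onset asynchrony must be 1000 ms")
    }
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("BehavioralSession", .validBehavioralSession)

#' PopulationCodeSpec: generative linear-nonlinear population code
#'
#' Describes the code r(x) = L x_z + M f_N(x) + eps for K = 2 binary task
#' features (value level and side/context). The two columns of L have lengths
#' dLV and dLA; the four columns of M are mutually orthogonal, orthogonal to
#' L, and each has length m = dN / sqrt(2), so that the nonlinear component
#' of the distance between any two conditions is dN.
#'
#' @slot nNeurons integer, population size N (>= 6 so L and M fit).
#' @slot dLV,dLA,dN nonnegative distances in z-scored rate units.
#' @slot sigma nonnegative noise SD (per neuron, at the analysis-window scale).
#' @slot L numeric N x 2 matrix.
#' @slot M numeric N x 4 matrix; columns indexed by condition
#'   c("11", "21", "12", "22") (value level, then context level).
#' @export
setClass("PopulationCodeSpec",
  representation(nNeurons = "integer", dLV = "numeric", dLA = "numeric",
                 dN = "numeric", sigma = "numeric", L = "matrix",
                 M = "matrix"))

.validPopulationCodeSpec <- function(object) {
  msgs <- character()
  N <- object@nNeurons
  if (N < 6)
    msgs <- c(msgs, "need at least 6 neurons to hold 6 orthogonal columns")
  if (any(c(object@dLV, object@dLA, object@dN, object@sigma) < 0))
    msgs <- c(msgs, "distances and sigma must be nonnegative")
  B <- cbind(object@L, object@M)
  if (nrow(B) != N) msgs <- c(msgs, "L and M must have nNeurons rows")
  if (!length(msgs)) {
    cn <- sqrt(colSums(B^2))
    G <- crossprod(B)
    off <- abs(G[upper.tri(G)])
    lim <- 1e-8 * outer(cn, cn)[upper.tri(G)] + 1e-12
    if (any(off > lim))
      msgs <- c(msgs, "columns of [L M] must be mutually orthogonal")
    if (abs(cn[1] - object@dLV) > 1e-8 * max(1, object@dLV))
      msgs <- c(msgs, "|L1| must equal dLV")
    if (abs(cn[2] - object@dLA) > 1e-8 * max(1, object@dLA))
      msgs <- c(msgs, "|L2| must equal dLA")
    m <- object@dN / sqrt(2)
    if (any(abs(cn[3:6] - m) > 1e-8 * max(1, m)))
      msgs <- c(msgs, "all columns of M must have length dN/sqrt(2)")
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("PopulationCodeSpec", .validPopulationCodeSpec)

#' NeuralSession: binned firing-rate tensor with condition labels
#'
#' @slot rates numeric array trials x neurons x bins (z-scored rate units;
#'   NA marks trials a neuron was not recorded on).
#' @slot binWidth bin width in ms (20 by default).
#' @slot binStarts numeric vector of bin start times in ms, relative to the
#'   alignment event.
#' @slot offerOnsets numeric vector of offer-onset times in ms on the bin
#'   time axis (one entry per offer epoch contained in the tensor).
#' @slot labels data.frame with one row per trial; for single-epoch sessions
#'   columns `value` (1 = low, 2 = high), `side` (1 = left, 2 = right) and
#'   `cond` (e.g. "21"); two-epoch sessions use value1/side1/value2/side2.
#' @slot alignment character, the event the time axis is locked to.
#' @slot seed integer generator seed (NA if external data).
#' @export
setClass("NeuralSession",
  representation(rates = "array", binWidth = "numeric",
                 binStarts = "numeric", offerOnsets = "numeric",
                 labels = "data.frame", alignment = "character",
                 seed = "integer"))

.validNeuralSession <- function(object) {
  msgs <- character()
  d <- dim(object@rates)
  if (length(d) != 3)
    msgs <- c(msgs, "rates must be a trials x neurons x bins array")
  else {
    if (length(object@binStarts) != d[3])
      msgs <- c(msgs, "binStarts must have one entry per bin")
    if (nrow(object@labels) != d[1])
      msgs <- c(msgs, "labels must have one row per trial")
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("NeuralSession", .validNeuralSession)

#' WindowRates: window-averaged, z-scored rates and their designs
#'
#' @slot rates named list of trials x neurons matrices, one per analysis
#'   window (offer1, delay1, and, when present, offer2, delay2).
#' @slot design named list of data.frames (one per window) with per-trial
#'   `value` (min-max normalized to \[0, 1\]) and `side` (effects coded -1/+1).
#' @slot windows data.frame describing each window (start, end, offer index).
#' @slot excluded data.frame log of excluded neurons (index, window, reason).
#' @export
setClass("WindowRates",
  representation(rates = "list", design = "list", windows = "data.frame",
                 excluded = "data.frame"))

#' GeometryEstimate: recovered linear-nonlinear geometry
#'
#' @slot dLV,dLA,dN nonnegative recovered distances.
#' @slot sigma noise SD along the value decoder axis.
#' @slot epsilon standard-error distance of the condition centroids.
#' @slot rho implied subspace correlation dLV^2 / (dLV^2 + dN^2).
#' @slot residual root reconstruction error of the distance-matrix fit.
#' @slot details list (distance matrix, fold scheme, multi-start spread).
#' @export
setClass("GeometryEstimate",
  representation(dLV = "numeric", dLA = "numeric", dN = "numeric",
                 sigma = "numeric", epsilon = "numeric", rho = "numeric",
                 residual = "numeric", details = "list"),
  prototype(sigma = NA_real_, epsilon = NA_real_, residual = NA_real_,
            details = list()))

setValidity("GeometryEstimate", function(object) {
  msgs <- character()
  if (any(c(object@dLV, object@dLA, object@dN) < 0))
    msgs <- c(msgs, "distances must be nonnegative")
  if (!is.na(object@rho) && (object@rho < -1e-9 || object@rho > 1 + 1e-9))
    msgs <- c(msgs, "rho must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' ErrorRatePrediction: closed-form and Monte-Carlo error rates
#'
#' @slot bindingError closed-form misbinding probability.
#' @slot ccgpError closed-form cross-condition generalization error.
#' @slot bindingMC,bindingMCSE Monte-Carlo oracle rate and its SE (NA if not
#'   computed).
#' @slot ccgpMC,ccgpMCSE Monte-Carlo/prototype-decoder oracle rate and SE.
#' @export
setClass("ErrorRatePrediction",
  representation(bindingError = "numeric", ccgpError = "numeric",
                 bindingMC = "numeric", bindingMCSE = "numeric",
                 ccgpMC = "numeric", ccgpMCSE = "numeric"),
  prototype(bindingError = NA_real_, ccgpError = NA_real_,
            bindingMC = NA_real_, bindingMCSE = NA_real_,
            ccgpMC = NA_real_, ccgpMCSE = NA_real_))

setValidity("ErrorRatePrediction", function(object) {
  v <- c(object@bindingError, object@ccgpError, object@bindingMC,
         object@ccgpMC)
  v <- v[!is.na(v)]
  if (any(v < -1e-12 | v > 1 + 1e-12)) "error rates must lie in [0, 1]"
  else TRUE
})

#' SubspaceCorrelationResult: observed vs noise-ceiling correlations
#'
#' @slot observed bootstrap left-vs-right subspace correlations.
#' @slot ceiling noise-ceiling correlations (same-side across bootstrap
#'   halves).
#' @slot p bootstrap-test p value (small p: observed below ceiling, i.e.
#'   separable subspaces).
#' @export
setClass("SubspaceCorrelationResult",
  representation(observed = "numeric", ceiling = "numeric", p = "numeric"))

setValidity("SubspaceCorrelationResult", function(object) {
  msgs <- character()
  if (length(object@observed) != length(object@ceiling))
    msgs <- c(msgs, "observed and ceiling must have equal length")
  if (any(abs(c(object@observed, object@ceiling)) > 1 + 1e-9))
    msgs <- c(msgs, "correlations must lie in [-1, 1]")
  if (length(msgs)) msgs else TRUE
})

#' BehaviorFitResult: fitted subjective-value choice models
#'
#' @slot models named list, one entry per candidate model: fitted parameters,
#'   Laplace log-evidence, covariance of log-parameters, convergence flag.
#' @slot selected model id with the highest log evidence.
#' @slot sv n x 2 matrix of per-trial subjective values under the selected
#'   model.
#' @slot accuracy fraction of choices predicted by the selected model.
#' @export
setClass("BehaviorFitResult",
  representation(models = "list", selected = "character", sv = "matrix",
                 accuracy = "numeric"))

setValidity("BehaviorFitResult", function(object) {
  msgs <- character()
  if (length(object@accuracy) && !is.na(object@accuracy) &&
      (object@accuracy < 0 || object@accuracy > 1))
    msgs <- c(msgs, "accuracy must lie in [0, 1]")
  if (length(object@sv) && any(!is.finite(object@sv)))
    msgs <- c(msgs, "subjective values must be finite")
  if (length(msgs)) msgs else TRUE
})

#' BehaviorLinkResult: subspace correlation vs suboptimal choice
#'
#' @slot pairs data.frame of per-bootstrap (corr, suboptRate) pairs.
#' @slot rEmpirical correlation across bootstraps.
#' @slot nullMean,nullSd moments of the permutation null of correlations.
#' @slot p 1 - pnorm((rEmpirical - nullMean) / nullSd).
#' @export
setClass("BehaviorLinkResult",
  representation(pairs = "data.frame", rEmpirical = "numeric",
                 nullMean = "numeric", nullSd = "numeric", p = "numeric"))

setValidity("BehaviorLinkResult", function(object) {
  if (length(object@p) && (object@p < 0 || object@p > 1))
    "p must lie in [0, 1]" else TRUE
})
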
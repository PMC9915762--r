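#' Accessors for the core classes
#'
#' `trials()` returns the trial table of a [BehavioralSession-class],
#' `nTrials()` its number of trials; `rates()` returns the firing-rate
#' tensor of a [NeuralSession-class], `conditionLabels()` its per-trial
#' label table and `nNeurons()` the population size of a session or code
#' spec; `distances()` extracts the recovered (dLV, dLA, dN) from a
#' [GeometryEstimate-class].
#'
#' @param object a package object.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases trials nTrials rates conditionLabels nNeurons distances
NULL

#' @rdname accessors
#' @export
setGeneric("trials", function(object) standardGeneric("trials"))
#' @rdname accessors
#' @export
setMethod("trials", "BehavioralSession", function(object) object@trials)

#' @rdname accessors
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))
#' @rdname accessors
#' @export
setMethod("nTrials", "BehavioralSession",
          function(object) nrow(object@trials))
#' @rdname accessors
#' @export
setMethod("nTrials", "NeuralSession", function(object) dim(object@rates)[1])

#' @rdname accessors
#' @export
setGeneric("rates", function(object) standardGeneric("rates"))
#' @rdname accessors
#' @export
setMethod("rates", "NeuralSession", function(object) object@rates)

#' @rdname accessors
#' @export
setGeneric("conditionLabels",
           function(object) standardGeneric("conditionLabels"))
#' @rdname accessors
#' @export
setMethod("conditionLabels", "NeuralSession", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("nNeurons", function(object) standardGeneric("nNeurons"))
#' @rdname accessors
#' @export
setMethod("nNeurons", "NeuralSession", function(object) dim(object@rates)[2])
#' @rdname accessors
#' @export
setMethod("nNeurons", "PopulationCodeSpec", function(object) object@nNeurons)

#' @rdname accessors
#' @export
setGeneric("distances", function(object) standardGeneric("distances"))
#' @rdname accessors
#' @export
setMethod("distances", "GeometryEstimate", function(object)
  c(dLV = object@dLV, dLA = object@dLA, dN = object@dN))

setMethod("show", "BehavioralSession", function(object) {
  tr <- object@trials
  cat("BehavioralSession for subject", object@subjectId, "\n")
  cat(" ", nrow(tr), "trials")
  if (nrow(tr) && "kind1" %in% names(tr)) {
    safe <- mean(tr$kind1 == "safe" | tr$kind2 == "safe")
    cat(sprintf(" (%.1f%% with a safe offer)", 100 * safe))
  }
  cat("\n")
  if (nrow(tr) && "choice" %in% names(tr) && any(!is.na(tr$choice)))
    cat(sprintf("  choices present on %d trials\n", sum(!is.na(tr$choice))))
  invisible(NULL)
})

setMethod("show", "PopulationCodeSpec", function(object) {
  cat("PopulationCodeSpec:", object@nNeurons, "neurons\n")
  cat(sprintf("  dLV = %.3g, dLA = %.3g, dN = %.3g, sigma = %.3g\n",
              object@dLV, object@dLA, object@dN, object@sigma))
  cat(sprintf("  implied subspace correlation rho = %.3f\n",
              impliedSubspaceCorrelation(object@dLV, object@dN)))
  invisible(NULL)
})

setMethod("show", "NeuralSession", function(object) {
  d <- dim(object@rates)
  cat("NeuralSession:", d[1], "trials x", d[2], "neurons x", d[3],
      "bins of", object@binWidth, "ms\n")
  cat("  aligned to:", object@alignment, "| offer onsets at",
      paste(object@offerOnsets, collapse = ", "), "ms\n")
  invisible(NULL)
})

setMethod("show", "GeometryEstimate", function(object) {
  cat("GeometryEstimate\n")
  cat(sprintf("  dLV = %.4g, dLA = %.4g, dN = %.4g\n",
              object@dLV, object@dLA, object@dN))
  cat(sprintf("  sigma = %.4g, epsilon = %.4g, rho = %.4g\n",
              object@sigma, object@epsilon, object@rho))
  if (!is.na(object@residual))
    cat(sprintf("  distance-matrix fit residual = %.3g\n", object@residual))
  invisible(NULL)
})

setMethod("show", "ErrorRatePrediction", function(object) {
  cat("ErrorRatePrediction\n")
  cat(sprintf("  binding error: predicted %.4g", object@bindingError))
  if (!is.na(object@bindingMC))
    cat(sprintf(", Monte-Carlo %.4g (SE %.2g)", object@bindingMC,
                object@bindingMCSE))
  cat("\n")
  cat(sprintf("  CCGP error:    predicted %.4g", object@ccgpError))
  if (!is.na(object@ccgpMC))
    cat(sprintf(", Monte-Carlo %.4g (SE %.2g)", object@ccgpMC,
                object@ccgpMCSE))
  cat("\n")
  invisible(NULL)
})

setMethod("show", "SubspaceCorrelationResult", function(object) {
  cat("SubspaceCorrelationResult\n")
  cat(sprintf("  observed: mean %.3f [%.3f, %.3f] over %d bootstraps\n",
              mean(object@observed), quantile(object@observed, 0.025),
              quantile(object@observed, 0.975), length(object@observed)))
  cat(sprintf("  ceiling:  mean %.3f | bootstrap p = %.4g\n",
              mean(object@ceiling), object@p))
  invisible(NULL)
})

setMethod("show", "BehaviorFitResult", function(object) {
  cat("BehaviorFitResult: selected model", object@selected, "\n")
  ev <- vapply(object@models, function(m) m$logEvidence, numeric(1))
  for (id in names(object@models))
    cat(sprintf("  %-11s logEvidence = %.2f\n", id, ev[[id]]))
  cat(sprintf("  choice-prediction accuracy = %.3f\n", object@accuracy))
  invisible(NULL)
})

setMethod("show", "BehaviorLinkResult", function(object) {
  cat("BehaviorLinkResult\n")
  cat(sprintf("  r = %.3f (null %.3f +/- %.3f), p = %.4g over %d bootstraps\n",
              object@rEmpirical, object@nullMean, object@nullSd, object@p,
              nrow(object@pairs)))
  invisible(NULL)
})
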
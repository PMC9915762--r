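## Orchestration: a validated configuration, stage toggles, and an
## end-to-end synthetic run with a reproducibility manifest.

#' Pipeline configuration
#'
#' Defaults mirror the analysis constants used throughout the package:
#' 20-ms bins, 400-ms analysis windows at 0-400 and 450-850 ms, 1000/500
#' bootstrap counts, 7 value levels, the middle-30-percentile binarization
#' band, 99% PCA variance, 10% decoding holdout, and trial/neuron minima
#' of 300 (regression), 160/80 (decoding splits) and 30 (simultaneous
#' sessions). Every stochastic stage takes its own seed derived from
#' `seed`.
#'
#' @param seed master integer seed.
#' @param nTrials behavioral trials to simulate.
#' @param nNeurons population size.
#' @param dLV,dLA,dN,sigma generative code geometry.
#' @param stages named logical toggles (syndata is always run when inputs
#'   are absent).
#' @param outDir output directory.
#' @param minTrialsRegression,minTrialsBroad,minTrialsNarrow,minNeurons
#'   inclusion thresholds.
#' @param nBootCeiling,nBootLink bootstrap counts.
#' @return validated config list.
#' @export
pipelineConfig <- function(seed, nTrials = 1000, nNeurons = 40, dLV = 1,
                           dLA = 1.5, dN = 1, sigma = 0.6,
                           stages = c(behavior = TRUE, neuronfit = TRUE,
                                      subspace = TRUE, geometry = TRUE,
                                      decode = TRUE, popstruct = TRUE),
                           outDir = tempfile("run"),
                           minTrialsRegression = 300, minTrialsBroad = 160,
                           minTrialsNarrow = 80, minNeurons = 30,
                           nBootCeiling = 1000, nBootLink = 500) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("config validation: a master seed is required")
  thr <- c(minTrialsRegression, minTrialsBroad, minTrialsNarrow,
           minNeurons, nBootCeiling, nBootLink)
  if (any(thr <= 0)) stop("config validation: thresholds must be positive")
  cfg <- list(seed = as.integer(seed), nTrials = nTrials,
              nNeurons = nNeurons, dLV = dLV, dLA = dLA, dN = dN,
              sigma = sigma, stages = stages, outDir = outDir,
              minTrialsRegression = minTrialsRegression,
              minTrialsBroad = minTrialsBroad,
              minTrialsNarrow = minTrialsNarrow, minNeurons = minNeurons,
              nBootCeiling = nBootCeiling, nBootLink = nBootLink)
  cfg$stageSeeds <- vapply(c("task", "choice", "code", "neural",
                             "neuronfit", "subspace", "geometry", "decode",
                             "popstruct"),
                           function(s) childSeed(seed, s), integer(1))
  cfg
}

#' Run the full synthetic pipeline
#'
#' Executes the stages in dependency order (simulate -> behavior ->
#' neuronfit -> subspace / geometry / decode / popstruct), writes each
#' stage's outputs under `config$outDir` and returns a manifest with MD5
#' hashes of every output file. Re-running with an identical config
#' reproduces identical hashes.
#'
#' @param config a [pipelineConfig()] list.
#' @return the manifest (list), invisibly writes
#'   `manifest.json` in the run directory.
#' @export
runPipeline <- function(config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  ss <- config$stageSeeds
  outputs <- character()
  emit <- function(name, obj) {
    p <- file.path(config$outDir, name)
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    outputs <<- c(outputs, p)
    p
  }
  ## stage: syndata + behavior simulation
  beh <- generateTaskSession(config$nTrials, seed = ss[["task"]])
  beh <- simulateChoices(beh, svParams(alpha = 0.8, gamma = 0.7,
                                       tau = 0.02),
                         seed = ss[["choice"]])
  p <- file.path(config$outDir, "behavioral_session.csv")
  writeBehavioralSession(beh, p); outputs <- c(outputs, p)
  spec <- makeCodeSpec(config$nNeurons, config$dLV, config$dLA, config$dN,
                       config$sigma, seed = ss[["code"]])
  filt <- filterTrials(beh)
  results <- list(removedTrials = as.list(attr(trials(filt), "removed")))
  ## stage: behavior model fit
  if (isTRUE(config$stages[["behavior"]])) {
    bf <- fitChoiceModel(filt, nStarts = 4, seed = ss[["choice"]])
    results$behavior <- list(
      selected = bf@selected, accuracy = bf@accuracy,
      logEvidence = lapply(bf@models, function(m) m$logEvidence),
      suboptimalRate = suboptimalChoiceRate(filt, bf@sv))
    emit("behavior.json", results$behavior)
    sv <- bf@sv
  } else {
    tr <- trials(filt)
    sv <- cbind(tr$prob1 * tr$stakes1, tr$prob2 * tr$stakes2)
  }
  neural <- simulateNeuralSession(filt, spec, seed = ss[["neural"]],
                                  sv = sv)
  ## stage: neuronfit
  if (isTRUE(config$stages[["neuronfit"]])) {
    wr <- computeWindowRates(neural,
                             minTrials = min(config$minTrialsRegression,
                                             nTrials(neural)))
    fits <- fitNeuronModels(wr, "offer1", nWaicDraws = 0,
                            seed = ss[["neuronfit"]])
    stacks <- stackAllNeurons(fits)
    results$neuronfit <- list(
      nNeurons = fits$nNeurons,
      meanFamilyWeights = as.list(colMeans(stacks$familyWeights)),
      fracInteractionBest = mean(apply(stacks$familyWeights, 1,
                                       which.max) == 3))
    emit("neuronfit.json", results$neuronfit)
    ## stage: subspace
    if (isTRUE(config$stages[["subspace"]])) {
      vl <- valueSubspaceVector(fits, "left")
      vr <- valueSubspaceVector(fits, "right")
      nc <- noiseCeilingTest(Y = wr@rates[["offer1"]],
                             design = wr@design[["offer1"]],
                             nBoot = config$nBootCeiling,
                             seed = ss[["subspace"]])
      results$subspace <- list(
        correlationLeftRight = as.numeric(subspaceCorrelation(vl, vr)),
        observedMean = mean(nc@observed), ceilingMean = mean(nc@ceiling),
        p = nc@p)
      emit("subspace.json", results$subspace)
    }
  }
  ## stage: geometry (on a balanced single-epoch population)
  if (isTRUE(config$stages[["geometry"]])) {
    pop <- simulatePopulation(spec, nRepeats = 200,
                              seed = ss[["geometry"]])
    g <- estimateGeometry(pop, seed = ss[["geometry"]])
    er <- predictErrorRates(spec, epsilon = g@epsilon)
    results$geometry <- list(
      dLV = g@dLV, dLA = g@dLA, dN = g@dN, sigma = g@sigma,
      epsilon = g@epsilon, rho = g@rho,
      predictedBindingError = er@bindingError,
      predictedCcgpError = er@ccgpError)
    emit("geometry.json", results$geometry)
  }
  ## stage: decode
  if (isTRUE(config$stages[["decode"]])) {
    pop <- simulatePopulation(spec, nRepeats = config$minTrialsBroad,
                              seed = ss[["decode"]], nBins = 50)
    pseudo <- buildPseudopopulation(list(pop),
                                    minTrials = config$minTrialsBroad,
                                    seed = ss[["decode"]])
    dec <- decodeAndGeneralize(pseudo, seed = ss[["decode"]])
    results$decode <- dec
    emit("decode.json", results$decode)
  }
  ## stage: popstruct
  if (isTRUE(config$stages[["popstruct"]]) &&
      isTRUE(config$stages[["neuronfit"]])) {
    idx <- sensitivityIndex(vl, vr)
    dt <- dipTest(idx[!is.na(idx)], nBoot = 500,
                  seed = ss[["popstruct"]])
    results$popstruct <- list(dip = dt$statistic, dipP = dt$p)
    emit("popstruct.json", results$popstruct)
  }
  emit("results.json", results)
  manifest <- list(
    config = config[setdiff(names(config), "stages")],
    stages = as.list(config$stages),
    outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                               basename(outputs))),
    versions = list(R = as.character(getRversion()),
                    package = as.character(utils::packageVersion(
                      "subspaceBind"))))
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
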
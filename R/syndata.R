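## Synthetic-data generators: the risky-choice task, softmax choices under a
## subjective-value model, and neural populations following the
## linear-nonlinear code r(x) = L x_z + M f_N(x) + eps.

#' Task configuration for the synthetic risky-choice session
#'
#' Defaults reproduce the study conditions of the task: offer kinds drawn
#' with probabilities (medium 43.75%, large 43.75%, safe 12.5%); stakes of
#' 0.125 / 0.165 / 0.240 mL for safe / medium / large offers; gamble
#' probabilities i.i.d. uniform on a 1% grid; a 1000-ms stimulus onset
#' asynchrony; and lognormal trial durations calibrated so that a small
#' configurable fraction (1% by default) exceeds the 7-s inattention cutoff.
#'
#' @param kindProbs named probabilities for offer kinds; must sum to 1.
#' @param stakes named reward volumes (mL) per kind.
#' @param probResolution grid resolution for gamble probabilities.
#' @param slowFrac target fraction of trials longer than 7 s.
#' @param durationSdLog lognormal sdlog of trial durations.
#' @return a list of task parameters.
#' @export
taskConfig <- function(kindProbs = c(medium = 0.4375, large = 0.4375,
                                     safe = 0.125),
                       stakes = c(safe = 0.125, medium = 0.165,
                                  large = 0.240),
                       probResolution = 0.01,
                       slowFrac = 0.01,
                       durationSdLog = 0.4) {
  if (abs(sum(kindProbs) - 1) > 1e-9 || any(kindProbs < 0))
    stop("offer-kind probabilities must be nonnegative and sum to 1")
  if (!all(names(kindProbs) %in% names(stakes)))
    stop("every offer kind needs a stakes entry")
  meanlog <- log(7) - qnorm(1 - slowFrac) * durationSdLog
  list(kindProbs = kindProbs, stakes = stakes,
       probResolution = probResolution, slowFrac = slowFrac,
       durationMeanLog = meanlog, durationSdLog = durationSdLog)
}

#' Generate a synthetic behavioral session
#'
#' Samples `nTrials` trials of the two-offer task. Offer kinds are drawn
#' independently per offer from `params$kindProbs`; gamble probabilities are
#' uniform on the 1% grid (safe offers have probability 1); sides and
#' presentation order are randomized per trial; offer 2 onset is exactly
#' 1000 ms after offer 1 onset. Choices are left NA (see
#' [simulateChoices()]).
#'
#' Trial table columns: `trial`; per offer `prob*`, `stakes*`, `kind*`,
#' `side*` ("L"/"R", offer 1 is the first-presented offer); `order`
#' ("left_first"/"right_first"); `choice` (1/2 or NA); `rewardDelivered`
#' (mL); `duration` (s); event times `tOffer1`, `tOffer2`, `tChoice` (ms).
#'
#' @param nTrials number of trials (>= 1).
#' @param params a [taskConfig()] list.
#' @param seed integer seed; sessions are bit-reproducible given
#'   (nTrials, params, seed).
#' @param subjectId subject label.
#' @return a [BehavioralSession-class].
#' @examples
#' s <- generateTaskSession(200, seed = 1)
#' mean(trials(s)$kind1 == "safe")
#' @export
generateTaskSession <- function(nTrials, params = taskConfig(), seed,
                                subjectId = "synthetic") {
  if (nTrials < 1) stop("nTrials must be >= 1")
  if (abs(sum(params$kindProbs) - 1) > 1e-9)
    stop("offer-kind probabilities must sum to 1")
  withSeed(seed, {
    kinds <- names(params$kindProbs)
    grid <- seq(0, 1, by = params$probResolution)
    drawOffer <- function(n) {
      kind <- sample(kinds, n, replace = TRUE, prob = params$kindProbs)
      prob <- sample(grid, n, replace = TRUE)
      prob[kind == "safe"] <- 1
      data.frame(prob = prob, stakes = unname(params$stakes[kind]),
                 kind = kind)
    }
    o1 <- drawOffer(nTrials)
    o2 <- drawOffer(nTrials)
    side1 <- sample(c("L", "R"), nTrials, replace = TRUE)
    side2 <- ifelse(side1 == "L", "R", "L")
    duration <- rlnorm(nTrials, params$durationMeanLog, params$durationSdLog)
    tr <- data.frame(
      trial = seq_len(nTrials),
      prob1 = o1$prob, stakes1 = o1$stakes, kind1 = o1$kind, side1 = side1,
      prob2 = o2$prob, stakes2 = o2$stakes, kind2 = o2$kind, side2 = side2,
      order = ifelse(side1 == "L", "left_first", "right_first"),
      choice = NA_integer_, rewardDelivered = NA_real_,
      duration = duration,
      tOffer1 = 0, tOffer2 = 1000,
      tChoice = NA_real_)
    ## choice event follows the second delay; tie it to trial duration
    tr$tChoice <- pmax(2100, round(tr$duration * 1000))
    new("BehavioralSession", trials = tr, subjectId = subjectId,
        seed = as.integer(seed))
  })
}

#' Simulate softmax choices for a behavioral session
#'
#' Fills the `choice` column: P(choose offer 1) =
#' logistic((SV1 - SV2) / tau) with subjective values from
#' [subjectiveValue()] under `svParams`. Reward delivery is resolved from
#' the chosen offer's probability and stakes.
#'
#' @param session a [BehavioralSession-class].
#' @param svParams a [svParams()] list (must include `tau` > 0).
#' @param seed integer seed.
#' @return the session with `choice` and `rewardDelivered` filled.
#' @export
simulateChoices <- function(session, svParams, seed) {
  if (svParams$tau <= 0) stop("softmax temperature tau must be > 0")
  tr <- trials(session)
  sv1 <- subjectiveValue(tr$prob1, tr$stakes1, svParams)
  sv2 <- subjectiveValue(tr$prob2, tr$stakes2, svParams)
  withSeed(seed, {
    p1 <- plogis((sv1 - sv2) / svParams$tau)
    choice <- ifelse(runif(nrow(tr)) < p1, 1L, 2L)
    win <- runif(nrow(tr)) <
      ifelse(choice == 1L, tr$prob1, tr$prob2)
    tr$choice <- choice
    tr$rewardDelivered <- ifelse(win,
      ifelse(choice == 1L, tr$stakes1, tr$stakes2), 0)
    session@trials <- tr
    validObject(session)
    session
  })
}

#' Construct a linear-nonlinear population code specification
#'
#' Builds L (N x 2) and M (N x 4) with exactly orthogonal columns by QR
#' orthonormalization of seeded Gaussian vectors, then scales the columns of
#' L to lengths dLV and dLA and the columns of M to a common length
#' m = dN / sqrt(2). With the z-scored stimulus coding used by
#' [simulatePopulation()], condition centroids then satisfy: value-only
#' pairs at distance sqrt(dLV^2 + dN^2), context-only pairs at
#' sqrt(dLA^2 + dN^2), and diagonal pairs at sqrt(dLV^2 + dLA^2 + dN^2).
#'
#' @param nNeurons population size N >= 6.
#' @param dLV,dLA,dN nonnegative linear and nonlinear distances.
#' @param sigma nonnegative noise SD at the 400-ms analysis-window scale.
#' @param seed integer seed for the random basis.
#' @return a [PopulationCodeSpec-class].
#' @export
makeCodeSpec <- function(nNeurons, dLV, dLA, dN, sigma, seed) {
  if (nNeurons < 6)
    stop("cannot hold 6 orthogonal columns with fewer than 6 neurons")
  withSeed(seed, {
    B <- qr.Q(qr(matrix(rnorm(nNeurons * 6), nNeurons, 6)))
    L <- B[, 1:2] %*% diag(c(dLV, dLA))
    m <- dN / sqrt(2)
    M <- B[, 3:6] * m
    colnames(M) <- condCodes()
    new("PopulationCodeSpec", nNeurons = as.integer(nNeurons),
        dLV = dLV, dLA = dLA, dN = dN, sigma = sigma, L = L, M = M)
  })
}

#' Condition centroids of a population code
#'
#' Returns the 4 x N matrix of noiseless condition responses. The stimulus
#' vector is z-scored over its two balanced levels and scaled so the linear
#' component of the value-pair (context-pair) distance equals dLV (dLA);
#' the nonlinear component adds the condition's column of M.
#'
#' @param spec a [PopulationCodeSpec-class].
#' @return matrix with rows named "11", "21", "12", "22".
#' @export
conditionCentroids <- function(spec) {
  conds <- condCodes()
  zv <- ifelse(condToValue(conds) == 2, 0.5, -0.5)
  za <- ifelse(condToContext(conds) == 2, 0.5, -0.5)
  C <- cbind(zv, za) %*% t(spec@L) + t(spec@M[, conds])
  rownames(C) <- conds
  C
}

#' Simulate a neural population under the linear-nonlinear code
#'
#' Each trial's analysis-window response is the condition centroid plus
#' isotropic Gaussian noise of SD `sigma` per neuron. The returned tensor
#' has `nBins` 20-ms bins whose mean over the full window reproduces that
#' response exactly: per-bin noise has SD sigma * sqrt(nBins), so the noise
#' SD is defined at the window scale (see the methods vignette).
#'
#' @param spec a [PopulationCodeSpec-class].
#' @param labels character vector of per-trial condition codes from
#'   `c("11", "21", "12", "22")` (value level then context level), or NULL
#'   to generate `nRepeats` balanced repeats of each condition.
#' @param nRepeats trials per condition when `labels` is NULL.
#' @param seed integer seed.
#' @param nBins number of 20-ms bins in the epoch.
#' @param windowBins number of bins whose average carries noise SD exactly
#'   `sigma` (defaults to `nBins`, i.e. sigma lives at the full-epoch
#'   scale; pass 20 to put it at the 400-ms analysis-window scale when
#'   generating longer epochs).
#' @return a single-epoch [NeuralSession-class].
#' @examples
#' spec <- makeCodeSpec(20, dLV = 1, dLA = 2, dN = 0.5, sigma = 0, seed = 1)
#' ns <- simulatePopulation(spec, nRepeats = 2, seed = 2)
#' @export
simulatePopulation <- function(spec, labels = NULL, nRepeats = 100, seed,
                               nBins = 20, windowBins = nBins) {
  if (is.null(labels))
    labels <- rep(condCodes(), each = nRepeats)
  labels <- as.character(labels)
  if (!all(labels %in% condCodes()))
    stop("labels must come from the 2 x 2 grid: ",
         paste(condCodes(), collapse = ", "))
  nTr <- length(labels)
  N <- nNeurons(spec)
  C <- conditionCentroids(spec)
  withSeed(seed, {
    resp <- C[labels, , drop = FALSE]  # nTr x N window response means
    arr <- array(NA_real_, c(nTr, N, nBins))
    sdBin <- spec@sigma * sqrt(windowBins)
    ## iid per-bin noise of SD sigma*sqrt(windowBins): the mean over any
    ## windowBins-bin window then has SD exactly sigma
    for (b in seq_len(nBins))
      arr[, , b] <- resp + if (sdBin > 0)
        matrix(rnorm(nTr * N, sd = sdBin), nTr, N) else 0
    ## with sigma = 0 all repeats of a condition are identical
    lab <- data.frame(value = condToValue(labels),
                      side = condToContext(labels),
                      cond = labels, stringsAsFactors = FALSE)
    new("NeuralSession", rates = arr, binWidth = 20,
        binStarts = seq(0, by = 20, length.out = nBins),
        offerOnsets = 0, labels = lab, alignment = "offer1",
        seed = as.integer(seed))
  })
}

#' Window-mean population responses of a single-epoch session
#'
#' Mean rate across the given bin range, per trial and neuron.
#'
#' @param neural a [NeuralSession-class].
#' @param window numeric c(start, end) in ms on the session's time axis
#'   (end exclusive); defaults to the full epoch.
#' @return trials x neurons matrix.
#' @export
windowMeans <- function(neural, window = NULL) {
  bs <- neural@binStarts
  if (is.null(window)) window <- c(min(bs), max(bs) + neural@binWidth)
  sel <- bs >= window[1] & bs < window[2]
  if (!any(sel)) stop("no bins fall inside the requested window")
  apply(neural@rates[, , sel, drop = FALSE], c(1, 2), mean)
}

#' Simulate a two-epoch neural session paired with behavior
#'
#' Generates a firing-rate tensor spanning both offer presentations (bins
#' 0-2000 ms, offer onsets at 0 and 1000 ms). Each offer's epoch follows the
#' linear-nonlinear code for the condition (binary value level x side) of
#' that offer. Value levels are a median split of offer expected value
#' unless subjective values are supplied.
#'
#' @param behavioral a [BehavioralSession-class] with choices present.
#' @param spec a [PopulationCodeSpec-class].
#' @param seed integer seed.
#' @param sv optional n x 2 matrix of subjective values used for the value
#'   split (defaults to probability x stakes).
#' @return a [NeuralSession-class] with labels value1/side1/value2/side2.
#' @export
simulateNeuralSession <- function(behavioral, spec, seed, sv = NULL) {
  tr <- trials(behavioral)
  if (is.null(sv))
    sv <- cbind(tr$prob1 * tr$stakes1, tr$prob2 * tr$stakes2)
  med <- median(c(sv))
  lvl <- function(v) ifelse(v > med, 2L, 1L)
  sideNum <- function(s) ifelse(s == "L", 1L, 2L)
  cond1 <- paste0(lvl(sv[, 1]), sideNum(tr$side1))
  cond2 <- paste0(lvl(sv[, 2]), sideNum(tr$side2))
  N <- nNeurons(spec)
  nTr <- nrow(tr)
  C <- conditionCentroids(spec)
  nBinsEpoch <- 50  # 1000 ms per epoch at 20 ms
  withSeed(seed, {
    arr <- array(NA_real_, c(nTr, N, 2 * nBinsEpoch))
    sdBin <- spec@sigma * sqrt(20)  # sigma defined at the 20-bin window scale
    for (b in seq_len(nBinsEpoch)) {
      arr[, , b] <- C[cond1, ] + if (sdBin > 0)
        matrix(rnorm(nTr * N, sd = sdBin), nTr, N) else 0
      arr[, , nBinsEpoch + b] <- C[cond2, ] + if (sdBin > 0)
        matrix(rnorm(nTr * N, sd = sdBin), nTr, N) else 0
    }
    lab <- data.frame(value1 = lvl(sv[, 1]), side1 = sideNum(tr$side1),
                      value2 = lvl(sv[, 2]), side2 = sideNum(tr$side2),
                      cond1 = cond1, cond2 = cond2,
                      sv1 = sv[, 1], sv2 = sv[, 2],
                      stringsAsFactors = FALSE)
    new("NeuralSession", rates = arr, binWidth = 20,
        binStarts = seq(0, by = 20, length.out = 2 * nBinsEpoch),
        offerOnsets = c(0, 1000), labels = lab, alignment = "offer1",
        seed = as.integer(seed))
  })
}

#' Simulate a session with a planted subspace-behavior link
#'
#' Builds a paired behavioral + neural session in which a latent per-trial
#' attentional state drives both quantities: on "lapse" trials the
#' conjunctive (nonlinear) part of the neural code is scaled down by
#' `lapseGain` (raising the measured subspace correlation toward its
#' ceiling) and the choice is made with a misbinding probability
#' `lapseMisbind` (raising the suboptimal-choice rate). Bootstrap resamples
#' that happen to contain more lapse trials therefore show both a higher
#' subspace correlation and more suboptimal choices, planting a positive
#' correlation for [behaviorLink()] to detect.
#'
#' @param nTrials trials in the session.
#' @param spec a [PopulationCodeSpec-class] (its dN applies to attentive
#'   trials).
#' @param choiceParams choice model parameters for attentive trials.
#' @param lapseProb probability a trial is a lapse trial.
#' @param lapseGain multiplier (< 1) on the nonlinear code during lapses.
#' @param lapseMisbind probability of swapping the two offers' values in
#'   the decision on lapse trials.
#' @param seed integer seed.
#' @return list(behavioral, neural, lapse = logical per trial).
#' @export
simulateLinkedSession <- function(nTrials, spec, choiceParams = svParams(),
                                  lapseProb = 0.3, lapseGain = 0.2,
                                  lapseMisbind = 0.5, seed) {
  beh <- generateTaskSession(nTrials, seed = childSeed(seed, "task"))
  tr <- trials(beh)
  sv1 <- subjectiveValue(tr$prob1, tr$stakes1, choiceParams)
  sv2 <- subjectiveValue(tr$prob2, tr$stakes2, choiceParams)
  withSeed(childSeed(seed, "lapse"), {
    lapse <- runif(nTrials) < lapseProb
    ## choices: softmax on (possibly misbound) values
    s1 <- sv1; s2 <- sv2
    swap <- lapse & runif(nTrials) < lapseMisbind
    s1[swap] <- sv2[swap]; s2[swap] <- sv1[swap]
    p1 <- plogis((s1 - s2) / choiceParams$tau)
    tr$choice <- ifelse(runif(nTrials) < p1, 1L, 2L)
    tr$rewardDelivered <- 0
    beh@trials <- tr
  })
  ## neural: offer-1 epoch code, nonlinear part attenuated on lapse trials
  med <- median(c(sv1, sv2))
  cond1 <- paste0(ifelse(sv1 > med, 2L, 1L),
                  ifelse(tr$side1 == "L", 1L, 2L))
  N <- nNeurons(spec)
  C <- conditionCentroids(spec)
  Mpart <- t(spec@M[, cond1])          # nTrials x N conjunctive component
  Lin <- C[cond1, ] - Mpart            # linear scaffold component
  gain <- ifelse(lapse, lapseGain, 1)
  resp <- Lin + Mpart * gain
  nBins <- 20
  neural <- withSeed(childSeed(seed, "neural"), {
    arr <- array(NA_real_, c(nTrials, N, nBins))
    sdBin <- spec@sigma * sqrt(nBins)
    for (b in seq_len(nBins))
      arr[, , b] <- resp + matrix(rnorm(nTrials * N, sd = sdBin),
                                  nTrials, N)
    lab <- data.frame(value = condToValue(cond1),
                      side = condToContext(cond1), cond = cond1,
                      sv1 = sv1, sv2 = sv2, stringsAsFactors = FALSE)
    new("NeuralSession", rates = arr, binWidth = 20,
        binStarts = seq(0, by = 20, length.out = nBins),
        offerOnsets = 0, labels = lab, alignment = "offer1",
        seed = as.integer(seed))
  })
  list(behavioral = beh, neural = neural, lapse = lapse)
}
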
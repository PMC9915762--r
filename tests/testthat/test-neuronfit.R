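test_that("window rates average the stated windows and z-score cleanly", {
  ## hand-built two-epoch session: rates encode the bin index so window
  ## means are known exactly
  nTr <- 320; N <- 3; nBins <- 100
  arr <- array(rep(seq_len(nBins), each = nTr * N), c(nTr, N, nBins))
  arr <- arr + array(rep(seq_len(nTr), N * nBins), c(nTr, N, nBins)) / 1000
  lab <- data.frame(value1 = rep(1:2, nTr / 2), side1 = rep(1:2, each = nTr / 2),
                    value2 = rep(2:1, nTr / 2), side2 = rep(2:1, each = nTr / 2))
  ns <- new("NeuralSession", rates = arr, binWidth = 20,
            binStarts = seq(0, by = 20, length.out = nBins),
            offerOnsets = c(0, 1000), labels = lab, alignment = "offer1",
            seed = 1L)
  wr <- computeWindowRates(ns, minTrials = 300)
  expect_setequal(names(wr@rates),
                  c("offer1", "delay1", "offer2", "delay2"))
  ## offer1 window = bins 1..20 (0-400 ms); raw mean known, z-scored
  raw <- mean(1:20) + seq_len(nTr) / 1000
  expect_equal(unname(wr@rates$offer1[, 1]),
               unname((raw - mean(raw)) / sd(raw)), tolerance = 1e-10)
  ## delay windows cover 450-850 ms: bins 24..43 (starts 460..840)...
  ## verified via the mean of the selected bin values
  rawD <- mean(24:43) + seq_len(nTr) / 1000
  expect_equal(unname(wr@rates$delay1[, 1]),
               unname((rawD - mean(rawD)) / sd(rawD)), tolerance = 1e-10)
  ## per-neuron per-window z-scoring
  for (w in names(wr@rates)) {
    expect_lt(max(abs(colMeans(wr@rates[[w]]))), 1e-10)
    expect_lt(max(abs(apply(wr@rates[[w]], 2, sd) - 1)), 1e-10)
  }
})

test_that("neurons failing the 300-trial rule or with no variance drop out", {
  nTr <- 320; N <- 3; nBins <- 100
  arr <- array(rnorm(nTr * N * nBins), c(nTr, N, nBins))
  arr[1:70, 2, ] <- NA           # neuron 2: only 250 recorded trials
  arr[, 3, ] <- 5                # neuron 3: constant rate
  lab <- data.frame(value1 = rep(1:2, nTr / 2), side1 = rep(1:2, each = nTr / 2),
                    value2 = rep(2:1, nTr / 2), side2 = rep(2:1, each = nTr / 2))
  ns <- new("NeuralSession", rates = arr, binWidth = 20,
            binStarts = seq(0, by = 20, length.out = nBins),
            offerOnsets = c(0, 1000), labels = lab, alignment = "offer1",
            seed = 1L)
  wr <- computeWindowRates(ns, minTrials = 300)
  expect_equal(ncol(wr@rates$offer1), 1L)
  ex <- wr@excluded
  expect_true(any(ex$neuron == 2 & grepl("250 trials", ex$reason)))
  expect_true(any(ex$neuron == 3 & grepl("zero variance", ex$reason)))
})

test_that("noiseless data are recovered exactly and bad designs refused", {
  n <- 200
  design <- makeDesign(n, seed = 61)
  y <- 1 + 2 * design$value - 0.5 * design$side
  fits <- fitNeuronModels(makeWindowRates(y, design), nWaicDraws = 0)
  cf <- fits$models[["interaction-lin"]]$coef
  expect_lt(abs(cf["(Intercept)", 1] - 1), 1e-10)
  expect_lt(abs(cf["value", 1] - 2), 1e-10)
  expect_lt(abs(cf["side", 1] + 0.5), 1e-10)
  expect_lt(abs(cf["value:side", 1]), 1e-10)
  ## rank-deficient design names the collinear column
  bad <- design; bad$side <- 1
  expect_error(fitNeuronModels(makeWindowRates(y, bad), nWaicDraws = 0),
               "side")
})

test_that("exact leave-one-out matches brute-force case deletion", {
  n <- 40
  design <- makeDesign(n, seed = 62)
  y <- withr::with_seed(63, 0.5 * design$value + rnorm(n))
  fits <- fitNeuronModels(makeWindowRates(y, design), nWaicDraws = 0)
  X <- cbind(1, design$value, design$side, design$value * design$side)
  p <- ncol(X)
  ref <- vapply(seq_len(n), function(i) {
    f <- lm.fit(X[-i, , drop = FALSE], y[-i])
    s2 <- sum(f$residuals^2) / (n - 1 - p)
    xi <- X[i, ]
    predVar <- s2 * (1 + drop(t(xi) %*% solve(crossprod(X[-i, ])) %*% xi))
    dnorm(y[i], drop(xi %*% f$coefficients), sqrt(predVar), log = TRUE)
  }, numeric(1))
  expect_equal(unname(fits$models[["interaction-lin"]]$loo[, 1]), ref,
               tolerance = 1e-10)
})

test_that("interaction coefficient intervals are calibrated and powerful", {
  n <- 400
  cover0 <- 0L; exclude0 <- 0L
  for (r in 1:50) {
    design <- makeDesign(n, seed = 700 + r)
    ## null: no interaction
    y0 <- withr::with_seed(800 + r,
                           0.6 * design$value + 0.2 * design$side + rnorm(n))
    f0 <- fitNeuronModels(makeWindowRates(y0, design),
                          nWaicDraws = 0)$models[["interaction-lin"]]
    ci0 <- f0$coef["value:side", 1] +
      c(-1, 1) * qnorm(0.975) * f0$se["value:side", 1]
    cover0 <- cover0 + (ci0[1] <= 0 && 0 <= ci0[2])
    ## alternative: unit interaction, sigma = 1
    y1 <- withr::with_seed(900 + r,
                           0.6 * design$value + design$value * design$side +
                             rnorm(n))
    f1 <- fitNeuronModels(makeWindowRates(y1, design),
                          nWaicDraws = 0)$models[["interaction-lin"]]
    ci1 <- f1$coef["value:side", 1] +
      c(-1, 1) * qnorm(0.975) * f1$se["value:side", 1]
    exclude0 <- exclude0 + (ci1[1] > 0 || ci1[2] < 0)
  }
  expect_gte(cover0 / 50, 0.9)
  expect_gte(exclude0 / 50, 0.9)
})

test_that("stacking weights form a simplex and respect model structure", {
  n <- 500
  design <- makeDesign(n, seed = 71)
  y <- withr::with_seed(72, 0.4 * design$value + 0.8 * design$value *
                          design$side + rnorm(n))
  fits <- fitNeuronModels(makeWindowRates(y, design), nWaicDraws = 100,
                          seed = 73)
  st <- stackModels(fits, 1)
  expect_equal(sum(st$weights), 1, tolerance = 1e-9)
  expect_true(all(st$weights >= -1e-12))
  expect_equal(unname(st$familyWeights["noise"] +
                        st$familyWeights["linear"] +
                        st$familyWeights["interaction"]), 1,
               tolerance = 1e-9)
  ## invariance to a per-trial constant added to every model's density
  shifted <- fits
  shift <- withr::with_seed(74, rnorm(n))
  for (m in names(shifted$models))
    shifted$models[[m]]$loo <- shifted$models[[m]]$loo + shift
  st2 <- stackModels(shifted, 1)
  expect_equal(st$weights, st2$weights, tolerance = 1e-6)
  ## degenerate candidates: mixture score equals the single-model score
  dup <- fits
  for (m in names(dup$models))
    dup$models[[m]]$loo <- fits$models[["linear-lin"]]$loo
  stDup <- stackModels(dup, 1)
  expect_equal(stDup$looScore, sum(fits$models[["linear-lin"]]$loo[, 1]),
               tolerance = 1e-8)
  ## WAIC is finite and ranks the generating family well
  expect_true(all(is.finite(st$waic)))
  expect_lt(st$waic[["interaction-lin"]], st$waic[["noise"]])
})

test_that("nested in-sample likelihoods dominate but stacking stays modest", {
  n <- 400
  design <- makeDesign(n, seed = 75)
  y <- withr::with_seed(76, 0.7 * design$value - 0.3 * design$side +
                          rnorm(n))
  fits <- fitNeuronModels(makeWindowRates(y, design), nWaicDraws = 0)
  ## in-sample residual sum of squares of the nesting model is no larger
  rssInt <- fits$models[["interaction-lin"]]$sigma[1]^2 * (400 - 4)
  rssLin <- fits$models[["linear-lin"]]$sigma[1]^2 * (400 - 3)
  expect_lte(rssInt, rssLin + 1e-12)
  ## but stacking does not systematically prefer the larger model
  st <- stackModels(fits, 1)
  expect_gte(unname(st$familyWeights["linear"]), 0.2)
})

test_that("stacking identifies noise and interaction regimes", {
  noiseWin <- 0L
  for (r in 1:30) {
    design <- makeDesign(1000, seed = 1000 + r)
    y <- withr::with_seed(1100 + r, rnorm(1000))
    st <- stackModels(fitNeuronModels(makeWindowRates(y, design),
                                      nWaicDraws = 0), 1)
    noiseWin <- noiseWin + (which.max(st$familyWeights) == 1L)
  }
  expect_gte(noiseWin / 30, 0.8)
  intWin <- 0L
  for (r in 1:20) {
    design <- makeDesign(500, seed = 2000 + r)
    y <- withr::with_seed(2100 + r,
                          0.5 * design$value + 0.3 * design$side +
                            design$value * design$side + rnorm(500))
    st <- stackModels(fitNeuronModels(makeWindowRates(y, design),
                                      nWaicDraws = 0), 1)
    intWin <- intWin + (st$familyWeights["interaction"] > 0.5)
  }
  expect_gte(intWin / 20, 0.9)
})

test_that("permutation ANOVA p values hit the formula floor and calibrate", {
  n <- 280
  v <- factor(rep(1:7, each = 40))
  s <- rep(c(-1, 1), 140)
  ## enormous value effect: p at the floor 1/(nPerm + 1)
  y <- as.numeric(v) * 10 + withr::with_seed(81, rnorm(n, sd = 0.01))
  pa <- permutationAnova(matrix(y), v, s, nPerm = 100, seed = 82)
  expect_equal(pa$pValue, 1 / 101)
  ## empty value bin is an error
  expect_error(permutationAnova(matrix(y), rep(0.5, n), s, nPerm = 100),
               "bins")
  ## null calibration: p approximately uniform over 200 neurons
  Y <- withr::with_seed(83, matrix(rnorm(n * 200), n, 200))
  pa0 <- permutationAnova(Y, v, s, nPerm = 199, seed = 84)
  for (p in list(pa0$pValue, pa0$pSide, pa0$pInteraction)) {
    expect_lt(mean(p < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
    expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
  }
})
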
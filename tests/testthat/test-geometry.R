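test_that("crossnobis estimates are unbiased and beat the naive distance", {
  withr::with_seed(111, {
    ## identical distributions: mean estimate ~ 0
    est <- vapply(1:500, function(r) {
      d <- list(a = matrix(rnorm(40 * 10), 40), b = matrix(rnorm(40 * 10), 40))
      crossnobisMatrix(d, nFolds = 4, seed = r)$D2["a", "b"]
    }, numeric(1))
    expect_lt(abs(mean(est)), 3 * sd(est) / sqrt(500))
    ## known separation delta = 2 along one axis: squared distance 4
    est2 <- vapply(1:60, function(r) {
      d <- list(a = matrix(rnorm(200 * 10), 200),
                b = cbind(matrix(rnorm(200 * 9), 200), rnorm(200) + 2))
      crossnobisMatrix(d, nFolds = 5, seed = r)$D2["a", "b"]
    }, numeric(1))
    expect_lt(abs(mean(est2) - 4), 3 * sd(est2) / sqrt(60))
    ## the naive squared distance is positively biased on pure noise
    naive <- vapply(1:200, function(r) {
      a <- matrix(rnorm(40 * 10), 40); b <- matrix(rnorm(40 * 10), 40)
      sum((colMeans(a) - colMeans(b))^2)
    }, numeric(1))
    expect_gt(mean(naive), mean(est) + 3 * sd(naive) / sqrt(200))
    ## condition smaller than the fold count is named
    expect_error(crossnobisMatrix(list(a = matrix(rnorm(30), 3),
                                       b = matrix(rnorm(100), 10)),
                                  nFolds = 5), "a")
  })
})

test_that("distance decomposition inverts the model exactly and stably", {
  ## exact forward model for (dLV, dLA, dN) = (1, 2, 0.5)
  D2 <- subspaceBind:::.modelD2(1, 4, 0.25)
  g <- decomposeDistances(D2, seed = 112)
  expect_lt(max(abs(distances(g) - c(1, 2, 0.5))), 1e-6)
  expect_equal(g@rho, 1 / 1.25, tolerance = 1e-6)
  ## rectangle (factorized code): dN recovered as 0
  gR <- decomposeDistances(subspaceBind:::.modelD2(1, 4, 0), seed = 113)
  expect_lt(distances(gR)["dN"], 1e-6)
  ## stability across initializations on a noisy matrix
  Dn <- D2 + withr::with_seed(114, {
    E <- matrix(rnorm(16, sd = 0.05), 4); E <- E + t(E); diag(E) <- 0; E
  })
  gN <- decomposeDistances(Dn, nStarts = 10, seed = 115)
  expect_lt(gN@details$multistartSpread, 1e-4)
  expect_error(decomposeDistances(matrix(NA_real_, 4, 4)), "non-finite")
})

test_that("noise sigma is measured along the decoder axis only", {
  spec <- makeCodeSpec(40, 3, 1, 0.8, 0, seed = 121)
  C <- conditionCentroids(spec)
  mk <- function(noiseFun) {
    lapply(setNames(rownames(C), rownames(C)), function(cc)
      t(C[cc, ] + t(noiseFun(1000))))
  }
  ## zero noise
  d0 <- mk(function(n) matrix(0, n, 40))
  expect_equal(estimateNoiseSigma(d0), 0)
  ## isotropic sigma = 0.5 within 5% at n ~ 1000
  withr::with_seed(122, {
    d1 <- mk(function(n) matrix(rnorm(n * 40, sd = 0.5), n, 40))
    expect_lt(abs(estimateNoiseSigma(d1) / 0.5 - 1), 0.05)
    ## noise confined orthogonally to the axis leaves sigma ~ 0
    v <- C["21", ] - C["11", ]; u <- v / sqrt(sum(v^2))
    P <- diag(40) - u %*% t(u)
    d2 <- mk(function(n) matrix(rnorm(n * 40, sd = 0.5), n, 40) %*% P)
    expect_lt(estimateNoiseSigma(d2), 0.05)
  })
})

test_that("the standard-error distance follows SEM scaling", {
  spec <- makeCodeSpec(50, 1, 1, 0.5, 0, seed = 123)
  C <- conditionCentroids(spec)
  mk <- function(n, sigma, seed) withr::with_seed(seed,
    lapply(setNames(rownames(C), rownames(C)), function(cc)
      t(C[cc, ] + t(matrix(rnorm(n * 50, sd = sigma), n, 50)))))
  e200 <- estimateSemDistance(mk(200, 0.5, 124))
  e800 <- estimateSemDistance(mk(800, 0.5, 125))
  ## eps ~ sigma * sqrt(2 N / n)
  expect_lt(abs(e200 / (0.5 * sqrt(2 * 50 / 200)) - 1), 0.1)
  ## quadrupling trials halves eps
  expect_lt(abs(e200 / e800 - 2), 0.25)
})

test_that("binding error rate: closed form, enumeration and edge cases", {
  expect_equal(confusableSets(2, 2)$NS, 0.25)
  expect_equal(predictedBindingError(1, 0), 0)       # infinite SNR
  expect_equal(predictedBindingError(0, 0), 0.125)   # chance among sets
  expect_equal(predictedBindingError(0, 1), 0.125)   # N_S / 2
  ## decreasing in dN / sigma
  grid <- vapply(seq(0, 3, 0.5), predictedBindingError, numeric(1),
                 sigma = 1)
  expect_true(all(diff(grid) < 0))
})

test_that("binding oracle matches the union-bound prediction", {
  ## dN = 0: decoder indifferent between chimeric sets; tie-broken rate
  spec0 <- makeCodeSpec(20, 8, 8, 0, 1, seed = 131)
  b0 <- bindingErrorOracle(spec0, nMC = 40000, seed = 132)
  expect_lt(abs(as.numeric(b0) - 0.125), 3 * attr(b0, "se"))
  ## dN / sigma = 10: essentially no misbinding
  spec10 <- makeCodeSpec(20, 8, 8, 10, 1, seed = 133)
  expect_lt(as.numeric(bindingErrorOracle(spec10, nMC = 20000,
                                          seed = 134)), 1e-4)
  ## grid agreement (2 Monte-Carlo SEs)
  for (dN in c(0.5, 1, 2)) {
    spec <- makeCodeSpec(20, 8, 8, dN, 1, seed = 135)
    b <- bindingErrorOracle(spec, nMC = 40000, seed = 136 + dN)
    ## three grid cells share the block, so give each 3 Monte-Carlo SEs
    expect_lt(abs(as.numeric(b) - predictedBindingError(dN, 1)),
              3 * attr(b, "se") + 1e-4)
  }
})

test_that("CCGP error rate: closed form and prototype oracle agree", {
  expect_equal(predictedCcgpError(0, 1, 1), 0.5)
  expect_equal(predictedCcgpError(2, 0, 1), pnorm(-1))
  expect_equal(predictedCcgpError(1, 1, 0), 0)
  ## decreasing in dLV, increasing in dN
  expect_true(all(diff(vapply(c(0.5, 1, 2), predictedCcgpError,
                              numeric(1), dN = 1, sigma = 1)) < 0))
  expect_true(all(diff(vapply(c(0.5, 1, 2), function(dn)
    predictedCcgpError(1, dn, 1), numeric(1))) > 0))
  for (dLV in c(0.8, 1.5)) for (dN in c(0.5, 1.5)) {
    spec <- makeCodeSpec(25, dLV, 1, dN, 1, seed = 140)
    g <- ccgpOracle(spec, nTest = 40000, nTrain = 20000, seed = 141)
    pred <- predictedCcgpError(dLV, dN, 1, attr(g, "epsilonTrain"))
    expect_lt(abs(as.numeric(g) - pred), 2 * attr(g, "se") + 2e-3)
  }
})

test_that("implied subspace correlation follows the distance ratio", {
  expect_equal(impliedSubspaceCorrelation(1, 0), 1)
  expect_equal(impliedSubspaceCorrelation(0, 1), 0)
  expect_equal(impliedSubspaceCorrelation(1, 1), 0.5)
  expect_error(impliedSubspaceCorrelation(0, 0), "undefined")
})

test_that("geometry is recovered end to end from simulated populations", {
  spec <- makeCodeSpec(100, dLV = 1, dLA = 2, dN = 1, sigma = 0.5,
                       seed = 151)
  pop <- simulatePopulation(spec, nRepeats = 500, seed = 152, nBins = 1)
  g <- estimateGeometry(pop, seed = 153)
  expect_lt(abs(g@dLV - 1) / 1, 0.1)
  expect_lt(abs(g@dLA - 2) / 2, 0.1)
  expect_lt(abs(g@dN - 1) / 1, 0.1)
  expect_lt(abs(g@sigma - 0.5) / 0.5, 0.1)
  expect_lt(abs(g@rho - 0.5), 0.05)
})
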
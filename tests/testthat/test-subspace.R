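test_that("value vectors combine coefficients by side", {
  n <- 300
  design <- makeDesign(n, seed = 91)
  ## no interaction: identical left and right vectors
  Y <- withr::with_seed(92, sapply(1:15, function(j)
    0.5 * j / 10 * design$value + 0.1 * design$side + rnorm(n, sd = 1e-8)))
  fits <- fitNeuronModels(makeWindowRates(Y, design), nWaicDraws = 0)
  vl <- valueSubspaceVector(fits, "left")
  vr <- valueSubspaceVector(fits, "right")
  expect_equal(vl, vr, tolerance = 1e-5)
  ## pure interaction: v_left = -v_right, correlation -1
  Y2 <- withr::with_seed(93, sapply(1:15, function(j)
    (j / 10) * design$value * design$side + rnorm(n, sd = 1e-8)))
  fits2 <- fitNeuronModels(makeWindowRates(Y2, design), nWaicDraws = 0)
  vl2 <- valueSubspaceVector(fits2, "left")
  vr2 <- valueSubspaceVector(fits2, "right")
  expect_equal(vl2, -vr2, tolerance = 1e-5)
  expect_equal(as.numeric(subspaceCorrelation(vl2, vr2)), -1,
               tolerance = 1e-6)
})

test_that("subspace correlation is a cosine with the expected null spread", {
  v <- rnorm(50)
  expect_equal(as.numeric(subspaceCorrelation(v, v)), 1)
  expect_equal(as.numeric(subspaceCorrelation(c(1, 0, 0), c(0, 1, 0))), 0)
  expect_error(subspaceCorrelation(rep(0, 10), rnorm(10)), "zero")
  draws <- withr::with_seed(94, replicate(1000,
    cosineSimilarity(rnorm(200), rnorm(200))))
  expect_lt(abs(mean(draws)), 3 / sqrt(200 * 1000) * 10)
  expect_lt(abs(sd(draws) - 1 / sqrt(200)), 0.01)
})

test_that("subspace correlation is invariant to scale and joint rotation", {
  withr::with_seed(95, {
    v1 <- rnorm(40); v2 <- rnorm(40)
    Q <- qr.Q(qr(matrix(rnorm(1600), 40)))
    r0 <- as.numeric(subspaceCorrelation(v1, v2))
    expect_equal(as.numeric(subspaceCorrelation(3.7 * v1, 0.2 * v2)), r0,
                 tolerance = 1e-12)
    expect_equal(as.numeric(subspaceCorrelation(Q %*% v1, Q %*% v2)), r0,
                 tolerance = 1e-12)
  })
})

test_that("noise-ceiling test is calibrated on matched codes and detects
           orthogonal ones", {
  pm <- vapply(1:20, function(r) {
    d <- makeCodedPopulation(dLV = 1, dN = 0, sigma = 0.5, seed = 9000 + r)
    noiseCeilingTest(Y = d$Y, design = d$design, nBoot = 200,
                     seed = r)@p
  }, numeric(1))
  expect_gte(mean(pm > 0.05), 0.9)
  po <- vapply(1:10, function(r) {
    d <- makeCodedPopulation(dLV = 0, dN = 2, sigma = 0.5, seed = 9500 + r)
    noiseCeilingTest(Y = d$Y, design = d$design, nBoot = 1200,
                     seed = r)@p
  }, numeric(1))
  expect_gte(mean(po < 0.001), 0.9)
  ## finite noise keeps the ceiling strictly below 1
  d <- makeCodedPopulation(dLV = 1, dN = 0.5, sigma = 0.6, seed = 96)
  res <- noiseCeilingTest(Y = d$Y, design = d$design, nBoot = 200,
                          seed = 97)
  expect_lt(mean(res@ceiling), 1)
  expect_error(noiseCeilingTest(Y = d$Y, design = d$design, nBoot = 201),
               "even")
})

test_that("all six task-functional comparisons are computable", {
  spec <- makeCodeSpec(30, 1, 1, 0.8, 0.4, seed = 98)
  beh <- filterTrials(simulateChoices(generateTaskSession(700, seed = 99),
                                      svParams(tau = 0.02), seed = 100))
  neu <- simulateNeuralSession(beh, spec, seed = 101)
  wr <- computeWindowRates(neu, minTrials = 300)
  fits <- list(offer1 = fitNeuronModels(wr, "offer1", nWaicDraws = 0),
               offer2 = fitNeuronModels(wr, "offer2", nWaicDraws = 0))
  cmp <- subspaceComparisons(fits)
  expect_equal(nrow(cmp), 6L)
  expect_true(all(is.finite(cmp$correlation)))
  expect_true(all(abs(cmp$correlation) <= 1))
})

test_that("alignment index spans its [0, 1] range as expected", {
  withr::with_seed(102, {
    load <- diag(c(6, 5, 4, rep(0.3, 17)))
    B <- matrix(rnorm(4000 * 20), 4000, 20) %*% load
    pc <- prcomp(B)
    expect_equal(alignmentIndex(pc$rotation[, 1:3], B), 1,
                 tolerance = 1e-9)
    ## subspace orthogonal to all variance
    B2 <- cbind(matrix(rnorm(500 * 3), 500, 3) %*% matrix(rnorm(9), 3),
                matrix(0, 500, 17))
    A <- rbind(matrix(0, 3, 2), diag(17)[, 1:2])
    expect_lt(alignmentIndex(A, B2), 1e-9)
    ## random k-dim subspace against isotropic data: total-variance
    ## normalization gives expectation k / N by the trace argument
    ai <- replicate(200, alignmentIndex(
      qr.Q(qr(matrix(rnorm(30 * 3), 30, 3))),
      matrix(rnorm(2000 * 30), 2000, 30), normalize = "total"))
    expect_lt(abs(mean(ai) - 3 / 30), 0.03)
    expect_error(alignmentIndex(matrix(rnorm(20 * 25), 20, 25), B),
                 "dimension")
  })
})

test_that("minimum population size finds the stability plateau", {
  withr::with_seed(103, {
    co <- rnorm(100)
    a <- estimateMinPopulationSize(co, seed = 104)
    b <- estimateMinPopulationSize(co, seed = 104)
    expect_identical(as.integer(a), as.integer(b))  # seeding contract
    prof <- attr(a, "profile")
    ## variance estimates converge to the truth as size grows
    expect_lt(abs(prof$variance[nrow(prof)] - var(co)), 0.1)
    ## spread decays with size (sublinear plateau growth)
    expect_true(all(diff(prof$spread) < 0))
    ## identical coefficients: smallest size, zero variance everywhere
    cc <- estimateMinPopulationSize(rep(1, 100), seed = 105)
    expect_equal(as.integer(cc), 5L)
    expect_true(all(attr(cc, "profile")$variance == 0))
    expect_error(estimateMinPopulationSize(rnorm(20), sizes = c(10, 30)),
                 "exceeds")
  })
})

test_that("behavior link recovers a planted attention effect", {
  ## higher lapse load in a bootstrap resample raises both the measured
  ## subspace correlation (nonlinear code attenuated) and the
  ## suboptimal-choice rate (misbound decisions)
  hits <- vapply(1:10, function(r) {
    spec <- makeCodeSpec(50, dLV = 1, dLA = 1, dN = 1.5, sigma = 0.4,
                         seed = 8000 + r)
    ls <- simulateLinkedSession(400, spec, svParams(tau = 0.02),
                                lapseProb = 0.35, lapseGain = 0,
                                lapseMisbind = 0.9, seed = 8100 + r)
    bl <- behaviorLink(ls$neural, ls$behavioral, nBoot = 300,
                       nPerm = 400, seed = r)
    ## p is the stated normal tail of the permutation z score
    expect_equal(bl@p,
                 1 - pnorm((bl@rEmpirical - bl@nullMean) / bl@nullSd))
    bl@p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  ## the session-size gate
  spec <- makeCodeSpec(10, 1, 1, 1, 0.4, seed = 106)
  ls <- simulateLinkedSession(100, spec, seed = 107)
  expect_error(behaviorLink(ls$neural, ls$behavioral), "30")
})
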
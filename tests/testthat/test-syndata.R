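test_that("task sessions reproduce the configured offer statistics", {
  s <- generateTaskSession(100000, seed = 1)
  tr <- trials(s)
  kinds <- c(tr$kind1, tr$kind2)
  pSafe <- mean(kinds == "safe")
  se <- sqrt(0.125 * 0.875 / length(kinds))
  expect_lt(abs(pSafe - 0.125), 3 * se)
  expect_lt(abs(mean(kinds == "medium") - 0.4375),
            3 * sqrt(0.4375 * 0.5625 / length(kinds)))
  ## stimulus onset asynchrony is exactly one second on every trial
  expect_true(all(tr$tOffer2 - tr$tOffer1 == 1000))
  ## stakes follow kind
  expect_true(all(tr$stakes1[tr$kind1 == "large"] == 0.240))
  expect_true(all(tr$prob1[tr$kind1 == "safe"] == 1))
})

test_that("gamble probabilities are uniform on the 1% grid", {
  s <- generateTaskSession(25000, seed = 7)
  tr <- trials(s)
  p <- c(tr$prob1[tr$kind1 != "safe"], tr$prob2[tr$kind2 != "safe"])
  expect_true(all(abs(p * 100 - round(p * 100)) < 1e-9))
  ## Kolmogorov-Smirnov against the discrete uniform, with a Monte-Carlo
  ## null at the same n (the discrete grid invalidates the asymptotic p)
  grid <- seq(0, 1, by = 0.01)
  ksStat <- function(x) {
    cdf <- ecdf(x)
    max(abs(cdf(grid) - (seq_along(grid)) / length(grid)))
  }
  obs <- ksStat(p)
  null <- withr::with_seed(99, replicate(200, ksStat(
    sample(grid, length(p), replace = TRUE))))
  expect_gt((sum(null >= obs) + 1) / 201, 0.01)
})

test_that("sessions are bit-reproducible from their seed", {
  a <- generateTaskSession(500, seed = 42)
  b <- generateTaskSession(500, seed = 42)
  expect_identical(trials(a), trials(b))
  p <- svParams(alpha = 0.8, tau = 0.05)
  expect_identical(trials(simulateChoices(a, p, seed = 9)),
                   trials(simulateChoices(b, p, seed = 9)))
})

test_that("softmax choices follow the logistic in relative value", {
  s <- generateTaskSession(10000, seed = 3)
  prm <- svParams(tau = 0.2, modelId = "obj-obj")
  s <- simulateChoices(s, prm, seed = 4)
  tr <- trials(s)
  dsv <- tr$prob1 * tr$stakes1 - tr$prob2 * tr$stakes2
  bins <- cut(dsv, quantile(dsv, seq(0, 1, 0.1)), include.lowest = TRUE)
  for (b in levels(bins)) {
    idx <- bins == b
    pHat <- mean(tr$choice[idx] == 1L)
    pThe <- mean(plogis(dsv[idx] / 0.2))
    expect_lt(abs(pHat - pThe),
              3 * sqrt(pThe * (1 - pThe) / sum(idx)) + 1e-9)
  }
  ## tau -> 0 limit: every choice is the subjective-value argmax
  s0 <- simulateChoices(s, svParams(tau = 1e-9, modelId = "obj-obj"),
                        seed = 5)
  tr0 <- trials(s0)
  dec <- abs(dsv) > 1e-12
  expect_true(all((tr0$choice == 1L) == (dsv > 0), na.rm = TRUE) ||
              all(((tr0$choice == 1L) == (dsv > 0))[dec]))
  ## equal subjective values: choice probability one half
  sEq <- s
  trEq <- trials(sEq)
  trEq$prob2 <- trEq$prob1; trEq$stakes2 <- trEq$stakes1
  sEq@trials <- trEq
  sEq <- simulateChoices(sEq, svParams(tau = 0.05, modelId = "obj-obj"),
                         seed = 6)
  expect_lt(abs(mean(trials(sEq)$choice == 1L) - 0.5),
            3 * sqrt(0.25 / nrow(trEq)))
})

test_that("the linear-nonlinear generator satisfies its geometry exactly", {
  spec <- makeCodeSpec(30, dLV = 1, dLA = 2, dN = 0.5, sigma = 0,
                       seed = 11)
  C <- conditionCentroids(spec)
  D <- as.matrix(dist(C))
  expect_lt(abs(D["11", "21"] - sqrt(1 + 0.25)), 1e-10)   # value pair
  expect_lt(abs(D["12", "22"] - sqrt(1 + 0.25)), 1e-10)
  expect_lt(abs(D["11", "12"] - sqrt(4 + 0.25)), 1e-10)   # context pair
  expect_lt(abs(D["11", "22"] - sqrt(1 + 4 + 0.25)), 1e-10) # diagonal
  ## sigma = 0: all repeats of a condition are identical
  pop <- simulatePopulation(spec, nRepeats = 3, seed = 12)
  Y <- windowMeans(pop)
  lab <- conditionLabels(pop)$cond
  for (cc in unique(lab)) {
    block <- Y[lab == cc, , drop = FALSE]
    expect_lt(max(abs(sweep(block, 2, block[1, ]))), 1e-12)
  }
  ## empirical 4x4 distances equal the model distances at sigma = 0
  cents <- t(vapply(c("11", "21", "12", "22"),
                    function(cc) colMeans(Y[lab == cc, , drop = FALSE]),
                    numeric(ncol(Y))))
  expect_lt(max(abs(as.matrix(dist(cents)) - D)), 1e-10)
})

test_that("orthogonality validity catches broken code specs", {
  spec <- makeCodeSpec(20, 1, 1, 1, 0.5, seed = 1)
  bad <- spec
  bad@L[, 1] <- bad@L[, 1] + 0.5 * bad@M[, 1]
  expect_error(validObject(bad), "orthogonal")
  expect_error(makeCodeSpec(5, 1, 1, 1, 0.5, seed = 1), "6")
})

test_that("a factorized code is ambiguous between chimeric stimulus sets", {
  ## dN = 0: the average response to X = {x11, x22} equals that to
  ## S = {x12, x21} exactly
  spec <- makeCodeSpec(25, dLV = 1.3, dLA = 0.9, dN = 0, sigma = 0,
                       seed = 13)
  C <- conditionCentroids(spec)
  expect_lt(max(abs((C["11", ] + C["22", ]) - (C["12", ] + C["21", ]))),
            1e-12)
  ## with dN > 0 the ambiguity is broken by sqrt(2) dN
  spec2 <- makeCodeSpec(25, dLV = 1.3, dLA = 0.9, dN = 0.8, sigma = 0,
                        seed = 13)
  C2 <- conditionCentroids(spec2)
  gap <- sqrt(sum(((C2["11", ] + C2["22", ]) -
                   (C2["12", ] + C2["21", ]))^2))
  expect_lt(abs(gap - sqrt(2) * 0.8), 1e-10)
})

test_that("regression on simulated rates recovers the subspace correlation", {
  spec <- makeCodeSpec(60, dLV = 1, dLA = 1, dN = 1, sigma = 0.3,
                       seed = 14)
  pop <- simulatePopulation(spec, nRepeats = 400, seed = 15, nBins = 1)
  lab <- conditionLabels(pop)
  design <- data.frame(value = lab$value - 1,
                       side = ifelse(lab$side == 1, 1, -1))
  vv <- subspaceBind:::.refitValueVectors(windowMeans(pop), design)
  rho <- cosineSimilarity(vv$left, vv$right)
  expect_lt(abs(rho - impliedSubspaceCorrelation(1, 1)), 0.08)
})

test_that("trial durations put the configured mass above the 7 s cutoff", {
  s <- generateTaskSession(20000, params = taskConfig(slowFrac = 0.01),
                           seed = 16)
  frac <- mean(trials(s)$duration > 7)
  expect_lt(abs(frac - 0.01), 3 * sqrt(0.01 * 0.99 / 20000))
})
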
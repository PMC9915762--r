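## Shared fixtures, built in code.

## A WindowRates object holding a single window with the given response
## matrix and design (value in [0,1], side in {-1, +1}).
makeWindowRates <- function(Y, design, window = "offer1") {
  Y <- as.matrix(Y)
  wr <- new("WindowRates",
            rates = setNames(list(Y), window),
            design = setNames(list(design), window),
            windows = data.frame(window = window, offer = 1L,
                                 start = 0, end = 400),
            excluded = data.frame())
  wr
}

## Balanced design of n trials: continuous value, effects-coded side.
makeDesign <- function(n, seed = 1) {
  withr::with_seed(seed, data.frame(
    value = runif(n),
    side = sample(c(-1, 1), n, replace = TRUE)))
}

## Single-epoch population matrices for the noise-ceiling tests.
makeCodedPopulation <- function(dLV, dN, sigma = 0.5, nNeurons = 40,
                                nRepeats = 100, seed = 1) {
  spec <- makeCodeSpec(nNeurons, dLV = dLV, dLA = 1, dN = dN,
                       sigma = sigma, seed = seed)
  pop <- simulatePopulation(spec, nRepeats = nRepeats,
                            seed = seed + 1000L, nBins = 1)
  lab <- conditionLabels(pop)
  list(spec = spec,
       Y = windowMeans(pop),
       design = data.frame(value = lab$value - 1,
                           side = ifelse(lab$side == 1, 1, -1)),
       pop = pop)
}

## Null table for the dip test at n = 500, shared across test files
## (computed once per session).
sharedDipNull <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- dipNull(500, nBoot = 299, seed = 424242)
    cache
  }
})
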
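# subspaceBind

When an animal chooses between two offers, the value of each offer must be
bound to the place (or moment) it appeared — otherwise a high value on the
left is indistinguishable from a high value on the right. `subspaceBind`
implements a population-geometry account of how neural populations solve
this binding problem: the value of offers in different contexts is encoded
in *semi-orthogonal subspaces*, produced by a mixture of linear and
nonlinear (conjunctive) mixed selectivity. The package is aimed at
computational and systems neuroscientists who want to simulate, fit and
stress-test this analysis pipeline end to end on synthetic data with known
ground truth.

## The model

Binary offer value and context (side, or offer epoch) define four
conditions x_vc, v, c ∈ {1, 2}. Population responses of N neurons follow a
linear–nonlinear code

    r(x) = L x_z + M f_N(x) + ε,     ε ~ N(0, σ² I)

where `L` (N×2, orthogonal columns of lengths d_LV and d_LA) is the linear
scaffold — a rectangle whose sides encode value and context factorially —
and `M` (N×4, mutually orthogonal columns of common length m = d_N/√2)
applies a conjunctive perturbation to each condition, so the nonlinear
component of every between-condition distance is d_N. The key quantities:

- **Subspace correlation** ρ = d_LV² / (d_LV² + d_N²): the cosine between
  the population value vectors of the two contexts (1 = one shared value
  code, 0 = orthogonal codes).
- **Binding error rate** ≈ N_S · Q(−√2·d_N / 2σ) with N_S = 1/4 by
  enumeration of linearly confusable stimulus sets: the probability a
  maximum-likelihood decoder decodes the *chimeric* pairing of values to
  contexts. It depends only on d_N and σ.
- **Generalization (CCGP) error rate** ≈ Q(−½ d_LV² / (σ √(d_LV² + d_N² +
  ε²))): the error of a linear decoder trained on the value contrast in
  one context and tested in the other (ε is the standard-error distance of
  the estimated centroids). It does not depend on d_LA.

Semi-orthogonal codes (0 < ρ < 1) keep both error rates low at once.
Around this core the package provides: a synthetic risky-choice task with
Prelec-warped power-utility softmax choices and a 4-model comparison by
penalized ML with Laplace evidence; per-neuron regression (noise / linear
/ interaction models, linear and B-spline value) with exact leave-one-out
Bayesian model stacking and permutation ANOVA; bootstrap noise-ceiling
tests of subspace separability and a session-level link between subspace
correlation and suboptimal choice; cross-validated (crossnobis) distance
matrices decomposed into (d_LV, d_LA, d_N); Monte-Carlo decoder oracles
for both error rates; pseudopopulation SVM decoding; and
population-structure statistics (sensitivity-index bimodality via an
exact Hartigan dip statistic, participation-ratio subspace contributions,
gain-vs-heterogeneous classification).

## Worked example

Simulate a population with known geometry, recover the geometry from
cross-validated distances, and compare the closed-form error rates with
Monte-Carlo decoder oracles:

```r
library(subspaceBind)

spec <- makeCodeSpec(nNeurons = 60, dLV = 1, dLA = 1.5, dN = 1,
                     sigma = 0.4, seed = 1)
spec
#> PopulationCodeSpec: 60 neurons
#>   dLV = 1, dLA = 1.5, dN = 1, sigma = 0.4
#>   implied subspace correlation rho = 0.500

pop  <- simulatePopulation(spec, nRepeats = 300, seed = 2, nBins = 1)
geom <- estimateGeometry(pop, seed = 3)
geom
#> GeometryEstimate
#>   dLV = 1.003, dLA = 1.51, dN = 0.9726
#>   sigma = 0.4031, epsilon = 0.2532, rho = 0.5156
#>   distance-matrix fit residual = 0.0795

predictErrorRates(spec, epsilon = geom@epsilon, nMC = 50000, seed = 4)
#> ErrorRatePrediction
#>   binding error: predicted 0.009637, Monte-Carlo 0.00724 (SE 0.00038)
#>   CCGP error:    predicted 0.1921, Monte-Carlo 0.194 (SE 0.0018)
```

The recovered distances match the generating (1, 1.5, 1) within a few
percent, the recovered subspace correlation sits at the implied ρ = 0.5,
and the closed-form CCGP error matches the prototype-decoder oracle
within Monte-Carlo error. The binding formula is a union-bound
approximation and sits slightly above the maximum-likelihood oracle when
the linear distances are only moderately larger than the noise (here
0.0096 vs 0.0072); with a wide linear scaffold the two agree within
Monte-Carlo error.

A full synthetic run — behavior simulation and model fitting, per-neuron
regression and stacking, subspace correlation against its noise ceiling,
geometry recovery and decoding — is one call:

```r
manifest <- runPipeline(pipelineConfig(seed = 7))
```

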
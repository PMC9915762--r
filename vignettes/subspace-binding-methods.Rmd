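---
title: "Binding value to space with semi-orthogonal subspaces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding value to space with semi-orthogonal subspaces: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subspaceBind)
```

This vignette is the package's own account of the models it implements,
the assumptions they rest on, the tunable parameters and their defaults,
and the design decisions taken where the methodology was genuinely open.

## The scientific problem

In a two-offer risky-choice task, each offer has a value and a location
(left/right) and a presentation epoch (first/second). A downstream reader
of the neural population must not only decode both values and both
locations but bind each value to its location: a purely factorized
(linear) population code makes the true stimulus pairing and its chimeric
swap exactly equally likely, so binding errors occur at chance. A
conjunctive (nonlinear) code component breaks this ambiguity at the cost
of generalization. The package quantifies that trade-off.

## The linear–nonlinear code

The generator (`makeCodeSpec()`, `simulatePopulation()`) draws responses

$$ r(x) = L x_z + M f_N(x) + \varepsilon, \qquad
   \varepsilon \sim \mathcal N(0, \sigma^2 I_N), $$

for the four conditions of the binary value × context grid. Choices made
here, and why:

- **Exact basis orthogonality.** The columns of `[L M]` are built by QR
  orthonormalization of seeded Gaussian vectors and then scaled, rather
  than relying on high-dimensional near-orthogonality of random vectors.
  This makes the small-N geometry exact: value-only condition pairs sit at
  distance $\sqrt{d_{LV}^2 + d_N^2}$, context-only pairs at
  $\sqrt{d_{LA}^2 + d_N^2}$, diagonal pairs at
  $\sqrt{d_{LV}^2 + d_{LA}^2 + d_N^2}$, to machine precision.
- **Stimulus coding.** The two levels of each feature are coded ±1/2
  after z-scoring, so the linear part of a value-pair distance is exactly
  $d_{LV}$ and is controlled by `L` alone, not by the arbitrary level
  labels.
- **Nonlinear column length.** Each condition's conjunctive column has
  length $m = d_N/\sqrt 2$, so the *difference* between two conditions'
  nonlinear components has length $d_N$, and the summed-response distance
  between a stimulus set and its chimeric partner is $\sqrt 2\, d_N$.
  These constants are not hard-coded articles of faith: the Monte-Carlo
  decoder oracles (below) independently confirm them.
- **Noise scale.** $\sigma$ is the SD of the *analysis-window mean*
  response. Tensors are emitted in 20-ms bins with iid per-bin noise of
  SD $\sigma\sqrt{B}$, where `windowBins` = B is the window length in
  bins (20 for the 400-ms windows). Averaging any B bins then reproduces
  SD $\sigma$ exactly; shorter windows (e.g. the three 300-ms decoding
  bins) carry proportionally more noise, which all estimators measure
  from data rather than assume.
- A Poisson spike-count emission layer was considered and deliberately
  left out of the core generator: the theory is stated in Gaussian terms
  and every downstream estimator consumes window means, for which the
  Gaussian description is the operative one.

## The behavioral model

The task generator reproduces the study conditions: offer kinds drawn at
(medium 43.75%, large 43.75%, safe 12.5%), stakes 0.165/0.240 mL for
risky offers (0.125 mL safe), gamble probabilities uniform on a 1% grid,
a 1000-ms stimulus onset asynchrony, and lognormal trial durations
calibrated so 1% exceed the 7-s inattention cutoff (both filters —
duration and safe offers — are applied by `filterTrials()`).

Choices follow a softmax on the subjective-value difference with
temperature τ, where SV = w(p)·u(s), u(s) = s^α (power utility) and
w(p) = exp(−β(−ln p)^γ), the two-parameter Prelec weighting function
(β = 1 recovers the one-parameter form; the two-parameter form nests it,
which is why it was chosen). The model space crosses objective vs power
stakes with objective vs Prelec probability (4 models).

Fitting (`fitChoiceModel()`) is penalized maximum likelihood on
log-parameters (a weak N(0, 2²) ridge) from 10 seeded starts — the
likelihood is multimodal — compared by a Laplace approximation to the log
evidence. A variational free-energy comparison would be asymptotically
equivalent; the Laplace route is deterministic and dependency-free. A
model whose Hessian is not positive definite is flagged non-identifiable
and cannot win.

**Known identifiability limit.** The task has only two risky stakes
magnitudes, so the utility exponent α is informed by a single contrast
and is weakly identified: at α near 1 the evidence for power-utility vs
objective-stakes models ties. Parameter recovery (coverage of the 95%
intervals) is reliable; model *selection* of the power-utility family is
reliable only for pronounced curvature.

## Per-neuron regression and model stacking

Window rates are 400-ms means (offer: 0–400 ms, delay: 450–850 ms after
each offer onset), z-scored per neuron and window; neurons need ≥ 300
recorded trials and nonzero variance. Five Gaussian OLS models are fitted
per neuron: intercept-only noise; value + side; and value + side +
side-by-value interaction, with value entered linearly or as a cubic
B-spline with 3 interior knots at the value quartiles (the spline
interaction multiplies every basis column by side). Side is effects-coded
−1/+1 and value min-max normalized to [0, 1]. Only the interaction models
can produce non-parallel value subspaces for the two sides.

Stacking weights maximize the leave-one-out log score of the mixture
predictive density. Because the candidates are Gaussian linear models,
the LOO predictive densities are available *exactly* from the OLS
case-deletion identities — no importance sampling is involved, so there
is no instability diagnostic or k-fold fallback to manage. The weight
optimization is a concave problem solved by EM. WAIC is reported
alongside from analytic normal-inverse-gamma posterior draws. On
degenerate (pure-noise) data stacking weights legitimately diffuse across
near-equivalent models; the noise model still receives the largest family
weight in most replicates, but this is a property of stacking, not a
model-selection guarantee.

Selectivity is assessed by a permutation ANOVA: value discretized into 7
equal-count levels, side, and their interaction; type-II F statistics are
referenced to a null built by permuting each neuron's rates against the
intact label table, with p = (#(F_perm ≥ F_obs) + 1)/(n_perm + 1).

## Subspace correlations and the noise ceiling

The value vector for one side is the population vector of model-predicted
rate changes from value 0 to 1: v(n) = β_value(n) ± β_interaction(n);
intercepts and side main effects cancel. The subspace correlation is the
cosine (unit-vector dot product) between two value vectors; the Pearson
correlation is attached as an attribute and is nearly identical in
practice.

The separability test compares the observed left–right correlation with a
noise ceiling — the correlation expected if both sides shared one value
code and disagreement arose only from firing-rate noise. A subtlety
matters here. If all bootstrap refits are made on resamples of the *same*
trial set, every refit shares the original sample's estimation noise in
the interaction coefficients; that shared noise inflates same-side
(ceiling) correlations and deflates left-vs-right ones, so matched codes
are systematically flagged as separated. `noiseCeilingTest()` therefore
estimates the two vectors entering *every* correlation — observed and
ceiling alike — from disjoint random halves of the trials within each
bootstrap iteration. Both distributions then carry the same attenuation,
the comparison is calibrated (verified in the test suite: no false
separation on matched codes, p < 0.001 on orthogonal ones), and the
surface of the procedure (1000 observed draws, 500 + 500 same-side
ceiling draws, bootstrap p = fraction of observed ≥ ceiling) is
unchanged.

The alignment index is provided in its canonical form (captured variance
normalized by the data's own top-k subspace) and, behind
`normalize = "total"`, as a total-variance fraction whose null
expectation is k/N — the two normalizations answer different questions
and both are exercised in the tests.

The session-level behavior link draws 500 bootstrap resamples, recomputes
the subspace correlation and the suboptimal-choice rate (fraction of
choices of the lower-SV offer, ties under 1e-9 excluded) on each
resample, correlates the two across bootstraps, and refers the
correlation to a permutation null via p = 1 − Φ((r − μ)/σ). The planted
effect used to validate it couples a latent per-trial attentional state
to both sides: lapse trials attenuate the conjunctive code (raising the
measured correlation toward its ceiling) and allow value misbinding in
the decision (raising the suboptimal rate). The minimum simultaneous
population (30 neurons) and the coefficient-variance plateau estimate of
the effective sample size mirror the analysis constants; the plateau
statistic is the *spread* of the subpopulation coefficient-variance
estimates (its mean is unbiased at every size and carries no information)
with a 5% relative-change tolerance.

## Geometry estimation and the error-rate theory

Cross-validated squared distances (`crossnobisMatrix()`) are the average
over ordered fold pairs of inner products of independent fold-wise
mean-difference vectors — unbiased, hence allowed to be negative under
the null; no noise-whitening is applied, and 5 folds are used by default.
The 4×4 matrix is decomposed by nonnegatively-constrained least squares
into (d_LV², d_LA², d_N²) under the equal-perturbation-length assumption;
the problem is convex, and the multi-start spread is reported as a
stability check. σ is the SD of trial residuals projected on the
unit-normalized training-pair centroid axis (the unit-projection
convention); the standard-error distance uses
ε² = 2·mean_c(Σ_j s²_jc/n_c), the factor 2 because a centroid
*difference* carries two centroids' estimation error.

Binding errors: N_S is computed by explicit enumeration of ordered
presented pairs and their linearly confusable chimeric multisets (1/4 for
the 2×2 two-stimulus case), not hard-coded, and the Q-orientation is
fixed by requiring the rate to decrease in d_N/σ. The closed form is a
union bound; the maximum-likelihood oracle (`bindingErrorOracle()`,
nearest summed-centroid decoding over all candidate multisets with
uniform tie-breaking) sits slightly below it when the linear distances
are only moderately larger than σ, because competing non-chimeric sets
occasionally win; the package reports the discrepancy rather than
asserting tightness. At d_N = 0 the oracle's tie-broken rate is exactly
N_S/2.

Generalization: for the prototype (nearest-class-centroid) decoder the
closed form is exact under the generator when ε → 0, and the oracle
(`ccgpOracle()`) confirms it within Monte-Carlo error across parameter
grids. The empirical SVM decoder adds finite-sample boundary noise; with
about 4000 pseudotrials per condition its CCGP error is statistically
indistinguishable from the prediction (the package's agreement tests use
the population-to-population standard error, which carries the decoder's
own variability).

## Decoding

Pseudopopulations use three non-overlapping 300-ms bins starting 100 ms
after offer onset as separate features, with all bins of one sampled
trial kept together; trials are sampled without replacement within
condition (with-replacement sampling is available), under per-condition
inclusion thresholds of 160 (broad splits) or 80 (narrow splits) trials.
Value is binarized by inclusive rank percentiles (p = (rank − ½)/n) at
35/65, excluding the middle 30-percentile band. Preprocessing —
per-feature z-scoring then PCA retaining ≥ 99% variance — is learned on
the training split only (a planted-leakage test corrupts the test rows
and asserts the training-side results are bit-identical); the soft-margin
linear SVM uses cost 1, 10% of training-context pseudotrials are held out
for standard accuracy, and CCGP accuracy is evaluated on all
test-context pseudotrials.

## Population structure

The sensitivity index z-scores each side's per-neuron value-tuning
coefficients across the population and takes the per-neuron difference;
a population-level gain or offset on one side is removed by that side's
z-scoring. Two side-specialized subpopulations produce a bimodal index
distribution, a shared heterogeneous population a unimodal one.

The dip statistic is implemented from its definition — the minimal
sup-distance between the empirical CDF and the class of unimodal CDFs
(convex below the mode, concave above, one jump allowed at the mode) — in
compiled C++: bisection on the tolerance with exact band-feasibility
checks for every mode position, including the convexity-continuation
constraints through the mode. Those junction constraints are what let the
dip see bimodal clusters that have internal spread; dropping them is
tempting and wrong. The implementation reproduces the analytic limits
(two equal point masses → 1/4, k equal spikes → 1/(2k), even spacing →
1/(2n)) and a set of frozen reference values computed with an independent
linear-programming encoding of the same definition. p values come from a
bootstrap uniform null at the observed n (the least favorable unimodal
null), which is exact at any sample size; null tables can be precomputed
and shared.

Subspace contributions are normalized fourth-power shares
v(n)⁴/Σv(j)⁴ (the participation-ratio form); the retained set is the
smallest top-ranked set reaching 95% cumulative contribution, with a
count-percentile alternative behind a flag since the retention rule
admits both readings. Gain vs heterogeneous classification bootstraps the
arg-peak of the 7-level value tuning per side and tests the peak shift
against a resampled null; neurons in only one subspace are gated out as
`single_subspace`, flat tuning is excluded.

## Problem sizes and reproducibility

Defaults mirror the analysis constants (20-ms bins; 400-ms windows at
0–400 and 450–850 ms; 1000/500 bootstrap counts; 7 value levels; 160/80
decoding thresholds; 30-neuron session minimum). The validation suite
runs at sizes chosen to make each statistical property measurable with
comfortable margins on a single CPU: e.g. geometry recovery at 100
neurons × 500 trials/condition, oracle grids at 10⁵ Monte-Carlo samples
per cell, calibration runs of 20–50 seeded replicates, dip tests at
n = 500 with shared 299-draw null tables. Every stochastic operation
takes an explicit seed; `runPipeline()` writes per-stage outputs with MD5
hashes and reproduces them bit-for-bit from the same configuration.

## What the synthetic tests do and do not show

The generator matches the statistical structure the analysis assumes:
isotropic Gaussian window noise, exactly orthogonal code axes, equal
nonlinear perturbation lengths, stationary tuning within a session. Real
recordings violate all four in degree — correlated noise across neurons,
approximate orthogonality, condition-dependent perturbations, drift — so
green tests here establish the *internal* correctness and calibration of
the pipeline, not that cortical populations satisfy the model. The
region-specific empirical findings (subspace correlations below their
noise ceilings, 10–19% interaction-model neurons, behavior-link r around
0.15–0.2, 13–18% suboptimal choices) concern recordings that are not
publicly deposited and are deliberately not asserted as targets anywhere
in this package.
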
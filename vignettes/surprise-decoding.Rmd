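---
title: "Decoding trial-by-trial surprise from epoched neural data"
author: "surpriseDecoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding trial-by-trial surprise from epoched neural data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surpriseDecoder)
```

This vignette is the package's account of its model and of the design
choices behind the implementation: what is computed, under which
assumptions, which parameters matter, and what the synthetic data can and
cannot tell you about real recordings.

## The ideal observer

A binary oddball stream x_1, …, x_T (0 = standard, 1 = deviant) is
modelled as a first-order Markov chain. Because each column of the 2×2
transition matrix sums to one, two probabilities suffice:
θ_{0|1} (a standard after a deviant) and θ_{1|0} (a deviant after a
standard). The observer maintains *leaky* transition counts n_{a|b}:
every time a transition is observed, all four counts are first multiplied
by exp(−1/w) and then the observed transition's count is incremented by
one. Unrolling the recursion, a transition observed k steps in the past
carries weight exp(−k/w), so w — the *integration coefficient* — is the
e-folding memory of the observer in units of trials. As w → ∞ the counts
become plain tallies and the observer is the classical perfect-memory
estimator.

With a uniform Beta(1, 1) prior on each free parameter, conjugacy keeps
the belief in closed form at every trial:

$$p(\theta \mid X) =
  \mathrm{Beta}(1 + n_{0|1},\, 1 + n_{1|1})\,
  \mathrm{Beta}(1 + n_{1|0},\, 1 + n_{0|0}).$$

The likelihood of a full sequence under fixed parameters is
$0.5\,\theta_{0|1}^{n_{0|1}}(1-\theta_{0|1})^{n_{1|1}}
 \theta_{1|0}^{n_{1|0}}(1-\theta_{1|0})^{n_{0|0}}$, the leading 0.5 being
the assumed probability of the first stimulus. The first trial induces no
transition: the belief is left untouched and the predictive probability
of trial 1 is exactly 1/2. These conventions are unit-tested against
brute-force oracles (exhaustive enumeration of all 2^T sequences sums the
likelihood to 1; a 2001-point grid-Bayes update reproduces the posterior
means).

Two modelling points were genuinely open and were settled as follows.

* **Prediction rule.** The predictive probability is the posterior mean
  of the relevant Beta factor (the Laplace rule), e.g.
  p(1|0) = (1 + n_{1|0})/(2 + n_{1|0} + n_{0|0}), not the MAP. The
  posterior predictive is the Bayes-optimal point prediction and the
  standard choice in the ideal-observer literature.
* **Where the leak acts.** The decay is applied at every transition,
  i.e. between the prior at trial t and the posterior at trial t
  (decay-then-increment). The alternative — decaying only between trials
  — differs by at most one decay factor on the newest count and is
  indistinguishable at the w values of interest; the recursion used here
  is the one whose unrolled weights are exactly exp(−lag/w).

## Three surprise quantifications

All three series are computed from the same belief trajectory and are
returned in nats (a `logBase = "2"` option rescales to bits; since the
decoder is exactly invariant under affine label transforms, the base has
no effect on any decoding result — this is asserted to 1e−9 in the
tests).

* **Shannon surprise** −log p(x_t | x_{t−1}): the unlikeliness of the
  input under the observer's prediction. Trial 1 is ln 2.
* **Bayesian surprise** KL(posterior ‖ prior), summed over the two
  independent Beta factors: how far the belief moved. Trial 1 is 0.
* **Confidence-corrected surprise** KL(current belief ‖ naive posterior),
  where the naive posterior is a uniform belief updated with only the
  single most recent transition: unexpectedness weighted by how committed
  the belief is. Trial 1 is 0.

The Beta–Beta KL divergence is evaluated in closed form with log-Beta and
digamma functions and verified against adaptive quadrature to 1e−6 over a
parameter grid. The KL orientations above are the defaults; both
orientations are available via the `orientation` argument because the
divergence direction for the two divergence-based measures is a
convention, not a mathematical necessity. The naive observer's
first-stimulus factor cancels in the factorized KL and is ignored.

A property worth knowing: for large w and equiprobable transitions the
running mean of Shannon surprise converges to ln 2, a useful sanity check
on long sequences.

## The decoder

Feature matrices S_{N×p′} are built from the epoch tensor under five
regimes: *entire* (all channels × all samples, e.g. p′ = 80 × 69 = 5520
for 69 components at 80 samples), *samples* (the single sample nearest a
target time), *intervals* (epoch start through a target time), *segments*
(baseline −200–0 ms, early 0–t1, middle t1–t2, late t2–600 ms), and
*spatial* (one channel's time course). Columns are ordered channel-major
so coefficient positions are stable and interpretable. Segment membership
uses half-open [start, end) windows, with the late segment closed at the
epoch end, so the four segments partition the epoch's columns exactly —
an invariant the tests assert literally.

Decoding is Lasso regression with nested cross-validation: an outer
fivefold split (a seeded uniform shuffle of trials, which the regression
treats as exchangeable), and within each training fold (i) features and
labels standardized using training-fold statistics only and (ii) the L1
penalty selected by an inner fivefold `cv.glmnet` over a ~20-point
logarithmic path. Decoding power is R² on each outer test fold, measured
against that fold's own label variance, averaged across folds (a pooled
variant is available). Held-out R² of a mis-fit model is legitimately
negative and is reported as such. The per-fold label standardization is
what makes the reported R² *exactly* affine-invariant in the labels.

The description of the analysis fixes fivefold cross-validation but not
the penalty-selection protocol; the nested layout was chosen because a
single-level protocol that selects the penalty on the same folds it
reports would bias R² upward. Feature standardization before the L1 fit
is on by default for the same reason: without it the penalty's meaning
depends on arbitrary per-channel scales.

Chance levels are obtained by uniformly permuting the label vector
(seeded; the identity permutation is not excluded) and rerunning the
*entire* nested fit each time; the empirical p-value of an observed R² is
(1 + #{chance ≥ observed}) / (n_permutations + 1). One hundred
permutations are used for the headline entire-epoch analyses.

Because decoding power depends on the integration coefficient, the
decoder is swept over a w grid and the maximum is reported, with ties
broken toward smaller w. The full default grid is the integers 1–100; the
acceptance analyses use the log-spaced subset {1, 2, 4, 8, 16, 32, 64,
100}, which is sufficient because neighbouring w produce highly
correlated label series and recovery is only meaningful to within a small
factor.

## Temporal structure: curves, boundaries, segments

The *samples* curve decodes each time point separately; the *intervals*
curve decodes growing prefixes (its final point coincides with the
entire-epoch fit — asserted element-wise in the tests). Segment
boundaries are then defined behaviourally from the samples curve: t1 is
the earliest post-stimulus time reaching 10% of the post-stimulus maximum
decoding power (baseline power is noise, so the pre-stimulus part of the
curve is excluded from the maximum), and t2 is the minimum of the curve
within [250, 400] ms (earliest sample on ties), separating the middle and
late response. A curve with no positive post-stimulus power has no
detectable response and boundary detection refuses it.

With multiple replicates the boundaries are detected once, on the
first/reference dataset's curve, and applied to all replicates — the
analysis reports a single (t1, t2) pair per measure; a per-replicate
option is a straightforward loop over `detectSegments()`.

Segment and channel comparisons use the standard machinery: paired
t-tests of decoding power against matched chance levels across
replicates, with a Bonferroni family of 12 (three measures × four
temporal conditions, threshold 0.0042); a one-way repeated-measures ANOVA
across early/middle/late segments via `aov` with an
`Error(subject/segment)` stratum, followed by the three pairwise paired
t-tests at threshold 0.05/3 ≈ 0.0167. Sphericity correction is
deliberately omitted. Degenerate inputs (identical powers everywhere)
yield F = 0, p = 1 rather than NaN.

## The synthetic-data generator

The generator emulates the study conditions the analysis assumes: one
block of 405 trials with deviant probability 1/3, epochs of 80 samples
spanning −200…600 ms, and an evoked component confined to a latency
window. Its model is

$$\mathrm{data}(n, c, t) = L_c\,(\beta_0 + \beta_1 S(n))\,g(t) +
  \eta(n, c, t),$$

with S the ground-truth surprise series **z-scored across trials** (so
β₁ means "signal amplitude per SD of surprise" regardless of measure),
g(t) a Gaussian bump at 250 ± 50 ms with unnormalized peak 1 (the
simplest smooth surrogate of an evoked component), L_c seeded
standard-normal channel loadings scaled to unit root-mean-square (a
reproducible, heterogeneous topography), and η Gaussian noise,
independent across trials and channels, AR(1) along time with stationary
marginal SD `noiseSd`. Defaults: β₀ = 1, β₁ = 0.5, noiseSd = 1 (a 0.5
gain-to-noise ratio), lag-1 autocorrelation 0.5 — the order of magnitude
a 30 Hz low-passed recording resampled near 100 Hz exhibits — and ground
truth Shannon at w = 16.

What this emulates well: a surprise-proportional single-trial response
with realistic trial counts, a nontrivial topography, and temporally
correlated noise. What it does *not* emulate: 1/f spectra and sensor
crosstalk, artifacts, spatiotemporally correlated noise fields, source
mixing, or any nonlinearity between surprise and amplitude. Passing the
recovery tests therefore demonstrates that the pipeline is correct and
sensitive under its own assumptions — not that real recordings carry this
much decodable surprise; published entire-epoch decoding powers on real
MEG data are an order of magnitude smaller than the synthetic ones here.

The generator is also the package's null machine: with β₁ = 0 the data
are statistically independent of the labels, and the decoder's
entire-epoch R² must fall inside the permutation chance band (mean chance
R² in [−0.05, 0.02] at these problem sizes — slightly negative, as
held-out R² under the null is).

## Numerical choices and degenerate inputs

* "Nearest sample" ties at half-grid resolve to the earlier sample;
  resampling is plain decimation onto an even grid over the same window
  (whether an anti-alias filter should precede the second decimation is
  left to upstream preprocessing; synthetic data need none).
* Constant feature columns standardize to all-zero rather than dividing
  by zero; single-column feature matrices are padded with a null column
  to satisfy the regression backend without affecting the fit.
* Zero-variance labels, empty segments, out-of-epoch target times,
  unknown channels, non-binary codes, and fold counts below 2 all raise
  immediate, named errors.
* KL round-off below zero is clipped at exactly 0 (divergences are
  nonnegative by construction).
* Beta parameters at or below 0 are rejected; degenerate transition
  probabilities 0/1 in the sequence likelihood zero the product instead
  of erroring (0⁰ = 1).

Component extraction (for sensor sets large enough that channel features
are strongly dependent) is a seeded symmetric fixed-point ICA with the
logcosh contrast on the channels × (trials · time) unfolding, written
in-package, with an iteration cap that is reported on non-convergence and
an identity bypass for data whose channels are already the features of
interest. Only magnetometer-style amplitude data are expected; no sensor
geometry is used anywhere, and topographic rendering is left to external
tools via the CSV output of `spatialMap()`.

## Reproducibility and problem sizes

Every stochastic step takes an explicit seed; a master seed fans out to
stage seeds as child(i) = (master + 7919·i) mod (2³¹ − 1), so stages can
be rerun in isolation. `runPipeline()` writes every intermediate and a
summary JSON that is byte-identical across reruns of the same config.

The bundled analyses run at the emulated study scale — 405 trials, 20
channels, 80 samples, 100 permutations for entire-epoch chance levels, 10
replicates with 10 permutations per segment for the replicate statistics
(the replicate-level t-test only consumes the per-replicate chance
*mean*, so a small permutation count per replicate suffices). A
sweep at the full w = 1…100 grid, denser permutation counts, or more
replicates are one-argument changes.

## Known limitations

* The observer is strictly first-order Markov with exponential
  forgetting; item-frequency observers, higher-order models and
  hierarchical volatility models are out of scope.
* The decoder is linear; any nonlinear surprise encoding is invisible to
  it beyond its linear component.
* Paired-measure spatial tests require replicates; a single dataset
  yields the map only.
* The synthetic generator's simplifications listed above mean absolute
  decoding powers obtained on it do not transfer to real data.
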
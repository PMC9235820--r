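# Shared fixtures, built in code.

# A small synthetic dataset: quick to simulate, still carries a clear
# surprise encoding at 250 +/- 50 ms.
smallSpec <- function(nTrials = 60L, nChannels = 4L, nSamples = 20L, ...) {
  syntheticEpochSpec(nTrials = nTrials, nChannels = nChannels,
                     timesMs = seq(-200, 600, length.out = nSamples), ...)
}

smallDataset <- function(seed = 11L, ...) {
  seq <- generateOddball(60, 1 / 3, seed = seed)
  list(seq = seq, tensor = simulateEpochs(seq, smallSpec(...)))
}

# Brute-force unweighted transition tallies (independent oracle for the
# leaky-count recursion at very large w).
tallyOracle <- function(labels) {
  n <- c(n0g0 = 0, n1g0 = 0, n0g1 = 0, n1g1 = 0)
  for (t in seq_along(labels)[-1]) {
    j <- 1L + labels[t] + 2L * labels[t - 1L]
    n[j] <- n[j] + 1
  }
  n
}

# Grid-based Bayesian posterior mean for one Beta factor (independent
# oracle for conjugate updating): uniform prior on a 2001-point theta
# grid, multiplied by Bernoulli likelihoods theta^k (1-theta)^m.
gridPosteriorMean <- function(k, m, nGrid = 2001L) {
  theta <- seq(0, 1, length.out = nGrid)
  post <- theta^k * (1 - theta)^m
  sum(theta * post) / sum(post)
}

# Numerical-quadrature KL between Beta densities (oracle for klBeta).
# Substituting x = sin^2(u) removes the endpoint singularities that appear
# for shape parameters below 1.
klQuadrature <- function(a1, b1, a2, b2) {
  integrand <- function(u) {
    x <- sin(u)^2
    stats::dbeta(x, a1, b1) *
      (stats::dbeta(x, a1, b1, log = TRUE) -
         stats::dbeta(x, a2, b2, log = TRUE)) * 2 * sin(u) * cos(u)
  }
  stats::integrate(integrand, 0, pi / 4, rel.tol = 1e-9,
                   subdivisions = 1000L)$value +
    stats::integrate(integrand, pi / 4, pi / 2, rel.tol = 1e-9,
                     subdivisions = 1000L)$value
}
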
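# The leaky-count recursion, the conjugate Beta belief, and the sequence
# likelihood.

test_that("leaky counts reduce to exact transition tallies at very large w", {
  cts <- transitionCounts(w = 1e9)
  cts <- updateCounts(cts, 0, 1)
  expect_equal(cts@n1g0, 1)
  expect_equal(cts@n0g0 + cts@n0g1 + cts@n1g1, 0)

  labels <- withr::with_seed(42, rbinom(1000, 1, 1 / 3))
  post <- surpriseDecoder:::leakyCountMatrix(labels, 1e9)
  oracle <- tallyOracle(labels)
  expect_equal(post[1000, ], oracle, tolerance = 1e-6)
})

test_that("exponential forgetting weights transitions by exp(-lag/w)", {
  cts <- transitionCounts(w = 1)
  cts <- updateCounts(cts, 0, 0)
  cts <- updateCounts(cts, 0, 0)
  expect_equal(cts@n0g0, 1 + exp(-1), tolerance = 1e-12)
  # direct evaluation of the weighted sum over lags for a longer run
  labels <- rep(0L, 6)
  post <- surpriseDecoder:::leakyCountMatrix(labels, 2.5)
  expect_equal(unname(post[6, "n0g0"]), sum(exp(-(0:4) / 2.5)),
               tolerance = 1e-12)
})

test_that("update rejects non-binary codes and negative-w construction", {
  expect_error(updateCounts(transitionCounts(1), 2, 0), "binary")
  expect_error(transitionCounts(-1))
})

test_that("belief trajectory matches a brute-force grid Bayesian update", {
  labels <- withr::with_seed(7, rbinom(50, 1, 1 / 3))
  traj <- beliefTrajectory(stimulusSequence(labels), w = 1e9)
  n <- tallyOracle(labels)
  post <- traj@posterior[50, ]
  # factor for theta_{1|0}: likelihood theta^{n1|0} (1-theta)^{n0|0}
  expect_equal(post[["alphaGiven0"]] / (post[["alphaGiven0"]] + post[["betaGiven0"]]),
               gridPosteriorMean(n[["n1g0"]], n[["n0g0"]]), tolerance = 1e-3)
  expect_equal(post[["alphaGiven1"]] / (post[["alphaGiven1"]] + post[["betaGiven1"]]),
               gridPosteriorMean(n[["n0g1"]], n[["n1g1"]]), tolerance = 1e-3)
})

test_that("belief trajectory honours the no-transition first trial", {
  traj <- beliefTrajectory(stimulusSequence(c(0L)), w = 3)
  expect_equal(length(traj), 1L)
  expect_equal(unname(traj@prior[1, ]), rep(1, 4))
  expect_equal(unname(traj@posterior[1, ]), rep(1, 4))

  traj2 <- beliefTrajectory(stimulusSequence(c(0L, 1L)), w = 3)
  st <- beliefAt(traj2, 2, "posterior")
  expect_equal(st@given0, c(2, 1))  # one 0 -> 1 transition
  expect_equal(st@given1, c(1, 1))
  # prior at t equals posterior at t - 1
  expect_equal(traj2@prior[2, ], traj2@posterior[1, ])
  expect_error(beliefTrajectory(integer(0), 3), "at least one trial")
  expect_error(beliefTrajectory(c(0, 1), w = 0), "positive")
})

test_that("trajectory parameters stay finite and >= 1 along long sequences", {
  labels <- withr::with_seed(3, rbinom(200, 1, 1 / 3))
  traj <- beliefTrajectory(stimulusSequence(labels), w = 16)
  expect_true(all(is.finite(traj@posterior)))
  expect_true(all(traj@posterior >= 1))
  expect_true(all(traj@prior >= 1))
})

test_that("predictive probability is the Beta-factor mean and sums to one", {
  expect_equal(predictiveProbability(beliefState(), 0, 1), 0.5)
  expect_equal(predictiveProbability(beliefState(), 1, 0), 0.5)
  b <- beliefState(given0 = c(3, 2))
  expect_equal(predictiveProbability(b, 0, 1), 0.6)
  for (prev in 0:1) {
    b2 <- beliefState(given1 = c(2.3, 5.1), given0 = c(7, 1.2))
    expect_equal(predictiveProbability(b2, prev, 0) +
                   predictiveProbability(b2, prev, 1), 1)
  }
  expect_error(predictiveProbability(beliefState(), 0, 3), "binary")
})

test_that("sequence likelihoods are correct and sum to one over all sequences", {
  expect_equal(sequenceLikelihood(c(0), 0.3, 0.9), 0.5)
  expect_equal(sequenceLikelihood(c(0, 1), 0.5, 0.2), 0.1)
  # degenerate parameters zero the product instead of erroring
  expect_equal(sequenceLikelihood(c(0, 1), 0.5, 0), 0)
  expect_equal(sequenceLikelihood(c(0, 0), 0.5, 0), 0.5)
  expect_error(sequenceLikelihood(integer(0), 0.5, 0.5), "at least one trial")

  for (T in c(5L, 8L)) {
    grid <- as.matrix(expand.grid(rep(list(0:1), T)))
    tot <- sum(apply(grid, 1, sequenceLikelihood,
                     theta01 = 0.37, theta10 = 0.81))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})
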
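# Nested cross-validated Lasso decoding, its invariances, and the
# permutation chance machinery.

test_that("a perfectly encoded label is decoded almost exactly", {
  X <- withr::with_seed(1, matrix(rnorm(200 * 10), 200))
  y <- 2 * X[, 3] + 1
  expect_gte(decodingPower(fitDecode(X, y, seed = 1)), 0.99)
})

test_that("labels independent of the features decode at chance", {
  X <- withr::with_seed(2, matrix(rnorm(400 * 100), 400))
  y <- withr::with_seed(3, rnorm(400))
  expect_lte(decodingPower(fitDecode(X, y, seed = 1)), 0.05)
})

test_that("decoding power is exactly invariant under affine label transforms", {
  d <- smallDataset()
  X <- buildFeatures(d$tensor, regimeSpec("entire"))
  y <- surpriseValues(surpriseSeries(d$seq, "shannon", 16))
  base <- decodingPower(fitDecode(X, y, seed = 4))
  for (ab in list(c(3.7, -2), c(-0.5, 10), c(1 / log(2), 0))) {
    r <- decodingPower(fitDecode(X, ab[1] * y + ab[2], seed = 4))
    expect_lt(abs(r - base), 1e-9)
  }
})

test_that("duplicating feature columns leaves the fit unchanged", {
  X <- withr::with_seed(5, matrix(rnorm(150 * 12), 150))
  y <- X[, 1] - 0.5 * X[, 7] + withr::with_seed(6, rnorm(150, sd = 0.5))
  r1 <- decodingPower(fitDecode(X, y, seed = 2))
  r2 <- decodingPower(fitDecode(cbind(X, X), y, seed = 2))
  expect_lt(abs(r1 - r2), 1e-6)
})

test_that("decoding is deterministic given the seed", {
  d <- smallDataset()
  X <- buildFeatures(d$tensor, regimeSpec("entire"))
  y <- surpriseSeries(d$seq, "shannon", 16)
  expect_identical(decodingPower(fitDecode(X, y, seed = 9)),
                   decodingPower(fitDecode(X, y, seed = 9)))
})

test_that("degenerate inputs are rejected with clear errors", {
  X <- matrix(rnorm(60 * 5), 60)
  expect_error(fitDecode(X, rep(1, 60)), "zero variance")
  expect_error(fitDecode(X, rnorm(59)), "must agree")
  expect_error(fitDecode(X[1:8, ], rnorm(8), nFolds = 5), "2 \\* nFolds")
  expect_error(fitDecode(X, rnorm(60), nFolds = 1), "at least 2")
})

test_that("held-out r2 rises monotonically with the signal-to-noise ratio", {
  r2s <- vapply(c(0, 0.25, 0.5, 1.0), function(snr) {
    seq <- generateOddball(200, 1 / 3, seed = 31)
    tensor <- simulateEpochs(seq, smallSpec(nTrials = 200, nChannels = 10,
                                            nSamples = 40, beta1 = snr,
                                            noiseSd = 1))
    X <- buildFeatures(tensor, regimeSpec("entire"))
    decodingPower(fitDecode(X, surpriseSeries(seq, "shannon", 16),
                            seed = 7))
  }, numeric(1))
  expect_true(all(diff(r2s) >= 0))
})

test_that("the empirical p-value follows the permutation formula", {
  ch <- new("ChanceDistribution", r2Samples = seq(-0.05, 0.04, length.out = 99),
            nPermutations = 99L, seed = 1L)
  expect_equal(empiricalP(ch, 1), 0.01)         # above every sample
  expect_equal(empiricalP(ch, -1), 1)           # below every sample
  expect_equal(empiricalP(ch, max(chanceSamples(ch))), 2 / 100)
})

test_that("chance distributions are seeded and centred near zero", {
  d <- smallDataset()
  X <- buildFeatures(d$tensor, regimeSpec("samples", tMs = 250))
  y <- surpriseSeries(d$seq, "shannon", 16)
  ch1 <- chanceLevel(X, y, nPermutations = 10, seed = 5)
  ch2 <- chanceLevel(X, y, nPermutations = 10, seed = 5)
  expect_identical(chanceSamples(ch1), chanceSamples(ch2))
  expect_lt(mean(chanceSamples(ch1)), 0.05)
})

test_that("the w sweep tags its results and breaks ties toward smaller w", {
  d <- smallDataset()
  sw <- sweepW(d$tensor, d$seq, "shannon", wGrid = 16, seed = 2)
  expect_equal(sw$bestW, 16)
  expect_length(sw$results, 1)

  sw3 <- sweepW(d$tensor, d$seq, "bayesian", wGrid = c(4, 16), seed = 2)
  expect_true(all(vapply(sw3$results, function(r) r@measure, character(1))
                  == "bayesian"))
  expect_true(all(vapply(sw3$results, function(r) r@regime@regime,
                         character(1)) == "entire"))
  expect_error(sweepW(d$tensor, d$seq, "shannon", wGrid = numeric(0)),
               "nonempty")
})
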
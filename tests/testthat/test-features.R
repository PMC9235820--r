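# Epoch container round trips, resampling, component extraction, and
# feature-matrix construction for every regime.

test_that("epoch tensors round-trip losslessly through the HDF5 container", {
  d <- smallDataset()
  path <- withr::local_tempfile(fileext = ".h5")
  writeEpochs(d$tensor, path)
  back <- readEpochs(path)
  expect_equal(epochData(back), epochData(d$tensor))
  expect_equal(epochTimes(back), epochTimes(d$tensor))
  expect_identical(channelNames(back), channelNames(d$tensor))
  expect_identical(trialLabels(back), trialLabels(d$tensor))
  expect_identical(back@kind, d$tensor@kind)
})

test_that("reading a container without stimuli names the missing dataset", {
  path <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(path)
  rhdf5::h5write(array(0, c(2, 2, 3)), path, "data")
  rhdf5::h5write(c(0, 10, 20), path, "times_ms")
  rhdf5::h5write(c("a", "b"), path, "channel_names")
  rhdf5::h5closeAll()
  expect_error(readEpochs(path), "missing dataset 'stimuli'")
})

test_that("resampling decimates onto an even grid over the same window", {
  seq <- generateOddball(10, 1 / 3, seed = 3)
  spec <- smallSpec(nTrials = 10, nChannels = 2, nSamples = 200)
  tensor <- simulateEpochs(seq, spec)
  down <- resampleEpochs(tensor, 80)
  expect_equal(dim(down)[3], 80)
  expect_equal(range(epochTimes(down)), range(epochTimes(tensor)))
  # identity when the sample count is unchanged
  same <- resampleEpochs(tensor, 200)
  expect_equal(epochData(same), epochData(tensor))
  # a constant-in-time signal stays constant
  flat <- epochTensor(array(5, c(3, 2, 50)), seq(-200, 600, length.out = 50),
                      stimuli = c(0, 1, 0))
  expect_true(all(epochData(resampleEpochs(flat, 10)) == 5))
  expect_error(resampleEpochs(tensor, 1), "at least 2")
  expect_error(resampleEpochs(tensor, 500), "upsample")
})

test_that("feature matrices have regime-consistent shape and ordering", {
  d <- smallDataset()  # 60 x 4 x 20
  times <- epochTimes(d$tensor)
  entire <- buildFeatures(d$tensor, regimeSpec("entire"))
  expect_equal(dim(featureValues(entire)), c(60, 4 * 20))
  # channel-major: channel varies slowest in the column index
  expect_equal(entire@featureIndex$channel,
               rep(channelNames(d$tensor), each = 20))
  # column content matches the tensor directly
  expect_equal(featureValues(entire)[, 20 + 3],
               epochData(d$tensor)[, 2, 3])

  samp <- buildFeatures(d$tensor, regimeSpec("samples", tMs = 0))
  expect_equal(ncol(featureValues(samp)), 4)

  spat <- buildFeatures(d$tensor,
                        regimeSpec("spatial", channel = "ch2"))
  expect_equal(ncol(featureValues(spat)), 20)
  expect_equal(featureValues(spat)[, 5], epochData(d$tensor)[, 2, 5])

  expect_error(buildFeatures(d$tensor, regimeSpec("samples", tMs = 900)),
               "outside the epoch")
  expect_error(buildFeatures(d$tensor,
                             regimeSpec("spatial", channel = "nope")),
               "unknown channel")
})

test_that("the interval ending at the last sample equals the entire epoch", {
  d <- smallDataset()
  times <- epochTimes(d$tensor)
  entire <- featureValues(buildFeatures(d$tensor, regimeSpec("entire")))
  iv <- featureValues(buildFeatures(d$tensor,
                                    regimeSpec("intervals",
                                               tMs = max(times))))
  expect_identical(iv, entire)
})

test_that("the four segments exactly partition the epoch's columns", {
  d <- smallDataset()
  times <- epochTimes(d$tensor)
  idx <- lapply(c("baseline", "early", "middle", "late"), function(seg)
    buildFeatures(d$tensor,
                  regimeSpec("segments", segment = seg, t1Ms = 60,
                             t2Ms = 350))@featureIndex)
  combined <- do.call(rbind, idx)
  entireIdx <- buildFeatures(d$tensor, regimeSpec("entire"))@featureIndex
  key <- function(df) sort(paste(df$channel, df$time_ms))
  expect_identical(key(combined), key(entireIdx))     # no gap
  expect_equal(nrow(combined), nrow(entireIdx))       # no overlap
  # boundaries belong to the later segment
  early <- idx[[2]]; middle <- idx[[3]]
  tBoundary <- times[nearestSampleAfter <- which(times >= 60)[1]]
  expect_true(tBoundary %in% middle$time_ms || tBoundary >= 350)
  expect_false(60 %in% early$time_ms && 60 %in% middle$time_ms)
  expect_error(buildFeatures(d$tensor,
                             regimeSpec("segments", segment = "middle",
                                        t1Ms = 60, t2Ms = 60.0001)),
               "no samples")
})

test_that("identity bypass relabels channels as components", {
  d <- smallDataset()
  comp <- extractComponents(d$tensor, method = "identity")
  expect_identical(comp@kind, "component")
  expect_equal(epochData(comp), epochData(d$tensor))
  expect_error(extractComponents(comp), "sensor-space")
})

test_that("fixed-point ICA unmixes a seeded two-source mixture", {
  n <- 4000
  src <- withr::with_seed(6, cbind(runif(n, -1, 1), rexp(n) - 1))
  A <- matrix(c(0.8, 0.3, -0.4, 0.9), 2, 2)
  X <- src %*% t(A)                      # n x 2 mixed channels
  arr <- array(0, c(1, 2, n)); arr[1, , ] <- t(X)
  tensor <- epochTensor(arr, seq_len(n), stimuli = 0L)
  comp <- extractComponents(tensor, nComponents = 2, seed = 3)
  S <- epochData(comp)[1, , ]
  cors <- abs(cor(t(S), src))
  # each source is recovered by some component up to sign/permutation
  expect_gt(max(cors[, 1]), 0.95)
  expect_gt(max(cors[, 2]), 0.95)
})
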
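# Power curves, segment-boundary detection, segment statistics, and the
# spatial map.

mkCurve <- function(times, r2, measure = "shannon") {
  new("PowerCurve", timesMs = times, r2 = r2, regime = "samples",
      measure = measure)
}

test_that("boundary detection matches the 10-percent / minimum definitions", {
  times <- seq(-200, 600, by = 10)
  # zero before 60 ms, rising to a 0.2 peak at 200 ms, dipping to 0.01 at
  # 350 ms, second bump at 450 ms
  r2 <- numeric(length(times))
  r2[times >= 60 & times <= 200] <-
    seq(0.02, 0.2, length.out = sum(times >= 60 & times <= 200))
  r2[times > 200 & times <= 350] <-
    seq(0.19, 0.01, length.out = sum(times > 200 & times <= 350))
  r2[times > 350 & times <= 450] <-
    seq(0.02, 0.1, length.out = sum(times > 350 & times <= 450))
  b <- detectSegments(mkCurve(times, r2))
  expect_equal(b@t1Ms, 60)
  expect_equal(b@t2Ms, 350)
  expect_identical(b@provenance, "detected")
})

test_that("a flat positive curve yields the earliest admissible boundaries", {
  times <- seq(-200, 600, by = 10)
  b <- detectSegments(mkCurve(times, rep(0.1, length(times))))
  expect_equal(b@t1Ms, times[times > 0][1])  # first post-stimulus sample
  expect_equal(b@t2Ms, 250)                  # earliest tie of the minimum
})

test_that("boundary detection refuses curves without a response", {
  times <- seq(-200, 600, by = 10)
  expect_error(detectSegments(mkCurve(times, numeric(length(times)))),
               "no detectable response")
  iv <- new("PowerCurve", timesMs = times, r2 = rep(0.1, length(times)),
            regime = "intervals", measure = "shannon")
  expect_error(detectSegments(iv), "samples-regime")
  short <- mkCurve(seq(-200, 300, by = 10), rep(0.1, 51))
  expect_error(detectSegments(short), "\\[0, 400\\]")
})

test_that("Bonferroni thresholds equal alpha over the family size", {
  expect_equal(round(bonferroniThreshold(0.05, 3), 4), 0.0167)
  expect_equal(round(bonferroniThreshold(0.05, 12), 4), 0.0042)
  for (m in c(1, 2, 5, 20)) expect_equal(bonferroniThreshold(0.05, m), 0.05 / m)
  expect_error(bonferroniThreshold(0.05, 0), ">= 1")
})

test_that("repeated-measures comparison distinguishes real segment effects", {
  set.seed(10)
  n <- 12
  tab <- cbind(early = rnorm(n, 0.00, 0.01),
               middle = rnorm(n, 0.15, 0.03),
               late = rnorm(n, 0.04, 0.02))
  out <- compareSegments(tab)
  expect_gt(out$anova$F, 10)
  expect_lt(out$anova$p, 0.001)
  cmp <- out$posthoc@comparisons
  expect_equal(cmp$threshold, rep(0.05 / 3, 3))
  expect_true(cmp$significant[cmp$label == "early vs middle"])
})

test_that("identical decoding powers give a null comparison, not an error", {
  tab <- matrix(0.1, nrow = 5, ncol = 3,
                dimnames = list(NULL, c("early", "middle", "late")))
  out <- compareSegments(tab)
  expect_equal(out$anova$p, 1)
  expect_false(any(out$posthoc@comparisons$significant))
  expect_error(compareSegments(tab[1, , drop = FALSE]), "2 replicates")
  tab[2, 2] <- NA
  expect_error(compareSegments(tab), "balanced")
})

test_that("chance comparison uses the family-of-12 threshold by default", {
  set.seed(11)
  obs <- cbind(baseline = rnorm(10, 0, 0.01), middle = rnorm(10, 0.2, 0.03))
  ch <- matrix(rnorm(20, 0, 0.01), 10, 2,
               dimnames = list(NULL, colnames(obs)))
  rep <- compareToChance(obs, ch)
  expect_equal(rep@comparisons$threshold, rep(0.05 / 12, 2))
  expect_true(rep@comparisons$significant[2])
  expect_false(rep@comparisons$significant[1])
  expect_error(compareToChance(obs, ch[, 1, drop = FALSE]), "matching")
})

test_that("segment powers pair every segment with its chance distribution", {
  d <- smallDataset()
  b <- segmentBoundaries(150, 380)
  sp <- segmentPowers(d$tensor, d$seq, "shannon", b, w = 16,
                      nPermutations = 5, seed = 3,
                      segments = c("baseline", "middle"))
  expect_named(sp, c("baseline", "middle"))
  expect_s4_class(sp$middle$result, "DecodingResult")
  expect_s4_class(sp$middle$chance, "ChanceDistribution")
  # the encoding sits at 250 +/- 50 ms: middle beats baseline clearly
  expect_gt(decodingPower(sp$middle$result),
            decodingPower(sp$baseline$result))
  expect_lte(sp$middle$p, 1 / 6)
})

test_that("the samples curve peaks inside the encoding window", {
  d <- smallDataset(seed = 21)
  curve <- samplesCurve(d$tensor, d$seq, "shannon", wGrid = 16, seed = 2)
  peak <- curve@timesMs[which.max(curve@r2)]
  expect_gte(peak, 150); expect_lte(peak, 350)
})

test_that("the intervals curve ends at the entire-epoch decoding power", {
  d <- smallDataset()
  curve <- intervalsCurve(d$tensor, d$seq, "shannon", wGrid = 16, seed = 2)
  times <- epochTimes(d$tensor)
  entire <- fitDecode(buildFeatures(d$tensor, regimeSpec("entire")),
                      surpriseSeries(d$seq, "shannon", 16),
                      seed = surpriseDecoder:::childSeed(2, length(times)))
  expect_equal(curve@r2[length(times)], decodingPower(entire),
               tolerance = 1e-12)
})

test_that("spatial maps localize concentrated loadings and demand replicates", {
  loadings <- c(0.05, 0.05, 2, 2, 0.05, 0.05)
  seq <- generateOddball(60, 1 / 3, seed = 41)
  tensor <- simulateEpochs(seq, smallSpec(nTrials = 60, nChannels = 6,
                                          loadings = loadings))
  sm <- spatialMap(tensor, seq, measures = "shannon", w = 16, seed = 5,
                   tests = FALSE)
  expect_equal(nrow(sm$table), 6)
  top2 <- sm$table$channel[order(sm$table$r2, decreasing = TRUE)][1:2]
  expect_setequal(top2, c("ch3", "ch4"))
  expect_null(sm$tests)
  expect_error(spatialMap(tensor, seq,
                          measures = c("shannon", "bayesian"), tests = TRUE),
               "two replicates")
})

test_that("pairwise measure tests run across replicates", {
  reps <- lapply(1:3, function(r) {
    seq <- generateOddball(60, 1 / 3, seed = 50 + r)
    list(seq = seq,
         tensor = simulateEpochs(seq, smallSpec(nTrials = 60, nChannels = 2,
                                                noiseSeed = 60 + r)))
  })
  sm <- spatialMap(lapply(reps, `[[`, "tensor"), lapply(reps, `[[`, "seq"),
                   measures = c("shannon", "bayesian"), w = 16, seed = 5)
  expect_equal(nrow(sm$table), 3 * 2 * 2)
  expect_s4_class(sm$tests, "StatsReport")
  expect_equal(nrow(sm$tests@comparisons), 2)  # one pair per channel
})
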
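# Temporal decoding-power curves, segment-boundary detection, segmentwise
# and spatial decoding, and the accompanying statistics.

powerCurve <- function(tensor, seq, measure, regime, wGrid, nFolds, seed,
                       nLambda) {
  times <- epochTimes(tensor)
  labelSets <- lapply(wGrid, function(w) surpriseSeries(seq, measure, w))
  r2 <- vapply(seq_along(times), function(i) {
    spec <- regimeSpec(regime, tMs = times[i])
    X <- buildFeatures(tensor, spec)
    max(vapply(labelSets, function(y)
      decodingPower(fitDecode(X, y, nFolds = nFolds,
                              seed = childSeed(seed, i),
                              nLambda = nLambda)), numeric(1)))
  }, numeric(1))
  new("PowerCurve", timesMs = times, r2 = r2, regime = regime,
      measure = measure)
}

#' Decoding-power curve over single samples
#'
#' For every sample time, decodes the surprise series from the channels'
#' values at that single sample and reports the maximum decoding power
#' across the w grid.
#'
#' @param tensor an [EpochTensor-class].
#' @param seq the matching [StimulusSequence-class].
#' @param measure surprise measure.
#' @param wGrid integration coefficients swept per time point.
#' @param nFolds,seed,nLambda passed to [fitDecode()].
#' @return A [PowerCurve-class] with regime "samples".
#' @export
samplesCurve <- function(tensor, seq, measure, wGrid = 16, nFolds = 5L,
                         seed = 1L, nLambda = 20L) {
  powerCurve(tensor, seq, measure, "samples", wGrid, nFolds, seed, nLambda)
}

#' Decoding-power curve over growing intervals
#'
#' Like [samplesCurve()] but the features at target time t are all samples
#' from the epoch start through t (all channels); at the final sample the
#' features coincide with the entire-epoch regime.
#'
#' @inheritParams samplesCurve
#' @return A [PowerCurve-class] with regime "intervals".
#' @export
intervalsCurve <- function(tensor, seq, measure, wGrid = 16, nFolds = 5L,
                           seed = 1L, nLambda = 20L) {
  powerCurve(tensor, seq, measure, "intervals", wGrid, nFolds, seed, nLambda)
}

#' Detect the early/middle and middle/late segment boundaries
#'
#' From a samples-regime decoding-power curve: t1 is the earliest
#' post-stimulus time whose power reaches 10 percent of the post-stimulus
#' maximum; t2 is the time of minimum power within [250, 400] ms (earliest
#' on ties), separating the middle and late response.
#'
#' @param curve a samples-regime [PowerCurve-class] covering [0, 400] ms.
#' @return A [SegmentBoundaries-class] with provenance "detected".
#' @export
detectSegments <- function(curve) {
  stopifnot(is(curve, "PowerCurve"))
  if (curve@regime != "samples")
    stop("boundary detection expects a samples-regime curve")
  times <- curve@timesMs
  post <- times > 0
  if (!any(post) || max(times) < 400 - 1e-9)
    stop("curve must cover the post-stimulus range [0, 400] ms")
  peak <- max(curve@r2[post])
  if (peak <= 0)
    stop("no detectable response: post-stimulus decoding power is not positive")
  reach <- post & curve@r2 >= 0.10 * peak - 1e-12
  if (!any(reach)) stop("no post-stimulus point reaches the threshold")
  t1 <- times[which(reach)[1]]
  win <- which(times >= 250 - 1e-9 & times <= 400 + 1e-9)
  t2 <- times[win[which.min(curve@r2[win])]]  # which.min: earliest tie
  if (t2 <= t1)
    stop("detected boundaries are not ordered (t1 = ", t1, ", t2 = ", t2, ")")
  new("SegmentBoundaries", t1Ms = t1, t2Ms = t2, measure = curve@measure,
      provenance = "detected")
}

#' Decode each temporal segment with its permutation chance level
#'
#' Builds the baseline/early/middle/late feature matrices from the
#' boundaries, decodes each, and pairs every observed decoding power with
#' its permutation chance distribution.
#'
#' @param tensor an [EpochTensor-class].
#' @param seq the matching [StimulusSequence-class].
#' @param measure surprise measure.
#' @param boundaries a [SegmentBoundaries-class].
#' @param w integration coefficient for the labels.
#' @param nPermutations permutations per segment.
#' @param nFolds,seed,nLambda passed to [fitDecode()].
#' @param segments which segments to decode.
#' @return Named list per segment, each with elements `result`
#'   ([DecodingResult-class]), `chance` ([ChanceDistribution-class]) and
#'   `p` (empirical p-value).
#' @export
segmentPowers <- function(tensor, seq, measure, boundaries, w = 16,
                          nPermutations = 100L, nFolds = 5L, seed = 1L,
                          nLambda = 20L,
                          segments = c("baseline", "early", "middle",
                                       "late")) {
  stopifnot(is(boundaries, "SegmentBoundaries"))
  y <- surpriseSeries(seq, measure, w)
  out <- lapply(segments, function(seg) {
    spec <- regimeSpec("segments", segment = seg,
                       t1Ms = boundaries@t1Ms, t2Ms = boundaries@t2Ms)
    X <- buildFeatures(tensor, spec)
    res <- fitDecode(X, y, nFolds = nFolds, seed = seed, nLambda = nLambda)
    ch <- chanceLevel(X, y, nPermutations = nPermutations, nFolds = nFolds,
                      seed = seed, nLambda = nLambda)
    list(result = res, chance = ch, p = empiricalP(ch, decodingPower(res)))
  })
  names(out) <- segments
  out
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha uncorrected level (default 0.05).
#' @param familySize number of tests in the family.
#' @return alpha / familySize.
#' @examples
#' bonferroniThreshold(0.05, 3)    # 0.0167
#' bonferroniThreshold(0.05, 12)   # 0.0042
#' @export
bonferroniThreshold <- function(alpha = 0.05, familySize) {
  if (familySize < 1) stop("familySize must be >= 1")
  alpha / familySize
}

statsReport <- function(labels, statistics, ps, familySize, alpha = 0.05) {
  thr <- bonferroniThreshold(alpha, familySize)
  new("StatsReport",
      comparisons = data.frame(label = labels, statistic = statistics,
                               p = ps, threshold = thr,
                               significant = ps < thr,
                               stringsAsFactors = FALSE),
      correction = "bonferroni", familySize = as.integer(familySize),
      alpha = alpha)
}

safePairedT <- function(x, y) {
  out <- tryCatch({
    tt <- t.test(x, y, paired = TRUE)
    c(statistic = unname(tt$statistic), p = tt$p.value)
  }, error = function(e) c(statistic = 0, p = 1))  # constant differences
  if (!all(is.finite(out))) out <- c(statistic = 0, p = 1)
  out
}

#' Compare segment decoding powers across replicates
#'
#' One-way repeated-measures ANOVA of decoding power across segments
#' (replicates as subjects), followed by paired t-tests for every segment
#' pair, with Bonferroni-corrected thresholds.
#'
#' @param r2Table numeric matrix, replicates x segments (>= 2 replicates,
#'   >= 2 segments, balanced by construction).
#' @param alpha uncorrected significance level.
#' @param familySize family size of the post-hoc tests (default: number of
#'   segment pairs).
#' @return A list with `anova` (data.frame: F, p) and `posthoc`
#'   (a [StatsReport-class]).
#' @export
compareSegments <- function(r2Table, alpha = 0.05, familySize = NULL) {
  r2Table <- as.matrix(r2Table)
  if (nrow(r2Table) < 2) stop("need at least 2 replicates (subjects)")
  if (ncol(r2Table) < 2) stop("need at least 2 segments")
  if (any(!is.finite(r2Table))) stop("r2 table must be complete (balanced)")
  segs <- colnames(r2Table)
  if (is.null(segs)) segs <- paste0("segment", seq_len(ncol(r2Table)))
  if (max(abs(r2Table - rowMeans(r2Table))) < 1e-12) {
    # no segment effect at all: F is 0/0 numerical noise in aov
    Fval <- 0; pval <- 1
  } else {
    long <- data.frame(
      r2 = as.vector(r2Table),
      segment = factor(rep(segs, each = nrow(r2Table)), levels = segs),
      subject = factor(rep(seq_len(nrow(r2Table)), ncol(r2Table))))
    fit <- aov(r2 ~ segment + Error(subject / segment), data = long)
    tab <- summary(fit)[["Error: subject:segment"]][[1]]
    Fval <- tab["segment", "F value"]
    pval <- tab["segment", "Pr(>F)"]
    if (!is.finite(Fval)) { Fval <- 0; pval <- 1 }
  }
  pairs <- combn(segs, 2, simplify = FALSE)
  ph <- t(vapply(pairs, function(pr)
    safePairedT(r2Table[, pr[1]], r2Table[, pr[2]]), numeric(2)))
  if (is.null(familySize)) familySize <- length(pairs)
  list(anova = data.frame(F = Fval, p = pval),
       posthoc = statsReport(
         labels = vapply(pairs, paste, character(1), collapse = " vs "),
         statistics = ph[, "statistic"], ps = ph[, "p"],
         familySize = familySize, alpha = alpha))
}

#' Paired comparison of decoding powers against their chance levels
#'
#' For every condition (column), a paired t-test of the observed decoding
#' powers against the matched chance levels across replicates, with a
#' Bonferroni threshold over the full test family (default 12: three
#' surprise measures times four temporal conditions).
#'
#' @param observed replicates x conditions matrix of decoding powers.
#' @param chance matching matrix of chance levels (e.g. per-replicate
#'   permutation means).
#' @param familySize number of tests in the corrected family.
#' @param alpha uncorrected significance level.
#' @return A [StatsReport-class].
#' @export
compareToChance <- function(observed, chance, familySize = 12L,
                            alpha = 0.05) {
  observed <- as.matrix(observed); chance <- as.matrix(chance)
  if (!all(dim(observed) == dim(chance)))
    stop("observed and chance must have matching dimensions")
  if (nrow(observed) < 2) stop("need at least 2 replicates")
  conds <- colnames(observed)
  if (is.null(conds)) conds <- paste0("condition", seq_len(ncol(observed)))
  res <- t(vapply(seq_len(ncol(observed)), function(j)
    safePairedT(observed[, j], chance[, j]), numeric(2)))
  statsReport(labels = paste(conds, "vs chance"),
              statistics = res[, "statistic"], ps = res[, "p"],
              familySize = familySize, alpha = alpha)
}

#' Per-channel spatial decoding map
#'
#' Decodes each channel's (optionally segment-restricted) time course
#' separately for every surprise measure and, with multiple replicates,
#' compares measure pairs per channel with paired t-tests across
#' replicates.
#'
#' @param tensors an [EpochTensor-class] (kind "sensor") or list of them
#'   (replicates).
#' @param seqs a [StimulusSequence-class] or list matching `tensors`.
#' @param measures surprise measures to decode.
#' @param w integration coefficient for the labels.
#' @param boundaries optional [SegmentBoundaries-class] with `segment` to
#'   restrict the time window.
#' @param segment optional segment name ("baseline"/"early"/"middle"/"late").
#' @param nFolds,seed,nLambda passed to [fitDecode()].
#' @param tests run the pairwise measure comparisons (needs >= 2
#'   replicates and >= 2 measures).
#' @return A list with `table` (data.frame: replicate, channel, measure,
#'   r2) and `tests` (a [StatsReport-class], or NULL when not requested).
#' @export
spatialMap <- function(tensors, seqs,
                       measures = c("shannon", "bayesian",
                                    "confidence_corrected"),
                       w = 16, boundaries = NULL, segment = NA_character_,
                       nFolds = 5L, seed = 1L, nLambda = 20L,
                       tests = length(measures) > 1) {
  if (is(tensors, "EpochTensor")) tensors <- list(tensors)
  if (is(seqs, "StimulusSequence")) seqs <- list(seqs)
  if (length(seqs) == 1L) seqs <- rep(seqs, length(tensors))
  stopifnot(length(seqs) == length(tensors))
  for (tn in tensors)
    if (tn@kind != "sensor")
      stop("spatial analysis expects sensor-space tensors")
  if (tests && length(tensors) < 2)
    stop("pairwise measure tests need at least two replicates; ",
         "rerun with tests = FALSE for a single dataset")
  if (!is.na(segment) && is.null(boundaries))
    stop("a segment restriction needs boundaries")

  chans <- channelNames(tensors[[1]])
  rows <- list()
  for (r in seq_along(tensors)) {
    tensor <- tensors[[r]]
    labels <- lapply(measures, function(m)
      surpriseSeries(seqs[[r]], m, w))
    for (ci in seq_along(chans)) {
      spec <- if (is.na(segment))
        regimeSpec("spatial", channel = chans[ci])
      else regimeSpec("spatial", channel = chans[ci], segment = segment,
                      t1Ms = boundaries@t1Ms, t2Ms = boundaries@t2Ms)
      X <- buildFeatures(tensor, spec)
      for (mi in seq_along(measures)) {
        res <- fitDecode(X, labels[[mi]], nFolds = nFolds,
                         seed = childSeed(seed, r * 1000 + ci),
                         nLambda = nLambda)
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = r, channel = chans[ci], measure = measures[mi],
          r2 = decodingPower(res), stringsAsFactors = FALSE)
      }
    }
  }
  table <- do.call(rbind, rows)

  testReport <- NULL
  if (tests) {
    pairs <- combn(measures, 2, simplify = FALSE)
    labs <- character(); stat <- numeric(); ps <- numeric()
    for (ch in chans) {
      for (pr in pairs) {
        a <- table$r2[table$channel == ch & table$measure == pr[1]]
        b <- table$r2[table$channel == ch & table$measure == pr[2]]
        tt <- safePairedT(a, b)
        labs <- c(labs, paste0(ch, ": ", pr[1], " vs ", pr[2]))
        stat <- c(stat, tt["statistic"]); ps <- c(ps, tt["p"])
      }
    }
    testReport <- statsReport(labs, stat, ps, familySize = length(labs))
  }
  list(table = table, tests = testReport)
}
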
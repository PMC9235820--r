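#' @import methods
#' @importFrom stats rnorm runif rbinom sd var t.test aov predict quantile
#' @importFrom utils combn write.csv read.csv
NULL

#' StimulusSequence: a binary oddball stimulus stream
#'
#' Ordered binary trial labels for one oddball block, with 0 coding the
#' frequent (standard) stimulus and 1 the rare (deviant) one, together with
#' the generating deviant probability and the seed used to draw the labels
#' (both may be NA for imported sequences).
#'
#' @slot labels integer vector of 0/1 trial codes.
#' @slot pDeviant probability of a deviant on each trial (NA if unknown).
#' @slot seed integer seed used by [generateOddball()] (NA if not generated).
#' @seealso [generateOddball()], [surpriseSeries()]
#' @export
setClass("StimulusSequence",
  representation(labels = "integer", pDeviant = "numeric", seed = "integer"),
  prototype(labels = integer(), pDeviant = NA_real_, seed = NA_integer_))

setValidity("StimulusSequence", function(object) {
  msg <- character()
  if (length(object@labels) < 1L)
    msg <- c(msg, "sequence must contain at least one trial")
  if (length(object@labels) && !all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must all be 0 (standard) or 1 (deviant)")
  p <- object@pDeviant
  if (!is.na(p) && (p < 0 || p > 1))
    msg <- c(msg, "pDeviant must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a StimulusSequence from existing labels
#'
#' @param labels numeric or integer vector of 0/1 codes.
#' @param pDeviant generating deviant probability, if known.
#' @param seed generating seed, if any.
#' @return A [StimulusSequence-class] object.
#' @examples
#' stimulusSequence(c(0, 0, 1, 0))
#' @export
stimulusSequence <- function(labels, pDeviant = NA_real_, seed = NA_integer_) {
  new("StimulusSequence", labels = as.integer(labels),
      pDeviant = as.numeric(pDeviant), seed = as.integer(seed))
}

#' @describeIn StimulusSequence-class number of trials
#' @param x a StimulusSequence
#' @export
setMethod("length", "StimulusSequence", function(x) length(x@labels))

#' Trial labels of a stimulus sequence or epoch tensor
#'
#' @param x a [StimulusSequence-class] or [EpochTensor-class].
#' @return Integer vector of 0/1 codes, one per trial.
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))

#' @rdname trialLabels
#' @export
setMethod("trialLabels", "StimulusSequence", function(x) x@labels)

setMethod("show", "StimulusSequence", function(object) {
  n <- length(object@labels)
  cat("StimulusSequence with", n, "trials;",
      sum(object@labels == 1L), "deviants")
  if (!is.na(object@pDeviant)) cat(" (p_deviant =", object@pDeviant, ")")
  cat("\n")
})

#' TransitionCounts: leaky transition tallies of the ideal observer
#'
#' The four exponentially weighted counts n_{a|b} of transitions from
#' stimulus type b to type a, with integration coefficient w (the e-folding
#' memory scale, in trials). With w -> Inf the counts equal plain integer
#' transition tallies.
#'
#' @slot n0g0,n1g0,n0g1,n1g1 nonnegative leaky counts n_{a|b}.
#' @slot w positive integration coefficient.
#' @slot trialIndex index of the last trial folded into the counts.
#' @seealso [updateCounts()], [beliefTrajectory()]
#' @export
setClass("TransitionCounts",
  representation(n0g0 = "numeric", n1g0 = "numeric", n0g1 = "numeric",
                 n1g1 = "numeric", w = "numeric", trialIndex = "integer"),
  prototype(n0g0 = 0, n1g0 = 0, n0g1 = 0, n1g1 = 0, w = Inf,
            trialIndex = 1L))

setValidity("TransitionCounts", function(object) {
  cts <- c(object@n0g0, object@n1g0, object@n0g1, object@n1g1)
  if (any(cts < 0)) return("all transition counts must be nonnegative")
  if (object@w <= 0) return("integration coefficient w must be positive")
  TRUE
})

#' Construct an empty TransitionCounts
#' @param w positive integration coefficient (trials); Inf = no forgetting.
#' @return A [TransitionCounts-class] with all counts zero.
#' @export
transitionCounts <- function(w = Inf) {
  new("TransitionCounts", w = as.numeric(w))
}

setMethod("show", "TransitionCounts", function(object) {
  cat(sprintf(
    "TransitionCounts (w = %g, trial %d): n0|0=%.4g n1|0=%.4g n0|1=%.4g n1|1=%.4g\n",
    object@w, object@trialIndex, object@n0g0, object@n1g0, object@n0g1,
    object@n1g1))
})

#' BeliefState: the factorized Beta belief over transition probabilities
#'
#' The observer's belief about the two free transition probabilities
#' theta_{0|1} and theta_{1|0} factorizes into two independent Beta
#' distributions: Beta(1 + n_{0|1}, 1 + n_{1|1}) for theta_{0|1} and
#' Beta(1 + n_{1|0}, 1 + n_{0|0}) for theta_{1|0}.
#'
#' @slot given1 length-2 numeric (alpha, beta) of the theta_{0|1} factor.
#' @slot given0 length-2 numeric (alpha, beta) of the theta_{1|0} factor.
#' @export
setClass("BeliefState",
  representation(given1 = "numeric", given0 = "numeric"),
  prototype(given1 = c(1, 1), given0 = c(1, 1)))

setValidity("BeliefState", function(object) {
  if (length(object@given1) != 2L || length(object@given0) != 2L)
    return("each Beta factor needs exactly (alpha, beta)")
  if (any(c(object@given1, object@given0) <= 0))
    return("Beta parameters must be positive")
  TRUE
})

#' Construct a BeliefState
#' @param given1 numeric (alpha, beta) of the Beta factor for theta_{0|1}.
#' @param given0 numeric (alpha, beta) of the Beta factor for theta_{1|0}.
#' @return A [BeliefState-class].
#' @export
beliefState <- function(given1 = c(1, 1), given0 = c(1, 1)) {
  new("BeliefState", given1 = as.numeric(given1), given0 = as.numeric(given0))
}

setMethod("show", "BeliefState", function(object) {
  cat(sprintf("BeliefState: theta0|1 ~ Beta(%.4g, %.4g), theta1|0 ~ Beta(%.4g, %.4g)\n",
              object@given1[1], object@given1[2],
              object@given0[1], object@given0[2]))
})

#' BeliefTrajectory: per-trial prior and posterior beliefs
#'
#' Prior and posterior Beta parameters for each trial of a stimulus
#' sequence, under leaky integration with coefficient w. Rows are trials;
#' columns are (alphaGiven1, betaGiven1, alphaGiven0, betaGiven0). The
#' prior at trial t is the posterior after trial t - 1; the prior at trial
#' 1 is the uniform belief Beta(1,1) x Beta(1,1).
#'
#' @slot prior,posterior T x 4 parameter matrices.
#' @slot w integration coefficient.
#' @slot labels the 0/1 sequence the trajectory was computed from.
#' @seealso [beliefTrajectory()], [beliefAt()]
#' @export
setClass("BeliefTrajectory",
  representation(prior = "matrix", posterior = "matrix", w = "numeric",
                 labels = "integer"))

setValidity("BeliefTrajectory", function(object) {
  T <- length(object@labels)
  if (nrow(object@prior) != T || nrow(object@posterior) != T)
    return("prior/posterior must have one row per trial")
  if (ncol(object@prior) != 4L || ncol(object@posterior) != 4L)
    return("parameter matrices must have 4 columns")
  if (any(object@prior < 1) || any(object@posterior < 1))
    return("Beta parameters must be >= 1 for nonnegative counts")
  TRUE
})

setMethod("length", "BeliefTrajectory", function(x) length(x@labels))

setMethod("show", "BeliefTrajectory", function(object) {
  cat("BeliefTrajectory over", length(object@labels), "trials (w =",
      object@w, ")\n")
})

#' SurpriseSeries: one per-trial surprise measure
#'
#' @slot values numeric surprise per trial (nats unless logBase = "2").
#' @slot measure one of "shannon", "bayesian", "confidence_corrected".
#' @slot w integration coefficient the series was computed at.
#' @slot logBase "e" (nats) or "2" (bits).
#' @seealso [surpriseSeries()]
#' @export
setClass("SurpriseSeries",
  representation(values = "numeric", measure = "character", w = "numeric",
                 logBase = "character"),
  prototype(measure = "shannon", w = Inf, logBase = "e"))

setValidity("SurpriseSeries", function(object) {
  if (!object@measure %in% c("shannon", "bayesian", "confidence_corrected"))
    return("unknown surprise measure")
  if (!object@logBase %in% c("e", "2")) return("logBase must be 'e' or '2'")
  if (any(!is.finite(object@values))) return("surprise values must be finite")
  if (any(object@values < -1e-12)) return("surprise values must be nonnegative")
  TRUE
})

setMethod("length", "SurpriseSeries", function(x) length(x@values))

#' Numeric values of a surprise series
#' @param x a [SurpriseSeries-class].
#' @return numeric vector, one value per trial.
#' @export
setGeneric("surpriseValues", function(x) standardGeneric("surpriseValues"))

#' @rdname surpriseValues
#' @export
setMethod("surpriseValues", "SurpriseSeries", function(x) x@values)

setMethod("show", "SurpriseSeries", function(object) {
  cat(sprintf("SurpriseSeries '%s' (w = %g, base %s): %d trials, mean %.4f\n",
              object@measure, object@w, object@logBase,
              length(object@values), mean(object@values)))
})

#' EpochTensor: epoched sensor or component data
#'
#' A trials x channels x timepoints array with a millisecond time axis and
#' the per-trial 0/1 stimulus labels, the container all feature matrices
#' are built from.
#'
#' @slot data numeric array, trials x channels x timepoints.
#' @slot timesMs strictly increasing sample times in ms.
#' @slot channelNames one identifier per channel/component.
#' @slot stimuli integer 0/1 label per trial.
#' @slot kind "sensor" or "component".
#' @seealso [simulateEpochs()], [readEpochs()], [buildFeatures()]
#' @export
setClass("EpochTensor",
  representation(data = "array", timesMs = "numeric",
                 channelNames = "character", stimuli = "integer",
                 kind = "character"),
  prototype(kind = "sensor"))

setValidity("EpochTensor", function(object) {
  d <- dim(object@data)
  msg <- character()
  if (length(d) != 3L) msg <- c(msg, "data must be a 3-D array")
  else {
    if (any(d < 1L)) msg <- c(msg, "all tensor dimensions must be >= 1")
    if (length(object@timesMs) != d[3])
      msg <- c(msg, "timesMs length must match the time dimension")
    if (length(object@channelNames) != d[2])
      msg <- c(msg, "channelNames length must match the channel dimension")
    if (length(object@stimuli) != d[1])
      msg <- c(msg, "stimuli length must match the trial dimension")
  }
  if (length(object@timesMs) > 1 && any(diff(object@timesMs) <= 0))
    msg <- c(msg, "timesMs must be strictly increasing")
  if (any(!is.finite(object@data)))
    msg <- c(msg, "data must contain no missing or infinite values")
  if (!object@kind %in% c("sensor", "component"))
    msg <- c(msg, "kind must be 'sensor' or 'component'")
  if (length(object@stimuli) && !all(object@stimuli %in% c(0L, 1L)))
    msg <- c(msg, "stimuli must be 0/1")
  if (length(msg)) msg else TRUE
})

#' Construct an EpochTensor
#'
#' @param data trials x channels x timepoints numeric array.
#' @param timesMs sample times in ms.
#' @param channelNames channel identifiers (default "ch1", ...).
#' @param stimuli per-trial 0/1 labels.
#' @param kind "sensor" (default) or "component".
#' @return An [EpochTensor-class].
#' @export
epochTensor <- function(data, timesMs, channelNames = NULL, stimuli,
                        kind = "sensor") {
  if (is.null(channelNames))
    channelNames <- paste0("ch", seq_len(dim(data)[2]))
  new("EpochTensor", data = data, timesMs = as.numeric(timesMs),
      channelNames = as.character(channelNames),
      stimuli = as.integer(stimuli), kind = kind)
}

#' @describeIn EpochTensor-class trials x channels x timepoints dimensions
#' @param x an EpochTensor
#' @export
setMethod("dim", "EpochTensor", function(x) dim(x@data))

#' Epoch data array
#' @param x an [EpochTensor-class].
#' @return the trials x channels x timepoints array.
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' @rdname epochData
#' @export
setMethod("epochData", "EpochTensor", function(x) x@data)

#' Epoch time axis in milliseconds
#' @param x an [EpochTensor-class].
#' @return numeric vector of sample times.
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))

#' @rdname epochTimes
#' @export
setMethod("epochTimes", "EpochTensor", function(x) x@timesMs)

#' Channel or component names
#' @param x an [EpochTensor-class].
#' @return character vector of identifiers.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname channelNames
#' @export
setMethod("channelNames", "EpochTensor", function(x) x@channelNames)

#' @rdname trialLabels
#' @export
setMethod("trialLabels", "EpochTensor", function(x) x@stimuli)

setMethod("show", "EpochTensor", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochTensor (%s): %d trials x %d channels x %d samples, [%g, %g] ms\n",
              object@kind, d[1], d[2], d[3],
              min(object@timesMs), max(object@timesMs)))
})

#' RegimeSpec: a temporal/spatial feature-selection regime
#'
#' Describes which part of the epoch feeds the decoder: the entire epoch,
#' the single sample nearest a target time, the growing interval from epoch
#' start to a target time, one of the four data-driven segments (baseline,
#' early, middle, late, bounded by t1 and t2), or a single channel's time
#' course for spatial analysis.
#'
#' @slot regime one of "entire", "samples", "intervals", "segments", "spatial".
#' @slot tMs target time (samples/intervals regimes).
#' @slot segment segment name (segments regime, or optional restriction of
#'   the spatial regime).
#' @slot t1Ms,t2Ms segment boundaries in ms.
#' @slot channel channel identifier (spatial regime).
#' @seealso [regimeSpec()], [buildFeatures()]
#' @export
setClass("RegimeSpec",
  representation(regime = "character", tMs = "numeric", segment = "character",
                 t1Ms = "numeric", t2Ms = "numeric", channel = "character"),
  prototype(tMs = NA_real_, segment = NA_character_, t1Ms = NA_real_,
            t2Ms = NA_real_, channel = NA_character_))

setValidity("RegimeSpec", function(object) {
  if (!object@regime %in% c("entire", "samples", "intervals", "segments",
                            "spatial"))
    return("unknown regime")
  if (object@regime %in% c("samples", "intervals") && is.na(object@tMs))
    return("samples/intervals regimes need a target time tMs")
  if (object@regime == "segments" &&
      (is.na(object@segment) || is.na(object@t1Ms) || is.na(object@t2Ms)))
    return("segments regime needs segment name and boundaries t1Ms, t2Ms")
  if (object@regime == "spatial" && is.na(object@channel))
    return("spatial regime needs a channel")
  if (!is.na(object@segment) &&
      !object@segment %in% c("baseline", "early", "middle", "late"))
    return("segment must be baseline/early/middle/late")
  TRUE
})

#' Construct a RegimeSpec
#'
#' @param regime "entire", "samples", "intervals", "segments" or "spatial".
#' @param tMs target time in ms (samples/intervals).
#' @param segment "baseline", "early", "middle" or "late".
#' @param t1Ms,t2Ms segment boundaries in ms (segments regime; also used
#'   when a spatial regime is restricted to a segment).
#' @param channel channel identifier (spatial).
#' @return A [RegimeSpec-class].
#' @examples
#' regimeSpec("entire")
#' regimeSpec("samples", tMs = 250)
#' regimeSpec("segments", segment = "middle", t1Ms = 60, t2Ms = 350)
#' @export
regimeSpec <- function(regime, tMs = NA_real_, segment = NA_character_,
                       t1Ms = NA_real_, t2Ms = NA_real_,
                       channel = NA_character_) {
  new("RegimeSpec", regime = regime, tMs = as.numeric(tMs),
      segment = as.character(segment), t1Ms = as.numeric(t1Ms),
      t2Ms = as.numeric(t2Ms), channel = as.character(channel))
}

setMethod("show", "RegimeSpec", function(object) {
  extra <- switch(object@regime,
    samples = paste0(" @ ", object@tMs, " ms"),
    intervals = paste0(" up to ", object@tMs, " ms"),
    segments = paste0(" '", object@segment, "' (t1=", object@t1Ms,
                      ", t2=", object@t2Ms, " ms)"),
    spatial = paste0(" channel ", object@channel,
                     if (!is.na(object@segment))
                       paste0(", segment ", object@segment) else ""),
    "")
  cat("RegimeSpec:", object@regime, extra, "\n", sep = "")
})

#' FeatureMatrix: the decoder's design matrix for one regime
#'
#' @slot values N x p' numeric matrix (trials by selected features).
#' @slot regime the [RegimeSpec-class] that produced it.
#' @slot featureIndex data.frame mapping each column to (channel, time_ms);
#'   columns are ordered channel-major (channel varies slowest).
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", regime = "RegimeSpec",
                 featureIndex = "data.frame"))

setValidity("FeatureMatrix", function(object) {
  if (nrow(object@featureIndex) != ncol(object@values))
    return("featureIndex must describe every column")
  TRUE
})

#' Numeric design matrix of a FeatureMatrix
#' @param x a [FeatureMatrix-class].
#' @return the N x p' matrix.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname featureValues
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d trials x %d features (regime %s)\n",
              nrow(object@values), ncol(object@values), object@regime@regime))
})

#' DecodingResult: cross-validated decoding power for one fit
#'
#' @slot r2 mean held-out fraction of variance explained (may be negative).
#' @slot foldR2 per-outer-fold R-squared values.
#' @slot lambda chosen L1 penalty per outer fold.
#' @slot regime the [RegimeSpec-class] decoded.
#' @slot measure surprise measure used as label.
#' @slot w integration coefficient of the label series.
#' @slot nFolds number of outer folds.
#' @slot seed seed that fixed the fold assignment.
#' @seealso [fitDecode()]
#' @export
setClass("DecodingResult",
  representation(r2 = "numeric", foldR2 = "numeric", lambda = "numeric",
                 regime = "RegimeSpec", measure = "character", w = "numeric",
                 nFolds = "integer", seed = "integer"),
  prototype(measure = NA_character_, w = NA_real_))

setValidity("DecodingResult", function(object) {
  if (length(object@r2) != 1L || object@r2 > 1 + 1e-12)
    return("r2 must be a single value <= 1")
  TRUE
})

#' Decoding power (held-out R-squared)
#' @param x a [DecodingResult-class].
#' @return single numeric R-squared.
#' @export
setGeneric("decodingPower", function(x) standardGeneric("decodingPower"))

#' @rdname decodingPower
#' @export
setMethod("decodingPower", "DecodingResult", function(x) x@r2)

setMethod("show", "DecodingResult", function(object) {
  cat(sprintf("DecodingResult: R2 = %.4f (%d-fold, regime %s%s)\n",
              object@r2, object@nFolds, object@regime@regime,
              if (!is.na(object@measure))
                paste0(", ", object@measure, " w=", object@w) else ""))
})

#' ChanceDistribution: permutation chance levels for a decoding analysis
#'
#' @slot r2Samples chance R-squared, one per label permutation.
#' @slot nPermutations number of permutations.
#' @slot seed seed of the permutation stream.
#' @seealso [chanceLevel()], [empiricalP()]
#' @export
setClass("ChanceDistribution",
  representation(r2Samples = "numeric", nPermutations = "integer",
                 seed = "integer"))

setValidity("ChanceDistribution", function(object) {
  if (length(object@r2Samples) != object@nPermutations)
    return("one chance sample per permutation required")
  if (object@nPermutations < 1L) return("need at least one permutation")
  TRUE
})

#' Chance R-squared samples
#' @param x a [ChanceDistribution-class].
#' @return numeric vector of permutation R-squared values.
#' @export
setGeneric("chanceSamples", function(x) standardGeneric("chanceSamples"))

#' @rdname chanceSamples
#' @export
setMethod("chanceSamples", "ChanceDistribution", function(x) x@r2Samples)

setMethod("show", "ChanceDistribution", function(object) {
  cat(sprintf("ChanceDistribution: %d permutations, mean %.4f, sd %.4f\n",
              object@nPermutations, mean(object@r2Samples),
              sd(object@r2Samples)))
})

#' PowerCurve: decoding power as a function of time
#'
#' @slot timesMs sample times.
#' @slot r2 decoding power at each time (max over the swept w grid).
#' @slot regime "samples" or "intervals".
#' @slot measure surprise measure decoded.
#' @slot replicates optional replicate x time matrix of per-replicate curves
#'   (0 rows when the curve comes from a single dataset).
#' @seealso [samplesCurve()], [intervalsCurve()], [detectSegments()]
#' @export
setClass("PowerCurve",
  representation(timesMs = "numeric", r2 = "numeric", regime = "character",
                 measure = "character", replicates = "matrix"),
  prototype(replicates = matrix(numeric(), 0, 0)))

setValidity("PowerCurve", function(object) {
  if (length(object@timesMs) != length(object@r2))
    return("one r2 value per time point required")
  if (!object@regime %in% c("samples", "intervals"))
    return("regime must be 'samples' or 'intervals'")
  TRUE
})

setMethod("show", "PowerCurve", function(object) {
  cat(sprintf("PowerCurve (%s, %s): %d time points, max R2 = %.4f at %g ms\n",
              object@regime, object@measure, length(object@r2),
              max(object@r2), object@timesMs[which.max(object@r2)]))
})

#' SegmentBoundaries: the times separating early/middle/late segments
#'
#' @slot t1Ms first time reaching 10 percent of the post-stimulus maximum
#'   decoding power (early/middle boundary).
#' @slot t2Ms time of minimum decoding power within [250, 400] ms
#'   (middle/late boundary).
#' @slot measure surprise measure the curve was computed for.
#' @slot provenance "detected" or "user_supplied".
#' @seealso [detectSegments()], [segmentPowers()]
#' @export
setClass("SegmentBoundaries",
  representation(t1Ms = "numeric", t2Ms = "numeric", measure = "character",
                 provenance = "character"),
  prototype(measure = NA_character_, provenance = "user_supplied"))

setValidity("SegmentBoundaries", function(object) {
  if (!(object@t1Ms > 0 && object@t2Ms > object@t1Ms))
    return("boundaries must satisfy 0 < t1 < t2")
  if (!object@provenance %in% c("detected", "user_supplied"))
    return("provenance must be 'detected' or 'user_supplied'")
  TRUE
})

#' Construct SegmentBoundaries by hand
#' @param t1Ms,t2Ms boundary times in ms, 0 < t1 < t2.
#' @param measure optional measure tag.
#' @return A [SegmentBoundaries-class] with provenance "user_supplied".
#' @export
segmentBoundaries <- function(t1Ms, t2Ms, measure = NA_character_) {
  new("SegmentBoundaries", t1Ms = as.numeric(t1Ms), t2Ms = as.numeric(t2Ms),
      measure = as.character(measure), provenance = "user_supplied")
}

setMethod("show", "SegmentBoundaries", function(object) {
  cat(sprintf("SegmentBoundaries: t1 = %g ms, t2 = %g ms (%s)\n",
              object@t1Ms, object@t2Ms, object@provenance))
})

#' StatsReport: a family of statistical comparisons with Bonferroni control
#'
#' @slot comparisons data.frame with columns label, statistic, p, threshold,
#'   significant.
#' @slot correction correction method ("bonferroni").
#' @slot familySize number of tests in the corrected family.
#' @slot alpha uncorrected significance level.
#' @seealso [compareSegments()], [compareToChance()]
#' @export
setClass("StatsReport",
  representation(comparisons = "data.frame", correction = "character",
                 familySize = "integer", alpha = "numeric"),
  prototype(correction = "bonferroni", alpha = 0.05))

setValidity("StatsReport", function(object) {
  need <- c("label", "statistic", "p", "threshold", "significant")
  if (!all(need %in% names(object@comparisons)))
    return(paste("comparisons must have columns:",
                 paste(need, collapse = ", ")))
  if (object@familySize < 1L) return("familySize must be >= 1")
  thr <- object@alpha / object@familySize
  if (any(abs(object@comparisons$threshold - thr) > 1e-12))
    return("threshold must equal alpha / familySize")
  if (any(object@comparisons$significant !=
          (object@comparisons$p < object@comparisons$threshold)))
    return("significant flag must equal p < threshold")
  TRUE
})

setMethod("show", "StatsReport", function(object) {
  cat(sprintf("StatsReport (%s, family %d, threshold %.4f):\n",
              object@correction, object@familySize,
              object@alpha / object@familySize))
  print(object@comparisons, row.names = FALSE)
})
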
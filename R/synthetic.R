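# Synthetic oddball sequences and surprise-encoding epochs.
#
# The generator emulates one oddball block of ~405 trials with deviant
# probability 1/3 and epochs spanning [-200, 600] ms at 80 samples, and
# injects a surprise-proportional evoked component: a Gaussian latency bump
# whose trial-to-trial amplitude is an affine function of a chosen surprise
# series, spread over channels by a fixed random topography, plus additive
# (optionally AR(1)-correlated) Gaussian noise.  It gives every downstream
# stage a known ground truth to recover.

#' Generate a binary oddball stimulus sequence
#'
#' Trials are drawn independently Bernoulli(pDeviant); 0 codes the
#' standard, 1 the deviant. The same seed always yields the same sequence.
#'
#' @param T number of trials (>= 1).
#' @param pDeviant deviant probability in [0, 1].
#' @param seed integer seed.
#' @return A [StimulusSequence-class].
#' @examples
#' seq <- generateOddball(405, 1/3, seed = 7)
#' mean(trialLabels(seq))
#' @export
generateOddball <- function(T, pDeviant = 1 / 3, seed = 1L) {
  if (!is.numeric(T) || T < 1) stop("T must be a positive integer")
  if (pDeviant < 0 || pDeviant > 1) stop("pDeviant must lie in [0, 1]")
  labels <- withSeed(seed, rbinom(as.integer(T), 1L, pDeviant))
  new("StimulusSequence", labels = as.integer(labels),
      pDeviant = pDeviant, seed = as.integer(seed))
}

#' Specification of a synthetic surprise-encoding epoch dataset
#'
#' Defaults match the emulated study conditions: 405 trials at deviant
#' probability 1/3, 20 channels, 80 samples spanning [-200, 600] ms, an
#' encoding bump at 250 +/- 50 ms, surprise gain / noise ratio 0.5 with the
#' Shannon series at w = 16 as ground truth, and mildly autocorrelated
#' noise (lag-1 correlation 0.5, the order of magnitude a 30 Hz low-passed
#' recording resampled near 100 Hz exhibits).
#'
#' @param nTrials number of trials.
#' @param nChannels number of channels.
#' @param timesMs strictly increasing sample times (ms).
#' @param encodeCenterMs,encodeWidthMs latency and Gaussian width of the
#'   encoding bump (ms).
#' @param beta0 surprise-independent evoked amplitude (arbitrary units).
#' @param beta1 surprise gain: amplitude added per standard deviation of
#'   surprise.
#' @param noiseSd standard deviation of the additive noise.
#' @param ar1Rho lag-1 autocorrelation of the noise along time, in [0, 1).
#' @param trueMeasure surprise measure injected as ground truth.
#' @param trueW integration coefficient of the injected series.
#' @param loadingSeed,noiseSeed seeds of the channel topography and the
#'   noise draw.
#' @param loadings optional explicit channel loadings (overrides
#'   loadingSeed); recycled/validated to nChannels.
#' @return A list with class "SyntheticEpochSpec".
#' @export
syntheticEpochSpec <- function(nTrials = 405L, nChannels = 20L,
                               timesMs = seq(-200, 600, length.out = 80),
                               encodeCenterMs = 250, encodeWidthMs = 50,
                               beta0 = 1, beta1 = 0.5, noiseSd = 1,
                               ar1Rho = 0.5,
                               trueMeasure = "shannon", trueW = 16,
                               loadingSeed = 1L, noiseSeed = 2L,
                               loadings = NULL) {
  spec <- list(nTrials = as.integer(nTrials), nChannels = as.integer(nChannels),
               timesMs = as.numeric(timesMs),
               encodeCenterMs = encodeCenterMs, encodeWidthMs = encodeWidthMs,
               beta0 = beta0, beta1 = beta1, noiseSd = noiseSd,
               ar1Rho = ar1Rho, trueMeasure = trueMeasure, trueW = trueW,
               loadingSeed = as.integer(loadingSeed),
               noiseSeed = as.integer(noiseSeed), loadings = loadings)
  class(spec) <- "SyntheticEpochSpec"
  validateEpochSpec(spec)
  spec
}

validateEpochSpec <- function(spec) {
  with(spec, {
    if (length(timesMs) < 1L) stop("time grid must be nonempty")
    if (any(diff(timesMs) <= 0)) stop("timesMs must be strictly increasing")
    if (noiseSd < 0) stop("noiseSd must be nonnegative")
    if (ar1Rho < 0 || ar1Rho >= 1) stop("ar1Rho must lie in [0, 1)")
    if (encodeWidthMs <= 0) stop("encodeWidthMs must be positive")
    lo <- encodeCenterMs - 2 * encodeWidthMs
    hi <- encodeCenterMs + 2 * encodeWidthMs
    post <- timesMs[timesMs >= 0]
    if (!length(post) || hi < min(post) || lo > max(post))
      stop("encoding window [center +/- 2*width] must intersect the ",
           "post-stimulus interval")
    if (!is.null(loadings) && length(loadings) != nChannels)
      stop("loadings must have one value per channel")
  })
  invisible(spec)
}

#' Simulate surprise-encoding epochs for a stimulus sequence
#'
#' Builds data(n, c, t) = L_c * (beta0 + beta1 * S(n)) * g(t) + eta(n, c, t)
#' where S is the ground-truth surprise series (z-scored across trials),
#' g(t) = exp(-(t - center)^2 / (2 width^2)) is the unnormalized encoding
#' bump, L_c are seeded standard-normal channel loadings scaled to unit
#' root-mean-square, and eta is Gaussian noise, independent across trials
#' and channels, optionally AR(1) along time with stationary marginal
#' standard deviation `noiseSd`.
#'
#' @param seq a [StimulusSequence-class].
#' @param spec a [syntheticEpochSpec()] whose nTrials matches the sequence.
#' @return An [EpochTensor-class] of kind "sensor" carrying the sequence's
#'   labels.
#' @examples
#' seq <- generateOddball(60, 1/3, seed = 1)
#' spec <- syntheticEpochSpec(nTrials = 60, nChannels = 4,
#'                            timesMs = seq(-200, 600, length.out = 20))
#' dim(simulateEpochs(seq, spec))
#' @export
simulateEpochs <- function(seq, spec = syntheticEpochSpec()) {
  if (!is(seq, "StimulusSequence")) seq <- stimulusSequence(seq)
  validateEpochSpec(spec)
  if (length(seq) != spec$nTrials)
    stop("spec$nTrials must equal the sequence length")
  N <- spec$nTrials; C <- spec$nChannels; Ts <- length(spec$timesMs)

  S <- surpriseValues(surpriseSeries(seq, spec$trueMeasure, spec$trueW))
  Sz <- if (spec$beta1 == 0) numeric(N) else zscore(S)

  g <- exp(-(spec$timesMs - spec$encodeCenterMs)^2 /
             (2 * spec$encodeWidthMs^2))
  L <- if (!is.null(spec$loadings)) as.numeric(spec$loadings)
       else withSeed(spec$loadingSeed, rnorm(C))
  L <- L / sqrt(mean(L^2))

  amp <- spec$beta0 + spec$beta1 * Sz                   # per trial
  signal <- outer(amp, L) %o% g                         # N x C x T

  if (spec$noiseSd > 0) {
    eta <- withSeed(spec$noiseSeed, {
      z <- array(rnorm(N * C * Ts), c(N, C, Ts))
      if (spec$ar1Rho > 0) {
        rho <- spec$ar1Rho
        e <- z
        e[, , 1] <- z[, , 1]
        for (t in 2:Ts)
          e[, , t] <- rho * e[, , t - 1] + sqrt(1 - rho^2) * z[, , t]
        e
      } else z
    })
    signal <- signal + spec$noiseSd * eta
  }
  epochTensor(signal, spec$timesMs, stimuli = seq@labels, kind = "sensor")
}

#' Write a stimulus sequence as a single-column CSV
#'
#' @param seq a [StimulusSequence-class].
#' @param path output path; the column header is "stimulus".
#' @return `path`, invisibly.
#' @export
writeSequenceCSV <- function(seq, path) {
  if (!is(seq, "StimulusSequence")) seq <- stimulusSequence(seq)
  write.csv(data.frame(stimulus = seq@labels), path, row.names = FALSE)
  invisible(path)
}

#' Read a stimulus sequence from a single-column CSV
#'
#' @param path CSV with a "stimulus" column of 0/1 codes.
#' @param pDeviant optional known generating probability.
#' @return A [StimulusSequence-class].
#' @export
readSequenceCSV <- function(path, pDeviant = NA_real_) {
  df <- read.csv(path)
  if (!"stimulus" %in% names(df))
    stop("sequence CSV must have a 'stimulus' column")
  stimulusSequence(df$stimulus, pDeviant = pDeviant)
}
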
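# Epoch container I/O, resampling, and feature-matrix construction.

#' Write an EpochTensor to an HDF5 container
#'
#' Datasets: `data` (float64, trials x channels x timepoints), `times_ms`
#' (float64), `channel_names` (UTF-8 strings), `stimuli` (integer 0/1);
#' the tensor kind is stored in the scalar `kind` dataset. Round-trips
#' losslessly through [readEpochs()].
#'
#' @param tensor an [EpochTensor-class].
#' @param path output file path (overwritten if present).
#' @return `path`, invisibly.
#' @export
writeEpochs <- function(tensor, path) {
  stopifnot(is(tensor, "EpochTensor"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(tensor@data, path, "data")
  rhdf5::h5write(tensor@timesMs, path, "times_ms")
  rhdf5::h5write(tensor@channelNames, path, "channel_names")
  rhdf5::h5write(tensor@stimuli, path, "stimuli")
  rhdf5::h5write(tensor@kind, path, "kind")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read an EpochTensor from an HDF5 container
#'
#' @param path file written by [writeEpochs()] (or any HDF5 file exposing
#'   the same datasets).
#' @return An [EpochTensor-class].
#' @export
readEpochs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  present <- rhdf5::h5ls(path)$name
  for (need in c("data", "times_ms", "channel_names", "stimuli"))
    if (!need %in% present)
      stop("epoch container is missing dataset '", need, "'")
  on.exit(rhdf5::h5closeAll())
  kind <- if ("kind" %in% present)
    as.character(rhdf5::h5read(path, "kind")) else "sensor"
  epochTensor(data = rhdf5::h5read(path, "data"),
              timesMs = as.numeric(rhdf5::h5read(path, "times_ms")),
              channelNames = as.character(rhdf5::h5read(path, "channel_names")),
              stimuli = as.integer(rhdf5::h5read(path, "stimuli")),
              kind = kind)
}

#' Resample epochs onto an evenly spaced coarser grid
#'
#' Plain decimation: the new grid is `nSamples` evenly spaced times over
#' the original window, and each new sample takes the value of the nearest
#' original sample (ties resolve to the earlier one).
#'
#' @param tensor an [EpochTensor-class].
#' @param nSamples target number of samples (2 <= nSamples <= current).
#' @return The resampled [EpochTensor-class].
#' @export
resampleEpochs <- function(tensor, nSamples) {
  stopifnot(is(tensor, "EpochTensor"))
  Ts <- length(tensor@timesMs)
  if (nSamples < 2) stop("nSamples must be at least 2")
  if (nSamples > Ts) stop("cannot upsample: nSamples exceeds current grid")
  grid <- seq(min(tensor@timesMs), max(tensor@timesMs),
              length.out = nSamples)
  idx <- nearestSample(tensor@timesMs, grid)
  epochTensor(tensor@data[, , idx, drop = FALSE], tensor@timesMs[idx],
              tensor@channelNames, tensor@stimuli, tensor@kind)
}

# Time-column selector for a regime; returns integer sample indices.
# Segment membership uses half-open [start, end) intervals except that the
# late segment keeps the final sample, so the four segments exactly
# partition the epoch.
regimeTimeIndex <- function(times, spec) {
  switch(spec@regime,
    entire = seq_along(times),
    samples = {
      if (spec@tMs < min(times) || spec@tMs > max(times))
        stop("target time lies outside the epoch")
      nearestSample(times, spec@tMs)
    },
    intervals = {
      if (spec@tMs < min(times) || spec@tMs > max(times))
        stop("target time lies outside the epoch")
      which(times <= spec@tMs + 1e-9)
    },
    segments = ,
    spatial = {
      if (spec@regime == "spatial" && is.na(spec@segment))
        return(seq_along(times))
      win <- segmentWindow(spec@segment, spec@t1Ms, spec@t2Ms,
                           min(times), max(times))
      idx <- if (is.na(win[2])) which(times >= win[1])
             else which(times >= win[1] & times < win[2])
      if (!length(idx)) stop("segment '", spec@segment, "' contains no samples")
      idx
    })
}

segmentWindow <- function(segment, t1, t2, tMin, tMax) {
  switch(segment,
    baseline = c(tMin, 0),
    early = c(0, t1),
    middle = c(t1, t2),
    late = c(t2, NA),  # closed at the epoch end
    stop("unknown segment: ", segment))
}

#' Build the decoder's feature matrix for a regime
#'
#' Selects epoch samples according to the regime and flattens them to an
#' N x p' matrix with channel-major column order (channel varies slowest):
#' entire = all channels' full time courses; samples = the single sample
#' nearest tMs, all channels; intervals = all samples from epoch start
#' through tMs; segments = the samples inside the named segment (half-open
#' [start, end), late segment closed at the epoch end); spatial = one
#' channel's time course, optionally restricted to a segment.
#'
#' @param tensor an [EpochTensor-class].
#' @param spec a [RegimeSpec-class].
#' @return A [FeatureMatrix-class].
#' @examples
#' seq <- generateOddball(40, 1/3, 1)
#' spec <- syntheticEpochSpec(nTrials = 40, nChannels = 3,
#'                            timesMs = seq(-200, 600, length.out = 20))
#' tensor <- simulateEpochs(seq, spec)
#' dim(featureValues(buildFeatures(tensor, regimeSpec("entire"))))
#' @export
buildFeatures <- function(tensor, spec) {
  stopifnot(is(tensor, "EpochTensor"), is(spec, "RegimeSpec"))
  validObject(spec)
  times <- tensor@timesMs
  tIdx <- regimeTimeIndex(times, spec)
  if (spec@regime == "spatial") {
    cIdx <- match(spec@channel, tensor@channelNames)
    if (is.na(cIdx)) stop("unknown channel: ", spec@channel)
  } else {
    cIdx <- seq_along(tensor@channelNames)
  }
  sub <- tensor@data[, cIdx, tIdx, drop = FALSE]
  # channel-major flatten: column (c-1)*|tIdx| + t
  vals <- matrix(aperm(sub, c(1, 3, 2)), nrow = dim(sub)[1])
  idx <- data.frame(
    channel = rep(tensor@channelNames[cIdx], each = length(tIdx)),
    time_ms = rep(times[tIdx], length(cIdx)),
    stringsAsFactors = FALSE)
  new("FeatureMatrix", values = vals, regime = spec, featureIndex = idx)
}
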
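# The three per-trial surprise quantifications used as decoder labels.
#
# All three are driven by the ideal observer's factorized Beta belief.
# Shannon surprise is the negative log posterior-predictive probability of
# the observed stimulus ("unlikeliness"); Bayesian surprise is the KL
# divergence from the prior to the posterior belief ("belief shift");
# confidence-corrected surprise is the KL divergence between the current
# belief and the posterior a naive observer would hold after seeing only
# the most recent transition from a uniform prior ("unexpectedness scaled
# by commitment").

#' Kullback-Leibler divergence between two Beta distributions
#'
#' Closed form via log-Beta and digamma functions:
#' KL(Beta(a1,b1) || Beta(a2,b2)) = ln B(a2,b2) - ln B(a1,b1)
#'   + (a1-a2) psi(a1) + (b1-b2) psi(b1) + (a2-a1+b2-b1) psi(a1+b1).
#' Vectorized over its arguments.
#'
#' @param a1,b1 parameters of the first (reference) Beta distribution.
#' @param a2,b2 parameters of the second Beta distribution.
#' @return Nonnegative divergence in nats.
#' @examples
#' klBeta(2, 3, 2, 3)   # 0
#' klBeta(2, 1, 1, 1)   # log(2) - 1/2
#' @export
klBeta <- function(a1, b1, a2, b2) {
  if (any(c(a1, b1, a2, b2) <= 0))
    stop("Beta parameters must be positive")
  lbeta(a2, b2) - lbeta(a1, b1) +
    (a1 - a2) * digamma(a1) + (b1 - b2) * digamma(b1) +
    (a2 - a1 + b2 - b1) * digamma(a1 + b1)
}

# KL between two factorized beliefs given as T x 4 parameter matrices,
# summed over the two independent Beta factors.
klFactorized <- function(p, q) {
  klBeta(p[, "alphaGiven1"], p[, "betaGiven1"],
         q[, "alphaGiven1"], q[, "betaGiven1"]) +
    klBeta(p[, "alphaGiven0"], p[, "betaGiven0"],
           q[, "alphaGiven0"], q[, "betaGiven0"])
}

# Predictive probability of the observed stimulus at each trial, from the
# prior parameter matrix; trial 1 is 1/2 by assumption.
predictiveSeries <- function(trajectory) {
  labels <- trajectory@labels
  T <- length(labels)
  p <- numeric(T)
  p[1] <- 0.5
  if (T > 1) {
    pr <- trajectory@prior
    for (t in 2:T) {
      if (labels[t - 1] == 0) {
        p1 <- pr[t, "alphaGiven0"] / (pr[t, "alphaGiven0"] + pr[t, "betaGiven0"])
        p[t] <- if (labels[t] == 1) p1 else 1 - p1
      } else {
        p0 <- pr[t, "alphaGiven1"] / (pr[t, "alphaGiven1"] + pr[t, "betaGiven1"])
        p[t] <- if (labels[t] == 0) p0 else 1 - p0
      }
    }
  }
  p
}

# Naive observer's posterior parameters: uniform belief updated with only
# the single observed transition at each trial (zeros at trial 1).
naivePosterior <- function(labels) {
  T <- length(labels)
  n <- matrix(0, T, 4, dimnames = list(NULL, c("n0g0", "n1g0", "n0g1", "n1g1")))
  if (T > 1)
    for (t in 2:T)
      n[t, 1L + labels[t] + 2L * labels[t - 1L]] <- 1
  paramsFromCounts(n)
}

#' Per-trial surprise series of a stimulus sequence
#'
#' Computes one of the three surprise quantifications along the sequence,
#' under leaky integration with coefficient `w`. At trial 1 (no preceding
#' transition) Shannon surprise is -log(1/2) and the two divergence-based
#' measures are 0.
#'
#' The Kullback-Leibler orientation of the divergence-based measures is
#' configurable: the defaults are KL(posterior || prior) for Bayesian
#' surprise and KL(current belief || naive posterior) for the
#' confidence-corrected variant.
#'
#' @param seq a [StimulusSequence-class] or 0/1 vector.
#' @param measure "shannon", "bayesian" or "confidence_corrected".
#' @param w positive integration coefficient (trials).
#' @param logBase "e" for nats (default) or "2" for bits.
#' @param orientation "forward" for the default KL orientation, "reverse"
#'   to swap the two arguments (ignored for Shannon surprise).
#' @return A [SurpriseSeries-class].
#' @examples
#' s <- surpriseSeries(generateOddball(50, 1/3, seed = 1), "shannon", w = 16)
#' head(surpriseValues(s))
#' @export
surpriseSeries <- function(seq,
                           measure = c("shannon", "bayesian",
                                       "confidence_corrected"),
                           w, logBase = c("e", "2"),
                           orientation = c("forward", "reverse")) {
  measure <- match.arg(measure)
  logBase <- match.arg(logBase)
  orientation <- match.arg(orientation)
  if (!is(seq, "StimulusSequence")) seq <- stimulusSequence(seq)
  traj <- beliefTrajectory(seq, w)
  fac <- logBaseFactor(logBase)
  vals <- switch(measure,
    shannon = -log(predictiveSeries(traj)),
    bayesian = {
      v <- if (orientation == "forward")
        klFactorized(traj@posterior, traj@prior)
      else klFactorized(traj@prior, traj@posterior)
      v[1] <- 0
      v
    },
    confidence_corrected = {
      np <- naivePosterior(seq@labels)
      v <- if (orientation == "forward") klFactorized(traj@prior, np)
      else klFactorized(np, traj@prior)
      v[1] <- 0
      v
    })
  vals <- pmax(vals, 0) * fac  # clip divergence round-off at exactly 0
  new("SurpriseSeries", values = as.numeric(vals), measure = measure,
      w = w, logBase = logBase)
}

#' @rdname surpriseSeries
#' @export
shannonSurprise <- function(seq, w, logBase = "e")
  surpriseSeries(seq, "shannon", w, logBase)

#' @rdname surpriseSeries
#' @export
bayesianSurprise <- function(seq, w, logBase = "e",
                             orientation = c("forward", "reverse"))
  surpriseSeries(seq, "bayesian", w, logBase, orientation)

#' @rdname surpriseSeries
#' @export
confidenceCorrectedSurprise <- function(seq, w, logBase = "e",
                                        orientation = c("forward", "reverse"))
  surpriseSeries(seq, "confidence_corrected", w, logBase, orientation)

#' Write a surprise series next to its sequence as CSV
#'
#' Columns: trial, stimulus, surprise.
#'
#' @param series a [SurpriseSeries-class].
#' @param seq the [StimulusSequence-class] it was computed from.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSurpriseCSV <- function(series, seq, path) {
  if (!is(seq, "StimulusSequence")) seq <- stimulusSequence(seq)
  stopifnot(length(series) == length(seq))
  write.csv(data.frame(trial = seq_along(series@values),
                       stimulus = seq@labels,
                       surprise = series@values),
            path, row.names = FALSE)
  invisible(path)
}
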
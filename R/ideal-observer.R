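# Bayesian ideal observer over binary oddball sequences.
#
# The observer models the stimulus stream as a first-order Markov chain and
# tracks the two free transition probabilities theta_{0|1} and theta_{1|0}
# through leaky transition counts: at every new transition all four counts
# are multiplied by exp(-1/w) before the observed transition's count is
# incremented by 1, so an observation at lag k carries weight exp(-k/w).
# Conjugacy of the Beta prior with the Bernoulli transition likelihoods
# keeps the belief in closed form:
#   p(theta | X) = Beta(1 + n_{0|1}, 1 + n_{1|1}) * Beta(1 + n_{1|0}, 1 + n_{0|0}).

# Count matrices for all trials: columns n0g0, n1g0, n0g1, n1g1.  The first
# trial induces no transition, so counts stay zero there.
leakyCountMatrix <- function(labels, w) {
  T <- length(labels)
  post <- matrix(0, T, 4,
                 dimnames = list(NULL, c("n0g0", "n1g0", "n0g1", "n1g1")))
  decay <- exp(-1 / w)
  cnt <- numeric(4)
  if (T > 1) {
    for (t in 2:T) {
      cnt <- cnt * decay
      j <- 1L + labels[t] + 2L * labels[t - 1L]  # (curr | prev) cell
      cnt[j] <- cnt[j] + 1
      post[t, ] <- cnt
    }
  }
  post
}

#' Fold one observed transition into the leaky counts
#'
#' All four counts decay by exp(-1/w), then the count of the observed
#' transition (curr after prev) is incremented by 1. This recursion is
#' equivalent to weighting the transition observed k steps ago by
#' exp(-k/w), with the most recent transition at weight 1.
#'
#' @param counts a [TransitionCounts-class].
#' @param prev,curr the previous and current stimulus codes (0 or 1).
#' @return The updated [TransitionCounts-class].
#' @examples
#' cts <- transitionCounts(w = 1)
#' cts <- updateCounts(cts, 0, 0)   # n0|0 = 1
#' cts <- updateCounts(cts, 0, 0)   # n0|0 = 1 + exp(-1)
#' @export
updateCounts <- function(counts, prev, curr) {
  stopifnot(is(counts, "TransitionCounts"))
  stopIfNot01(c(prev, curr))
  decay <- exp(-1 / counts@w)
  v <- c(counts@n0g0, counts@n1g0, counts@n0g1, counts@n1g1) * decay
  j <- 1L + as.integer(curr) + 2L * as.integer(prev)
  v[j] <- v[j] + 1
  initialize(counts, n0g0 = v[1], n1g0 = v[2], n0g1 = v[3], n1g1 = v[4],
             trialIndex = counts@trialIndex + 1L)
}

paramsFromCounts <- function(countRows) {
  # (alphaGiven1, betaGiven1, alphaGiven0, betaGiven0) =
  #   (1 + n0|1, 1 + n1|1, 1 + n1|0, 1 + n0|0)
  cbind(alphaGiven1 = 1 + countRows[, "n0g1"],
        betaGiven1  = 1 + countRows[, "n1g1"],
        alphaGiven0 = 1 + countRows[, "n1g0"],
        betaGiven0  = 1 + countRows[, "n0g0"])
}

#' Prior and posterior beliefs along a stimulus sequence
#'
#' Iterates the leaky-count recursion over the sequence and returns, for
#' every trial, the Beta parameters of the belief before (prior) and after
#' (posterior) observing that trial. Trial 1 induces no transition, so both
#' its prior and posterior are the uniform belief.
#'
#' @param seq a [StimulusSequence-class] (or 0/1 vector).
#' @param w positive integration coefficient in trials; Inf disables
#'   forgetting.
#' @return A [BeliefTrajectory-class].
#' @examples
#' tr <- beliefTrajectory(stimulusSequence(c(0, 1)), w = Inf)
#' beliefAt(tr, 2, "posterior")  # Beta(1,1) x Beta(2,1)
#' @export
beliefTrajectory <- function(seq, w) {
  if (!is(seq, "StimulusSequence")) seq <- stimulusSequence(seq)
  if (length(seq) < 1L) stop("sequence must be nonempty")
  if (!is.numeric(w) || w <= 0) stop("w must be a positive number")
  post <- leakyCountMatrix(seq@labels, w)
  prior <- rbind(rep(0, 4), post[-nrow(post), , drop = FALSE])
  colnames(prior) <- colnames(post)
  new("BeliefTrajectory",
      prior = paramsFromCounts(prior), posterior = paramsFromCounts(post),
      w = w, labels = seq@labels)
}

#' Belief at one trial of a trajectory
#'
#' @param trajectory a [BeliefTrajectory-class].
#' @param trial trial index (1-based).
#' @param which "prior" (before observing the trial) or "posterior".
#' @return A [BeliefState-class].
#' @export
beliefAt <- function(trajectory, trial, which = c("prior", "posterior")) {
  which <- match.arg(which)
  p <- slot(trajectory, which)[trial, ]
  beliefState(given1 = p[c("alphaGiven1", "betaGiven1")],
              given0 = p[c("alphaGiven0", "betaGiven0")])
}

#' Posterior-predictive probability of the next stimulus
#'
#' The probability the observer assigns to observing `nxt` after `prev`,
#' i.e. the mean of the relevant Beta factor (Laplace rule): for example
#' p(1 | 0) = (1 + n_{1|0}) / (2 + n_{1|0} + n_{0|0}). The two
#' probabilities conditioned on the same previous stimulus sum to 1
#' exactly.
#'
#' @param belief a [BeliefState-class].
#' @param prev,nxt previous and candidate next stimulus codes (0 or 1).
#' @return A probability.
#' @examples
#' predictiveProbability(beliefState(), 0, 1)            # 0.5 (uniform)
#' predictiveProbability(beliefState(given0 = c(3, 2)), 0, 1)  # 0.6
#' @export
predictiveProbability <- function(belief, prev, nxt) {
  stopifnot(is(belief, "BeliefState"))
  stopIfNot01(c(prev, nxt))
  if (prev == 0) {
    p1 <- belief@given0[1] / sum(belief@given0)  # mean of theta_{1|0}
    if (nxt == 1) p1 else 1 - p1
  } else {
    p0 <- belief@given1[1] / sum(belief@given1)  # mean of theta_{0|1}
    if (nxt == 0) p0 else 1 - p0
  }
}

#' Likelihood of a whole sequence under fixed transition probabilities
#'
#' Evaluates 0.5 * theta01^n01 * (1-theta01)^n11 * theta10^n10 *
#' (1-theta10)^n00 with plain (unweighted) transition tallies; the leading
#' 0.5 is the assumed probability of the first stimulus. Degenerate
#' parameters 0 or 1 are allowed and simply zero the product when the
#' corresponding tally is positive (0^0 counts as 1).
#'
#' @param seq a [StimulusSequence-class] (or 0/1 vector).
#' @param theta01 probability of a 0 following a 1.
#' @param theta10 probability of a 1 following a 0.
#' @return The sequence probability.
#' @examples
#' sequenceLikelihood(c(0), 0.3, 0.3)        # 0.5
#' sequenceLikelihood(c(0, 1), 0.5, 0.2)     # 0.5 * 0.2
#' @export
sequenceLikelihood <- function(seq, theta01, theta10) {
  if (!is(seq, "StimulusSequence")) seq <- stimulusSequence(seq)
  if (length(seq) < 1L) stop("sequence must be nonempty")
  if (theta01 < 0 || theta01 > 1 || theta10 < 0 || theta10 > 1)
    stop("transition probabilities must lie in [0, 1]")
  n <- leakyCountMatrix(seq@labels, Inf)[length(seq), ]
  0.5 * theta01^n[["n0g1"]] * (1 - theta01)^n[["n1g1"]] *
    theta10^n[["n1g0"]] * (1 - theta10)^n[["n0g0"]]
}
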
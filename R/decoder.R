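# Cross-validated sparse decoding of surprise labels from feature matrices.
#
# Nested cross-validation: the outer K-fold split (seeded shuffle of trial
# indices) measures held-out R-squared; within each training fold the
# features are standardized with training-fold statistics and the L1
# penalty is chosen by an inner fivefold cv.glmnet over a logarithmic
# lambda path.  R-squared is computed per outer test fold against that
# fold's own label variance and averaged (a pooled variant is available).
# Labels are standardized per training fold as well, which makes every
# reported R-squared exactly invariant under affine label transforms.

asFeatureMatrix <- function(X) {
  if (is(X, "FeatureMatrix")) X@values else as.matrix(X)
}

asLabelVector <- function(y) {
  if (is(y, "SurpriseSeries")) y@values else as.numeric(y)
}

makeFolds <- function(N, nFolds, seed) {
  withSeed(seed, sample(rep_len(seq_len(nFolds), N)))
}

# Standardize the feature matrix once per outer fold (statistics from the
# training rows only); constant columns become all-zero.
prepFolds <- function(X, foldid) {
  lapply(sort(unique(foldid)), function(k) {
    tr <- foldid != k
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2, sd)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    Xs <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
    list(train = Xs[tr, , drop = FALSE], test = Xs[!tr, , drop = FALSE],
         trainIdx = which(tr), testIdx = which(!tr))
  })
}

# Fit one outer fold: inner CV for lambda on standardized (X, y), predict
# the test rows, return held-out R2 and the chosen lambda.
fitFold <- function(fold, y, innerFoldid, nLambda) {
  yTr <- y[fold$trainIdx]; yTe <- y[fold$testIdx]
  muY <- mean(yTr); sdY <- sd(yTr)
  if (!is.finite(sdY) || sdY == 0)
    stop("labels are constant within a training fold")
  ys <- (yTr - muY) / sdY
  Xtr <- fold$train
  if (ncol(Xtr) < 2) {  # glmnet needs >= 2 columns; pad with a null column
    Xtr <- cbind(Xtr, 0)
    Xte <- cbind(fold$test, 0)
  } else Xte <- fold$test
  cvfit <- glmnet::cv.glmnet(Xtr, ys, foldid = innerFoldid,
                             nlambda = nLambda, standardize = FALSE,
                             family = "gaussian")
  predS <- as.numeric(predict(cvfit, Xte, s = "lambda.min"))
  pred <- predS * sdY + muY
  list(r2 = 1 - sum((yTe - pred)^2) / sum((yTe - mean(yTe))^2),
       sse = sum((yTe - pred)^2), lambda = cvfit$lambda.min)
}

decodeCore <- function(folds, y, seed, nLambda, pooled) {
  innerIds <- lapply(seq_along(folds), function(k)
    makeFolds(length(folds[[k]]$trainIdx), 5L, childSeed(seed, 100 + k)))
  fits <- lapply(seq_along(folds), function(k)
    fitFold(folds[[k]], y, innerIds[[k]], nLambda))
  foldR2 <- vapply(fits, `[[`, numeric(1), "r2")
  r2 <- if (pooled) {
    1 - sum(vapply(fits, `[[`, numeric(1), "sse")) /
      sum((y - mean(y))^2)
  } else mean(foldR2)
  list(r2 = r2, foldR2 = foldR2,
       lambda = vapply(fits, `[[`, numeric(1), "lambda"))
}

#' Decode a surprise series from a feature matrix
#'
#' Nested cross-validated Lasso regression of the labels on the features;
#' the returned decoding power is the held-out fraction of label variance
#' explained, averaged over the outer folds (negative values indicate a
#' misfit model on held-out data).
#'
#' @param X a [FeatureMatrix-class] or numeric matrix (trials x features).
#' @param y a [SurpriseSeries-class] or numeric label vector.
#' @param nFolds outer folds (default fivefold).
#' @param seed seed fixing the outer and inner fold assignments.
#' @param nLambda length of the logarithmic L1 penalty path searched by the
#'   inner cross-validation.
#' @param pooled if TRUE, pool squared errors over folds instead of
#'   averaging per-fold R-squared.
#' @return A [DecodingResult-class].
#' @examples
#' X <- matrix(rnorm(200 * 10), 200)
#' y <- X[, 3] * 2 + 1
#' decodingPower(fitDecode(X, y, seed = 1))  # ~1: perfectly decodable
#' @export
fitDecode <- function(X, y, nFolds = 5L, seed = 1L, nLambda = 20L,
                      pooled = FALSE) {
  regime <- if (is(X, "FeatureMatrix")) X@regime else regimeSpec("entire")
  measure <- if (is(y, "SurpriseSeries")) y@measure else NA_character_
  w <- if (is(y, "SurpriseSeries")) y@w else NA_real_
  Xm <- asFeatureMatrix(X)
  yv <- asLabelVector(y)
  if (nrow(Xm) != length(yv))
    stop("feature rows and label length must agree")
  if (nFolds < 2) stop("nFolds must be at least 2")
  if (nrow(Xm) < 2 * nFolds)
    stop("need at least 2 * nFolds trials")
  if (sd(yv) == 0) stop("labels have zero variance; nothing to decode")
  foldid <- makeFolds(nrow(Xm), nFolds, seed)
  folds <- prepFolds(Xm, foldid)
  core <- decodeCore(folds, yv, seed, nLambda, pooled)
  new("DecodingResult", r2 = core$r2, foldR2 = core$foldR2,
      lambda = core$lambda, regime = regime, measure = measure, w = w,
      nFolds = as.integer(nFolds), seed = as.integer(seed))
}

#' Permutation chance distribution of decoding power
#'
#' Repeats the full nested cross-validated fit with the label vector
#' uniformly permuted each time (the identity permutation may occur by
#' chance), yielding the chance distribution the observed decoding power
#' is judged against.
#'
#' @inheritParams fitDecode
#' @param nPermutations number of label permutations (default 100).
#' @return A [ChanceDistribution-class].
#' @seealso [empiricalP()]
#' @export
chanceLevel <- function(X, y, nPermutations = 100L, nFolds = 5L, seed = 1L,
                        nLambda = 20L) {
  Xm <- asFeatureMatrix(X)
  yv <- asLabelVector(y)
  if (nPermutations < 1) stop("need at least one permutation")
  if (nrow(Xm) != length(yv))
    stop("feature rows and label length must agree")
  foldid <- makeFolds(nrow(Xm), nFolds, seed)
  folds <- prepFolds(Xm, foldid)  # label-independent: reused across perms
  perms <- withSeed(childSeed(seed, 17),
                    replicate(nPermutations, sample(length(yv)),
                              simplify = FALSE))
  r2s <- vapply(perms, function(p)
    decodeCore(folds, yv[p], seed, nLambda, pooled = FALSE)$r2, numeric(1))
  new("ChanceDistribution", r2Samples = r2s,
      nPermutations = as.integer(nPermutations), seed = as.integer(seed))
}

#' Empirical p-value of an observed decoding power
#'
#' (1 + number of chance samples >= observed) / (number of permutations + 1).
#'
#' @param chance a [ChanceDistribution-class].
#' @param observed the observed R-squared.
#' @return Empirical p-value in (0, 1].
#' @export
empiricalP <- function(chance, observed) {
  stopifnot(is(chance, "ChanceDistribution"))
  (1 + sum(chance@r2Samples >= observed)) / (chance@nPermutations + 1)
}

#' Sweep the integration coefficient and keep the best decoder
#'
#' Recomputes the surprise labels for every w in the grid, decodes each,
#' and reports all results together with the w of maximal decoding power
#' (ties broken toward smaller w). This reproduces the "max over w"
#' reporting policy of the decoding analysis.
#'
#' @param tensor an [EpochTensor-class].
#' @param seq the [StimulusSequence-class] of the same trials.
#' @param measure surprise measure for the labels.
#' @param spec the [RegimeSpec-class] to decode.
#' @param wGrid integration-coefficient grid (default 1:100).
#' @param nFolds,seed,nLambda passed to [fitDecode()].
#' @return A list with elements `results` (list of
#'   [DecodingResult-class]), `bestW`, and `bestR2`.
#' @export
sweepW <- function(tensor, seq, measure, spec = regimeSpec("entire"),
                   wGrid = 1:100, nFolds = 5L, seed = 1L, nLambda = 20L) {
  if (!length(wGrid)) stop("wGrid must be nonempty")
  wGrid <- sort(as.numeric(wGrid))
  X <- buildFeatures(tensor, spec)
  results <- lapply(wGrid, function(w)
    fitDecode(X, surpriseSeries(seq, measure, w), nFolds = nFolds,
              seed = seed, nLambda = nLambda))
  r2s <- vapply(results, decodingPower, numeric(1))
  best <- which.max(r2s)  # first (= smallest w) on ties
  list(results = results, bestW = wGrid[best], bestR2 = r2s[best],
       wGrid = wGrid, r2 = r2s)
}
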
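# Independent-component extraction for epoched sensor data.
#
# Fixed-point (FastICA-style) symmetric estimation with the logcosh
# contrast, applied to the channels x (trials * time) unfolding of the
# tensor.  Implemented in-package; seeded, with an identity bypass for
# synthetic data whose channels are already the sources of interest.

# Symmetric fixed-point ICA on a pre-whitened p x n matrix; returns the
# orthogonal unmixing matrix W (rows = components).
fastIcaSym <- function(Z, nComponents, seed, maxIter = 200, tol = 1e-6) {
  p <- nrow(Z); n <- ncol(Z)
  W <- withSeed(seed, matrix(rnorm(nComponents * p), nComponents, p))
  orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- orth(W)
  for (it in seq_len(maxIter)) {
    WX <- W %*% Z                      # k x n
    G <- tanh(WX)
    gPrime <- 1 - G^2
    W1 <- (G %*% t(Z)) / n - diag(rowMeans(gPrime), nComponents) %*% W
    W1 <- orth(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) return(list(W = W, converged = TRUE, iterations = it))
  }
  list(W = W, converged = FALSE, iterations = maxIter)
}

#' Extract independent components from epoched sensor data
#'
#' Trials are concatenated along time into a channels x (trials * time)
#' matrix, which is centered, whitened by eigendecomposition of its
#' covariance, and unmixed by seeded symmetric fixed-point iteration with
#' the logcosh contrast. Per-trial component time courses are returned as
#' a tensor of kind "component". `method = "identity"` bypasses estimation
#' and simply relabels channels as components (useful for synthetic data).
#'
#' @param tensor an [EpochTensor-class] of kind "sensor".
#' @param nComponents number of components (<= number of channels).
#' @param seed seed for the initial unmixing matrix.
#' @param method "fastica" (default) or "identity".
#' @param maxIter,tol fixed-point iteration cap and convergence tolerance
#'   (non-convergence raises a warning naming the cap).
#' @return An [EpochTensor-class] of kind "component" with components
#'   scaled to unit variance.
#' @export
extractComponents <- function(tensor, nComponents = dim(tensor)[2],
                              seed = 1L, method = c("fastica", "identity"),
                              maxIter = 200L, tol = 1e-6) {
  stopifnot(is(tensor, "EpochTensor"))
  method <- match.arg(method)
  if (tensor@kind != "sensor")
    stop("component extraction expects a sensor-space tensor")
  d <- dim(tensor@data)
  if (nComponents < 1 || nComponents > d[2])
    stop("nComponents must lie in [1, number of channels]")

  if (method == "identity") {
    return(epochTensor(tensor@data, tensor@timesMs, tensor@channelNames,
                       tensor@stimuli, kind = "component"))
  }

  # unfold to channels x (time * trials)
  X <- matrix(aperm(tensor@data, c(2, 3, 1)), nrow = d[2])
  mu <- rowMeans(X)
  Xc <- X - mu
  covX <- tcrossprod(Xc) / ncol(Xc)
  eg <- eigen(covX, symmetric = TRUE)
  keep <- seq_len(nComponents)
  ev <- pmax(eg$values[keep], .Machine$double.eps)
  K <- diag(1 / sqrt(ev), nComponents) %*% t(eg$vectors[, keep, drop = FALSE])
  Z <- K %*% Xc                               # whitened, k x n

  fit <- fastIcaSym(Z, nComponents, seed = seed, maxIter = maxIter, tol = tol)
  if (!fit$converged)
    warning("fixed-point ICA did not converge within ", maxIter,
            " iterations")
  S <- fit$W %*% Z                            # k x (time * trials)

  comp <- aperm(array(S, c(nComponents, d[3], d[1])), c(3, 1, 2))
  epochTensor(comp, tensor@timesMs, paste0("IC", seq_len(nComponents)),
              tensor@stimuli, kind = "component")
}
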
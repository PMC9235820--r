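# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic fan-out of a master seed to per-stage seeds.  Stage i gets
# (master + 7919 * i) mod (2^31 - 1); 7919 is just a fixed odd prime so
# neighbouring stages never collide for reasonable master seeds.
childSeed <- function(master, index) {
  as.integer((as.numeric(master) + 7919 * as.numeric(index)) %% 2147483647)
}

zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("cannot z-score a constant vector")
  (x - mean(x)) / s
}

# Index of the grid point nearest each target; ties at half-grid resolve to
# the earlier sample.
nearestSample <- function(times, target) {
  vapply(target, function(tt) {
    d <- abs(times - tt)
    which(d <= min(d) + 1e-12)[1]
  }, integer(1))
}

stopIfNot01 <- function(x, what = "stimulus code") {
  if (!all(x %in% c(0, 1)))
    stop(what, " must be binary (0 or 1)", call. = FALSE)
}

logBaseFactor <- function(logBase) {
  switch(logBase, e = 1, "2" = 1 / log(2),
         stop("logBase must be 'e' or '2'"))
}
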
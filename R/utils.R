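# Internal numerical helpers shared across the package.

# log of the (multivariate) beta function: sum(lgamma(x)) - lgamma(sum(x)).
# Accepts a vector (Dirichlet normalizer) or two scalars (Beta normalizer).
lnBetaVec <- function(x) sum(lgamma(x)) - lgamma(sum(x))

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-normalize a matrix of log-weights with per-row max subtraction.
normalizeRowsLog <- function(logW) {
  mx <- apply(logW, 1L, max)
  W <- exp(logW - mx)
  W / rowSums(W)
}

# x * log(x) with the 0 * log 0 := 0 convention; x floored at 1e-300 so
# exactly-zero responsibilities never produce NaN.
xlogx <- function(x) {
  out <- x * log(pmax(x, 1e-300))
  out[x <= 0] <- 0
  out
}

# Deterministic sub-seed derivation so each named source of randomness
# (initialization, rewiring, holdout, ...) draws from its own stream while
# everything flows from one top-level seed. Kept below 2^31 - 1.
subSeed <- function(seed, stream) {
  offsets <- c(init = 101L, rewire = 211L, holdout = 307L, assign = 401L,
               edges = 503L, restart = 601L, fixtures = 701L)
  off <- if (is.character(stream)) offsets[[stream]] else as.integer(stream)
  as.integer((as.double(seed) * 48271 + off * 7919) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
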
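# Mean-field variational Bayes for the multiple-network stochastic block
# model.  One full sweep follows the printed update order: expected
# log-parameters -> root assignments Q -> instantaneous assignments Q(t)
# (synchronously, from the pre-update matrices) -> Dirichlet counts ->
# transition counts -> Beta edge counts -> free energy.

# Observed-pair likelihood matrices for network t: Obs (numeric 0/1 with
# zero diagonal) and Aobs = A * Obs.  Masked-out pairs drop from every sum.
likMatrices <- function(net, t) {
  Obs <- observedMask(net, t) * 1
  list(Obs = Obs, Aobs = net@adjacency[[t]] * Obs)
}

# Sparse per-vertex structure for the sequential assignment updates:
# observed neighbours and unobserved partners (excluding i itself) of every
# vertex in network t.
likCache <- function(net, t) {
  lik <- likMatrices(net, t)
  N <- nrow(lik$Obs)
  nbrs <- lapply(seq_len(N), function(i) which(lik$Aobs[i, ] == 1))
  masked <- length(net@mask) > 0L
  unobs <- if (masked)
    lapply(seq_len(N), function(i) setdiff(which(lik$Obs[i, ] == 0), i))
  else NULL
  list(nbrs = nbrs, unobs = unobs)
}

# Sequential (vertex-by-vertex) update of one assignment matrix under the
# pairwise edge terms; each row uses the freshly updated rows before it, so
# the sweep is an exact coordinate-descent step and the free energy cannot
# increase.  Vertex order is fixed at 1..N for reproducibility.
seqAssignmentSweep <- function(Qt, eq11, eq12, priorRows, cache) {
  N <- nrow(Qt)
  cs <- colSums(Qt)
  for (i in seq_len(N)) {
    aRow <- colSums(Qt[cache$nbrs[[i]], , drop = FALSE])
    oRow <- cs - Qt[i, ]
    if (!is.null(cache$unobs))
      oRow <- oRow - colSums(Qt[cache$unobs[[i]], , drop = FALSE])
    lg <- eq12 * aRow - eq11 * oRow + priorRows[i, ]
    w <- exp(lg - max(lg))
    w <- w / sum(w)
    cs <- cs - Qt[i, ] + w
    Qt[i, ] <- w
  }
  Qt
}

checkFinite <- function(x, step) {
  if (!all(is.finite(unlist(x))))
    stop(sprintf("non-finite value produced in VB step '%s'", step))
  invisible(x)
}

#' Initialize a variational state
#'
#' Every row of Q and of each Q(t) is drawn from a symmetric Dirichlet(1)
#' and normalized; all posterior pseudo-counts start at their priors.
#'
#' @param net a \linkS4class{MultiNetwork}.
#' @param hyper a \linkS4class{Hyperparameters}.
#' @param seed integer seed (two calls with the same seed are identical).
#' @return a \linkS4class{VariationalState}.
#' @export
initState <- function(net, hyper, seed = 1L) {
  N <- nVertices(net); K <- hyper@K; Tn <- nNetworks(net)
  if (K > N) warning("K exceeds the number of vertices; extra modules will stay empty")
  set.seed(subSeed(seed, "init"))
  draw <- function() {
    M <- matrix(stats::rgamma(N * K, shape = 1), N, K)
    M / rowSums(M)
  }
  new("VariationalState",
      Q = draw(), Qt = replicate(Tn, draw(), simplify = FALSE),
      nTilde = hyper@n0,
      etaTilde = replicate(Tn, hyper@eta0, simplify = FALSE),
      alphaC = hyper@alphaC0, betaC = hyper@betaC0,
      alphaD = hyper@alphaD0, betaD = hyper@betaD0,
      freeEnergyTrace = numeric(0), hyper = hyper,
      details = list(seed = as.integer(seed), vertexIds = vertexIds(net)))
}

#' Expected log-parameters under the current posteriors
#'
#' Digamma expectations of the conjugate posteriors used by the assignment
#' updates: \code{ElnPi[k]} = E[ln pi_k], \code{ElnP[[t]][k, m]} =
#' E[ln P(t)_km], \code{eq11} = E[ln (1-theta_d)/(1-theta_c)] and
#' \code{eq12} = E[ln (1-theta_d)/(1-theta_c) + ln theta_c/theta_d].
#'
#' @param state a \linkS4class{VariationalState}.
#' @return list with elements \code{ElnPi}, \code{ElnP}, \code{eq11},
#'   \code{eq12}.
#' @export
vbExpectations <- function(state) {
  if (any(state@nTilde <= 0) || state@alphaC <= 0 || state@betaC <= 0 ||
      state@alphaD <= 0 || state@betaD <= 0 ||
      any(vapply(state@etaTilde, function(e) any(e <= 0), logical(1))))
    stop("all posterior hyperparameters must be positive")
  ElnPi <- digamma(state@nTilde) - digamma(sum(state@nTilde))
  ElnP <- lapply(state@etaTilde, function(eta)
    digamma(eta) - digamma(rowSums(eta)))
  eq11 <- digamma(state@betaD) - digamma(state@alphaD + state@betaD) -
          digamma(state@betaC) + digamma(state@alphaC + state@betaC)
  eq12 <- digamma(state@alphaC) - digamma(state@betaC) -
          digamma(state@alphaD) + digamma(state@betaD)
  list(ElnPi = ElnPi, ElnP = ElnP, eq11 = eq11, eq12 = eq12)
}

#' Update the root assignment matrix Q
#'
#' \code{Q_ik} is proportional to \code{exp(E[ln pi_k] + sum_t sum_m
#' Q(t)_im E[ln P(t)_km])}; rows are normalized in log space with max
#' subtraction.
#'
#' @param state a \linkS4class{VariationalState}.
#' @param expect output of \code{\link{vbExpectations}}.
#' @return the state with slot Q updated.
#' @export
vbUpdateRoot <- function(state, expect) {
  logQ <- matrix(expect$ElnPi, nrow(state@Q), state@hyper@K, byrow = TRUE)
  for (t in seq_along(state@Qt))
    logQ <- logQ + state@Qt[[t]] %*% t(expect$ElnP[[t]])
  state@Q <- normalizeRowsLog(logQ)
  state
}

#' Update one instantaneous assignment matrix Q(t)
#'
#' \code{Q(t)_ik} is proportional to \code{exp(sum_(j != i, observed)
#' (eq12 A(t)_ij - eq11) Q(t)_jk + sum_s Q_is E[ln P(t)_sk])}.  Rows are
#' updated sequentially in fixed vertex order, each row seeing the freshly
#' updated rows before it: the sweep is then an exact coordinate-descent
#' step on the free energy, which rules out the period-two oscillations
#' that whole-matrix (synchronous) updates exhibit on these pairwise
#' couplings.
#'
#' @param state a \linkS4class{VariationalState}.
#' @param expect output of \code{\link{vbExpectations}}.
#' @param net the \linkS4class{MultiNetwork} being fitted.
#' @param t network index.
#' @param cache optional precomputed neighbour structure (internal use).
#' @return the state with slot Qt[[t]] updated.
#' @export
vbUpdateInstant <- function(state, expect, net, t, cache = NULL) {
  if (is.null(cache)) cache <- likCache(net, t)
  state@Qt[[t]] <- seqAssignmentSweep(state@Qt[[t]], expect$eq11, expect$eq12,
                                      state@Q %*% expect$ElnP[[t]], cache)
  state
}

#' Update the Dirichlet counts of the root proportions
#'
#' \code{nTilde_k = sum_i Q_ik + n0_k}.
#'
#' @param state a \linkS4class{VariationalState}.
#' @return the state with slot nTilde updated.
#' @export
vbUpdateRootCounts <- function(state) {
  state@nTilde <- colSums(state@Q) + state@hyper@n0
  state
}

#' Update the transition-count matrix of one network
#'
#' \code{etaTilde(t) = Q' Q(t) + eta0}; the added mass sums to N.
#'
#' @param state a \linkS4class{VariationalState}.
#' @param t network index.
#' @return the state with slot etaTilde[[t]] updated.
#' @export
vbUpdateTransitionCounts <- function(state, t) {
  state@etaTilde[[t]] <- crossprod(state@Q, state@Qt[[t]]) + state@hyper@eta0
  state
}

#' Update the Beta edge-count posteriors
#'
#' Expected within-module edge/non-edge counts and their between-module
#' complements, accumulated over all networks and restricted to observed
#' pairs, are added to the four Beta priors.  For fully observed networks
#' the four increments sum to T N (N - 1) / 2.
#'
#' @param state a \linkS4class{VariationalState}.
#' @param net the \linkS4class{MultiNetwork} being fitted.
#' @return the state with slots alphaC, betaC, alphaD, betaD updated.
#' @export
vbUpdateEdgeCounts <- function(state, net) {
  h <- state@hyper
  withinEdges <- 0; withinPairs <- 0; totalEdges <- 0; totalPairs <- 0
  for (t in seq_along(state@Qt)) {
    lik <- likMatrices(net, t)
    Qt <- state@Qt[[t]]
    withinEdges <- withinEdges + sum(Qt * (lik$Aobs %*% Qt)) / 2
    withinPairs <- withinPairs + sum(Qt * (lik$Obs %*% Qt)) / 2
    totalEdges <- totalEdges + sum(lik$Aobs) / 2
    totalPairs <- totalPairs + sum(lik$Obs) / 2
  }
  state@alphaC <- withinEdges + h@alphaC0
  state@betaC <- withinPairs - withinEdges + h@betaC0
  state@alphaD <- totalEdges - withinEdges + h@alphaD0
  state@betaD <- (totalPairs - withinPairs) - (totalEdges - withinEdges) + h@betaD0
  state
}

#' Variational free energy (negative evidence lower bound)
#'
#' Assignment-entropy terms plus log-ratios of posterior to prior
#' normalizers of all conjugate families.  The value is exact only when
#' the posterior pseudo-counts reflect the current Q matrices (i.e. after
#' a full update sweep); it never increases across sweeps and upper-bounds
#' the negative log evidence.
#'
#' @param state a \linkS4class{VariationalState}.
#' @return the free energy (a scalar).
#' @export
vbFreeEnergy <- function(state) {
  h <- state@hyper
  single <- isTRUE(state@details$single)
  ent <- sum(xlogx(state@Q))
  if (!single) for (t in seq_along(state@Qt)) ent <- ent + sum(xlogx(state@Qt[[t]]))
  trans <- 0
  if (!single)
    for (t in seq_along(state@etaTilde))
      for (k in seq_len(h@K))
        trans <- trans - (lnBetaVec(state@etaTilde[[t]][k, ]) - lnBetaVec(h@eta0[k, ]))
  params <- -(lnBetaVec(c(state@alphaC, state@betaC)) +
              lnBetaVec(c(state@alphaD, state@betaD)) +
              lnBetaVec(state@nTilde) -
              lnBetaVec(c(h@alphaC0, h@betaC0)) -
              lnBetaVec(c(h@alphaD0, h@betaD0)) -
              lnBetaVec(h@n0))
  ent + trans + params
}

# One full update sweep (multi-network or degenerate single-network mode).
# With holdBeta = TRUE the Beta edge posteriors stay at their priors (the
# warm-up phase: coordinate descent over all blocks except q(theta)).
vbSweep <- function(state, net, expectSingle = FALSE, caches = NULL,
                    holdBeta = FALSE) {
  if (is.null(caches))
    caches <- lapply(seq_along(state@Qt), function(t) likCache(net, t))
  expect <- checkFinite(vbExpectations(state), "expectations")
  if (!expectSingle) {
    state <- vbUpdateRoot(state, expect)
    checkFinite(state@Q, "root assignment update")
    for (t in seq_along(state@Qt)) {
      state <- vbUpdateInstant(state, expect, net, t, cache = caches[[t]])
      checkFinite(state@Qt[[t]], "instantaneous assignment update")
    }
  } else {
    # Degenerate one-network limit: z(1) == z, so the single assignment
    # matrix absorbs both the edge terms and E[ln pi] directly (the
    # transition factor is the identity and contributes nothing).
    Q <- state@Qt[[1L]]
    prior <- matrix(expect$ElnPi, nrow(Q), state@hyper@K, byrow = TRUE)
    Q <- seqAssignmentSweep(Q, expect$eq11, expect$eq12, prior, caches[[1L]])
    checkFinite(Q, "single-network assignment update")
    state@Qt[[1L]] <- Q
    state@Q <- Q
  }
  state <- vbUpdateRootCounts(state)
  checkFinite(state@nTilde, "Dirichlet count update")
  if (!expectSingle)
    for (t in seq_along(state@Qt)) {
      state <- vbUpdateTransitionCounts(state, t)
      checkFinite(state@etaTilde[[t]], "transition count update")
    }
  if (!holdBeta) {
    state <- vbUpdateEdgeCounts(state, net)
    checkFinite(c(state@alphaC, state@betaC, state@alphaD, state@betaD),
                "edge count update")
  }
  state
}

vbRun <- function(net, hyper, opts, single = FALSE, init = NULL, restart = 1L) {
  state <- if (!is.null(init)) init
  else initState(net, hyper, seed = subSeed(opts$seed, 600L + restart))
  state@details$single <- single
  if (single) state@Q <- state@Qt[[1L]]
  caches <- lapply(seq_along(state@Qt), function(t) likCache(net, t))
  for (w in seq_len(opts$warmup %||% 0L))
    state <- vbSweep(state, net, expectSingle = single, caches = caches,
                     holdBeta = TRUE)
  trace <- numeric(0)
  Fold <- Inf; converged <- FALSE
  for (iter in seq_len(opts$maxIter)) {
    state <- vbSweep(state, net, expectSingle = single, caches = caches)
    Fnew <- vbFreeEnergy(state)
    checkFinite(Fnew, "free energy")
    trace <- c(trace, Fnew)
    if (is.finite(Fold) && abs(Fnew - Fold) / max(abs(Fold), 1e-12) < opts$relTol) {
      converged <- TRUE
      break
    }
    Fold <- Fnew
  }
  state@freeEnergyTrace <- if (opts$recordTrace) trace else trace[length(trace)]
  state@details$converged <- converged
  state@details$iterations <- length(trace)
  state@details$restart <- restart
  state
}

#' Fit the multiple-network stochastic block model
#'
#' Runs the closed-form variational Bayes algorithm from several random
#' initializations and returns the state with the lowest final free
#' energy.  Observation masks on the input are honoured: held-out pairs
#' are excluded from every likelihood sum.
#'
#' @param net a \linkS4class{MultiNetwork}.
#' @param K number of modules (ignored when \code{hyper} is given).
#' @param hyper a \linkS4class{Hyperparameters}; defaults to
#'   \code{defaultHyperparameters(K)}.
#' @param opts a \code{\link{fitOptions}} list.
#' @param init optional \linkS4class{VariationalState} to start from; when
#'   supplied, exactly one deterministic pass is run from it (used for
#'   warm starts and reproducibility checks).
#' @return the best \linkS4class{VariationalState}.
#' @examples
#' gp <- generatePlantedPartition(synthSpec(24, 2, c(12, 12), 0.9, 0.05, seed = 3))
#' fit <- fitMultiNet(gp$net, K = 2, opts = fitOptions(nRestarts = 3, seed = 1))
#' hardAssignments(fit, level = 1)
#' @export
fitMultiNet <- function(net, K = NULL, hyper = NULL, opts = fitOptions(),
                        init = NULL) {
  if (is.null(hyper)) {
    if (is.null(K)) stop("supply K or hyper")
    hyper <- defaultHyperparameters(K)
  }
  fitEngine(net, hyper, opts, single = FALSE, init = init)
}

#' Fit the single-network baseline
#'
#' The classical Bayesian stochastic block model for one network, realized
#' as the degenerate one-network limit of the multiple-network model in
#' which the instantaneous assignment coincides with the root assignment
#' (transition matrix fixed at the identity).  The same update engine,
#' edge terms and Beta/Dirichlet posteriors are used, so comparisons with
#' \code{\link{fitMultiNet}} isolate exactly the multi-network coupling.
#'
#' @inheritParams fitMultiNet
#' @return the best \linkS4class{VariationalState}, with \code{Q}
#'   identical to \code{Qt[[1]]}.
#' @export
fitSingleNet <- function(net, K = NULL, hyper = NULL, opts = fitOptions(),
                         init = NULL) {
  if (nNetworks(net) != 1L)
    stop("fitSingleNet requires a single-network MultiNetwork")
  if (is.null(hyper)) {
    if (is.null(K)) stop("supply K or hyper")
    hyper <- defaultHyperparameters(K)
  }
  fitEngine(net, hyper, opts, single = TRUE, init = init)
}

fitEngine <- function(net, hyper, opts, single, init = NULL) {
  if (!is.null(init)) {
    best <- vbRun(net, hyper, opts, single = single, init = init)
  } else {
    best <- NULL
    for (r in seq_len(opts$nRestarts)) {
      cand <- vbRun(net, hyper, opts, single = single, restart = r)
      fC <- cand@freeEnergyTrace[length(cand@freeEnergyTrace)]
      fB <- if (is.null(best)) Inf else best@freeEnergyTrace[length(best@freeEnergyTrace)]
      if (fC < fB) best <- cand
    }
  }
  validObject(best)
  best
}

#' Exact log evidence by exhaustive enumeration (tiny instances)
#'
#' Marginalizes theta, pi and all transition matrices analytically
#' (Beta/Dirichlet normalizer ratios) and sums the remaining discrete
#' assignments exhaustively.  Intended as an inference oracle: the
#' variational free energy upper-bounds the negative of this value.
#'
#' @param net a \linkS4class{MultiNetwork}.
#' @param hyper a \linkS4class{Hyperparameters}.
#' @return the log marginal likelihood ln p(A(1:T) | K).
#' @export
exactLogEvidence <- function(net, hyper) {
  N <- nVertices(net); Tn <- nNetworks(net); K <- hyper@K
  nCombos <- as.double(K)^(N * (Tn + 1))
  if (nCombos > 1e6)
    stop(sprintf("instance too large for enumeration: K^(N(T+1)) = %g > 1e6",
                 nCombos))
  allZ <- as.matrix(expand.grid(rep(list(seq_len(K)), N)))
  nA <- nrow(allZ)
  upper <- upper.tri(matrix(0, N, N))
  # per-assignment, per-network within/between edge and non-edge counts
  cp <- cm <- dp <- dm <- matrix(0, nA, Tn)
  for (a in seq_len(nA)) {
    same <- outer(allZ[a, ], allZ[a, ], "==")[upper]
    for (t in seq_len(Tn)) {
      e <- net@adjacency[[t]][upper]
      cp[a, t] <- sum(e[same]); cm[a, t] <- sum(same) - cp[a, t]
      dp[a, t] <- sum(e[!same]); dm[a, t] <- sum(!same) - dp[a, t]
    }
  }
  # transition Dirichlet normalizer ratio for a (root, instant) pair; the
  # prior is shared across networks so one table serves all t
  lnB0rows <- sum(apply(hyper@eta0, 1L, lnBetaVec))
  trans <- matrix(0, nA, nA)
  for (r in seq_len(nA)) for (a in seq_len(nA)) {
    counts <- hyper@eta0
    for (i in seq_len(N))
      counts[allZ[r, i], allZ[a, i]] <- counts[allZ[r, i], allZ[a, i]] + 1
    trans[r, a] <- sum(apply(counts, 1L, lnBetaVec)) - lnB0rows
  }
  rootTerm <- vapply(seq_len(nA), function(r)
    lnBetaVec(hyper@n0 + tabulate(allZ[r, ], K)) - lnBetaVec(hyper@n0),
    numeric(1))
  tuples <- as.matrix(expand.grid(rep(list(seq_len(nA)), Tn)))
  sumc <- function(M) rowSums(matrix(M[cbind(as.vector(tuples),
                                             rep(seq_len(Tn), each = nrow(tuples)))],
                                     nrow(tuples), Tn))
  scp <- sumc(cp); scm <- sumc(cm); sdp <- sumc(dp); sdm <- sumc(dm)
  thetaTerm <- lgamma(hyper@alphaC0 + scp) + lgamma(hyper@betaC0 + scm) -
    lgamma(hyper@alphaC0 + hyper@betaC0 + scp + scm) -
    lnBetaVec(c(hyper@alphaC0, hyper@betaC0)) +
    lgamma(hyper@alphaD0 + sdp) + lgamma(hyper@betaD0 + sdm) -
    lgamma(hyper@alphaD0 + hyper@betaD0 + sdp + sdm) -
    lnBetaVec(c(hyper@alphaD0, hyper@betaD0))
  perRoot <- vapply(seq_len(nA), function(r) {
    transSum <- rowSums(matrix(trans[r, as.vector(tuples)], nrow(tuples), Tn))
    rootTerm[r] + logSumExp(transSum + thetaTerm)
  }, numeric(1))
  logSumExp(perRoot)
}

#' Choose the number of modules by free energy
#'
#' Fits every candidate K and returns the one whose best restart attains
#' the lowest final free energy (the free energy approximates the negative
#' log evidence).
#'
#' @param net a \linkS4class{MultiNetwork}.
#' @param Ks integer vector of candidate module counts.
#' @param opts a \code{\link{fitOptions}} list.
#' @param hyperFor function mapping K to a \linkS4class{Hyperparameters};
#'   defaults to \code{defaultHyperparameters}.
#' @return list with elements \code{K} (the selected count),
#'   \code{freeEnergy} (named vector over candidates) and \code{fit} (the
#'   winning \linkS4class{VariationalState}).
#' @export
selectK <- function(net, Ks, opts = fitOptions(), hyperFor = defaultHyperparameters) {
  if (length(Ks) == 0L) stop("Ks must contain at least one candidate")
  fits <- lapply(Ks, function(K)
    fitMultiNet(net, hyper = hyperFor(K), opts = opts))
  fe <- vapply(fits, function(s)
    s@freeEnergyTrace[length(s@freeEnergyTrace)], numeric(1))
  names(fe) <- as.character(Ks)
  best <- which.min(fe)
  list(K = as.integer(Ks[best]), freeEnergy = fe, fit = fits[[best]])
}
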
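#' Create a held-out edge-prediction split
#'
#' Randomly holds out \code{(1 - trainRatio) * |E|} edges of one network.
#' Held-out pairs are marked unobserved (excluded from the likelihood
#' during fitting, not set to zero).  Negative test examples are either a
#' matched random sample of non-edges of the same size (\code{"balanced"},
#' the default, which keeps precision-recall baselines comparable across
#' training ratios) or every non-edge pair (\code{"all"}); sampled
#' negatives are likewise marked unobserved.
#'
#' @param net a \linkS4class{MultiNetwork}.
#' @param t index of the network to split (default 1).
#' @param trainRatio fraction of edges kept for training, in (0, 1).
#' @param seed integer seed.
#' @param negatives \code{"balanced"} or \code{"all"}.
#' @return a \linkS4class{HoldoutSplit}.
#' @export
makeHoldout <- function(net, t = 1L, trainRatio, seed = 1L,
                        negatives = c("balanced", "all")) {
  negatives <- match.arg(negatives)
  stopifnot(trainRatio > 0, trainRatio < 1)
  A <- net@adjacency[[t]]
  N <- nrow(A)
  E <- edgeList(A)
  m <- nrow(E)
  nHold <- round((1 - trainRatio) * m)
  if (nHold < 1L) stop("trainRatio leaves no edges to hold out")
  set.seed(subSeed(seed, "holdout"))
  heldIdx <- sample.int(m, nHold)
  held <- E[heldIdx, , drop = FALSE]
  nonIdx <- which(upper.tri(A) & A == 0, arr.ind = TRUE)
  mask <- matrix(TRUE, N, N); diag(mask) <- FALSE
  mask[held] <- FALSE; mask[held[, 2:1, drop = FALSE]] <- FALSE
  if (negatives == "balanced") {
    if (nrow(nonIdx) < nHold)
      stop("fewer non-edges than requested negative examples")
    negSel <- nonIdx[sample.int(nrow(nonIdx), nHold), , drop = FALSE]
    mask[negSel] <- FALSE; mask[negSel[, 2:1, drop = FALSE]] <- FALSE
  } else {
    negSel <- nonIdx
    # scored as negatives but only the held-out edges leave the likelihood
  }
  tp <- data.frame(i = c(held[, 2L], negSel[, 2L]),
                   j = c(held[, 1L], negSel[, 1L]),
                   label = c(rep(1, nrow(held)), rep(0, nrow(negSel))))
  # canonical i > j ordering (edgeList returns i < j columns)
  new("HoldoutSplit", trainMask = mask, testPairs = tp,
      network = as.integer(t), trainRatio = trainRatio,
      seed = as.integer(seed))
}

#' Posterior probability of an edge
#'
#' \code{p(A_ij = 1) = (mC - mD) sum_k Q(t)_ik Q(t)_jk + mD}, where mC and
#' mD are the posterior means of the within- and between-module edge
#' probabilities.  Symmetric in (i, j).
#'
#' @param state a fitted \linkS4class{VariationalState}.
#' @param i,j distinct vertex indices (vectors allowed, recycled
#'   pairwise).
#' @param t index of the network whose assignment posterior is used.
#' @return edge probabilities.
#' @export
edgeProbability <- function(state, i, j, t = 1L) {
  if (any(i == j)) stop("i and j must differ (simple graphs have no self-loops)")
  mC <- state@alphaC / (state@alphaC + state@betaC)
  mD <- state@alphaD / (state@alphaD + state@betaD)
  Qt <- state@Qt[[t]]
  sameModule <- rowSums(Qt[i, , drop = FALSE] * Qt[j, , drop = FALSE])
  (mC - mD) * sameModule + mD
}

#' Fit with held-out pairs removed from the likelihood
#'
#' Applies the split's observation mask to its network and runs the
#' multiple-network fit (or the single-network baseline when the input has
#' one network).  With an all-observed mask the trajectory is identical to
#' the unmasked fit.
#'
#' @param net a \linkS4class{MultiNetwork}.
#' @param split a \linkS4class{HoldoutSplit}.
#' @param K,hyper,opts,init as in \code{\link{fitMultiNet}}.
#' @param single fit the single-network baseline (requires one network).
#' @return the fitted \linkS4class{VariationalState}.
#' @export
fitWithMissing <- function(net, split, K = NULL, hyper = NULL,
                           opts = fitOptions(), init = NULL, single = FALSE) {
  masked <- setObservedMask(net, split@network, split@trainMask)
  deg <- rowSums(vapply(seq_len(nNetworks(masked)),
                        function(t) rowSums(observedMask(masked, t)),
                        numeric(nVertices(masked))))
  if (any(deg == 0))
    warning("some vertices have no observed pairs in any network; their assignments are prior-driven")
  if (single) fitSingleNet(masked, K = K, hyper = hyper, opts = opts, init = init)
  else fitMultiNet(masked, K = K, hyper = hyper, opts = opts, init = init)
}

#' ROC and precision-recall AUC for a held-out split
#'
#' ROC AUC via the midrank (Mann-Whitney) formula, equal to the
#' trapezoidal area under the ROC curve with tied scores handled by
#' midranks; PR AUC as step-wise average precision over descending score
#' thresholds (tied scores processed as one group).
#'
#' @param split a \linkS4class{HoldoutSplit} (provides the labels), or a
#'   0/1 label vector.
#' @param scores predicted probabilities aligned with the test pairs.
#' @return named vector \code{c(aucROC, aucPR)}.
#' @export
evaluateAUC <- function(split, scores) {
  labels <- if (is(split, "HoldoutSplit")) split@testPairs$label else split
  if (length(labels) != length(scores)) stop("labels and scores differ in length")
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  if (nPos == 0L || nNeg == 0L)
    stop("need at least one positive and one negative test example")
  r <- rank(scores)  # midranks for ties
  aucROC <- (sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  grp <- cumsum(!duplicated(sc))
  tpGrp <- tapply(lab, grp, sum); nGrp <- tapply(lab, grp, length)
  tp <- cumsum(tpGrp); nSeen <- cumsum(nGrp)
  prec <- tp / nSeen; rec <- tp / nPos
  aucPR <- sum(diff(c(0, rec)) * prec)
  c(aucROC = aucROC, aucPR = aucPR)
}
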
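# Independent scalar-loop oracles and tiny fixture builders shared by the
# suite.  Oracles deliberately avoid the package's vectorized code paths.

twoCliqueNet <- function() {
  A <- matrix(0, 6, 6)
  for (p in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6)))
    A[p[1], p[2]] <- A[p[2], p[1]] <- 1
  multiNetwork(A)
}

randomTinyNet <- function(N, Tn, p = 0.5, seed = 1) {
  set.seed(seed)
  adj <- replicate(Tn, {
    A <- matrix(0, N, N)
    up <- which(upper.tri(A))
    A[up] <- as.numeric(runif(length(up)) < p)
    A + t(A)
  }, simplify = FALSE)
  multiNetwork(adj)
}

oneHot <- function(labels, K, eps = 0) {
  N <- length(labels)
  M <- matrix(eps / max(K - 1, 1), N, K)
  M[cbind(seq_len(N), labels)] <- 1 - eps
  M / rowSums(M)
}

# pair-by-pair / vertex-by-vertex accumulation of the complete-data
# log-likelihood (reference for jointLogProb)
oracleJointLogProb <- function(net, root, instant, thetaC, thetaD, pi, P) {
  N <- nVertices(net); Tn <- nNetworks(net)
  ll <- 0
  for (t in seq_len(Tn)) {
    zt <- instant[[t]]@labels
    A <- adjacencyMatrix(net, t)
    for (i in seq_len(N)) for (j in seq_len(N)) if (i > j) {
      th <- if (zt[i] == zt[j]) thetaC else thetaD
      ll <- ll + if (A[i, j] == 1) log(th) else log(1 - th)
    }
    for (i in seq_len(N)) ll <- ll + log(P[[t]][root@labels[i], zt[i]])
  }
  for (i in seq_len(N)) ll <- ll + log(pi[root@labels[i]])
  ll
}

# entropy / mutual-information formula coded directly
oracleNMI <- function(a, b) {
  n <- length(a)
  mi <- 0
  for (x in unique(a)) for (y in unique(b)) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0) mi <- mi + pxy * log(pxy / ((sum(a == x) / n) * (sum(b == y) / n)))
  }
  ent <- function(v) {
    h <- 0
    for (x in unique(v)) { p <- sum(v == x) / n; h <- h - p * log(p) }
    h
  }
  d <- max(ent(a), ent(b))
  if (d == 0) 0 else mi / d
}

oracleAccuracy <- function(tab, refSizes) {
  sn_num <- 0
  for (i in seq_len(nrow(tab))) sn_num <- sn_num + max(tab[i, ])
  ppv_num <- 0
  for (j in seq_len(ncol(tab))) ppv_num <- ppv_num + max(tab[, j])
  Sn <- sn_num / sum(refSizes); PPV <- ppv_num / sum(tab)
  c(Sn = Sn, PPV = PPV, Acc = sqrt(Sn * PPV))
}

oracleSeparation <- function(tab) {
  n <- nrow(tab); m <- ncol(tab)
  sep <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    rs <- sum(tab[i, ]); cs <- sum(tab[, j])
    if (rs > 0 && cs > 0) sep <- sep + (tab[i, j] / rs) * (tab[i, j] / cs)
  }
  c(SepRef = sep / m, SepInf = sep / n, Sep = sqrt((sep / m) * (sep / n)))
}

# concordant-pair (rank-statistic) ROC AUC with half-credit for ties
oracleAUC <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# directly coded single-network VB (no transition machinery at all),
# run from a given starting assignment matrix; mirrors the degenerate
# one-network model of the package but shares none of its code.
oracleSingleVB <- function(A, hyper, Q0, maxIter = 200, relTol = 1e-6) {
  N <- nrow(A); K <- hyper@K
  Q <- Q0
  aC <- hyper@alphaC0; bC <- hyper@betaC0
  aD <- hyper@alphaD0; bD <- hyper@betaD0
  nT <- hyper@n0
  lnB <- function(x) sum(lgamma(x)) - lgamma(sum(x))
  Fold <- Inf; trace <- c()
  for (iter in seq_len(maxIter)) {
    ElnPi <- digamma(nT) - digamma(sum(nT))
    eq11 <- digamma(bD) - digamma(aD + bD) - digamma(bC) + digamma(aC + bC)
    eq12 <- digamma(aC) - digamma(bC) - digamma(aD) + digamma(bD)
    for (i in seq_len(N)) {
      lg <- numeric(K)
      for (k in seq_len(K)) {
        s <- 0
        for (j in seq_len(N)) if (j != i)
          s <- s + (eq12 * A[i, j] - eq11) * Q[j, k]
        lg[k] <- s + ElnPi[k]
      }
      w <- exp(lg - max(lg)); Q[i, ] <- w / sum(w)
    }
    nT <- colSums(Q) + hyper@n0
    wE <- 0; wP <- 0
    for (i in seq_len(N)) for (j in seq_len(N)) if (i > j) {
      s <- sum(Q[i, ] * Q[j, ])
      wP <- wP + s; wE <- wE + A[i, j] * s
    }
    E <- sum(A) / 2; Pn <- N * (N - 1) / 2
    aC <- wE + hyper@alphaC0; bC <- wP - wE + hyper@betaC0
    aD <- E - wE + hyper@alphaD0; bD <- (Pn - wP) - (E - wE) + hyper@betaD0
    Fv <- sum(ifelse(Q > 0, Q * log(Q), 0)) -
      (lnB(c(aC, bC)) + lnB(c(aD, bD)) + lnB(nT) -
       lnB(c(hyper@alphaC0, hyper@betaC0)) -
       lnB(c(hyper@alphaD0, hyper@betaD0)) - lnB(hyper@n0))
    trace <- c(trace, Fv)
    if (is.finite(Fold) && abs(Fv - Fold) / max(abs(Fold), 1e-12) < relTol) break
    Fold <- Fv
  }
  list(Q = Q, F = Fv, trace = trace)
}

relDiff <- function(a, b) abs(a - b) / max(abs(a), abs(b), 1e-12)

benchTheta <- paramsFromDegreeTargets(16, 6, 32, 128)
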
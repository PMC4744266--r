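test_that("initialization is row-stochastic, prior-anchored and reproducible", {
  net <- randomTinyNet(8, 2, seed = 5)
  h <- defaultHyperparameters(3)
  st <- initState(net, h, seed = 4)
  expect_equal(rowSums(st@Q), rep(1, 8), tolerance = 1e-12)
  for (t in 1:2) expect_equal(rowSums(st@Qt[[t]]), rep(1, 8), tolerance = 1e-12)
  expect_true(all(st@Q > 0))
  expect_identical(st@nTilde, h@n0)
  expect_identical(c(st@alphaC, st@betaC, st@alphaD, st@betaD),
                   c(h@alphaC0, h@betaC0, h@alphaD0, h@betaD0))
  expect_identical(st@etaTilde[[1]], h@eta0)
  st2 <- initState(net, h, seed = 4)
  expect_identical(st@Q, st2@Q)
  expect_identical(st@Qt, st2@Qt)
  expect_warning(initState(randomTinyNet(3, 1, seed = 1),
                           defaultHyperparameters(5), 1), "K exceeds")
})

test_that("digamma expectations match identities and a Monte-Carlo oracle", {
  net <- randomTinyNet(2, 1, seed = 2)
  h <- defaultHyperparameters(2, n0 = 1)
  st <- initState(net, h, 1)
  ex <- vbExpectations(st)
  # nTilde = (1, 1): E[ln pi_1] = psi(1) - psi(2) = -1
  expect_equal(ex$ElnPi[1], -1)
  # symmetric Beta posteriors zero both log-ratio expectations
  st@alphaC <- st@betaC <- st@alphaD <- st@betaD <- 2.5
  exSym <- vbExpectations(st)
  expect_equal(exSym$eq11, 0)
  expect_equal(exSym$eq12, 0)
  # Monte-Carlo check of E[ln pi_k] under Dirichlet(nTilde)
  st@nTilde <- c(3, 7)
  exMC <- vbExpectations(st)
  set.seed(99)
  nSamp <- 40000
  g1 <- rgamma(nSamp, 3); g2 <- rgamma(nSamp, 7)
  lp <- log(g1 / (g1 + g2))
  expect_lt(abs(mean(lp) - exMC$ElnPi[1]), 3 * sd(lp) / sqrt(nSamp))
  st@alphaC <- -1
  expect_error(vbExpectations(st), "positive")
})

test_that("assignment updates agree with independently coded scalar loops", {
  set.seed(14)
  net <- randomTinyNet(6, 2, seed = 14)
  h <- defaultHyperparameters(3)
  st <- initState(net, h, 3)
  # give the posteriors some arbitrary structure
  st@nTilde <- c(2, 5, 3)
  st@etaTilde <- lapply(1:2, function(t) matrix(runif(9, 1, 6), 3))
  st@alphaC <- 4; st@betaC <- 2; st@alphaD <- 1.5; st@betaD <- 6
  ex <- vbExpectations(st)
  # root update: Q_ik propto exp(E[ln pi_k] + sum_t sum_m Qt_im E[ln P_km])
  upd <- vbUpdateRoot(st, ex)
  for (i in 1:6) {
    lg <- numeric(3)
    for (k in 1:3) {
      s <- ex$ElnPi[k]
      for (t in 1:2) for (m in 1:3)
        s <- s + st@Qt[[t]][i, m] * ex$ElnP[[t]][k, m]
      lg[k] <- s
    }
    expect_equal(upd@Q[i, ], exp(lg - max(lg)) / sum(exp(lg - max(lg))),
                 tolerance = 1e-12)
  }
  # instantaneous update: sequential over vertices, each row seeing the
  # rows already updated before it
  updT <- vbUpdateInstant(upd, ex, net, 1)
  A <- adjacencyMatrix(net, 1)
  Qt <- st@Qt[[1]]
  for (i in 1:6) {
    lg <- numeric(3)
    for (k in 1:3) {
      s <- 0
      for (j in 1:6) if (j != i)
        s <- s + (ex$eq12 * A[i, j] - ex$eq11) * Qt[j, k]
      for (m in 1:3) s <- s + upd@Q[i, m] * ex$ElnP[[1]][m, k]
      lg[k] <- s
    }
    Qt[i, ] <- exp(lg - max(lg)) / sum(exp(lg - max(lg)))
  }
  expect_equal(updT@Qt[[1]], Qt, tolerance = 1e-10)
})

test_that("count updates match their closed forms", {
  net <- twoCliqueNet()
  h <- defaultHyperparameters(2)
  st <- initState(net, h, 1)
  # one-hot Q all in module 1: nTilde = (N + 1, 1)
  st@Q <- oneHot(rep(1, 6), 2)
  expect_equal(vbUpdateRootCounts(st)@nTilde, c(7, 1))
  # uniform Q: N/K + prior
  st@Q <- matrix(0.5, 6, 2)
  expect_equal(vbUpdateRootCounts(st)@nTilde, c(4, 4))
  # random Q: column sums plus prior
  set.seed(2); M <- matrix(rgamma(12, 1), 6, 2); M <- M / rowSums(M)
  st@Q <- M
  expect_equal(vbUpdateRootCounts(st)@nTilde, colSums(M) + h@n0)
  # transition counts: identical one-hot Q and Qt add module sizes on the diagonal
  lab <- c(1, 1, 1, 2, 2, 2)
  st@Q <- oneHot(lab, 2); st@Qt[[1]] <- oneHot(lab, 2)
  eta <- vbUpdateTransitionCounts(st, 1)@etaTilde[[1]]
  expect_equal(eta, h@eta0 + diag(c(3, 3)))
  # added transition mass is always N
  st@Q <- M; st@Qt[[1]] <- oneHot(c(2, 1, 2, 1, 1, 2), 2)
  eta2 <- vbUpdateTransitionCounts(st, 1)@etaTilde[[1]]
  expect_equal(sum(eta2 - h@eta0), 6)
})

test_that("Beta edge-count updates match hand counts and the pair identity", {
  net <- twoCliqueNet()  # two disjoint triangles
  h <- defaultHyperparameters(2)
  st <- initState(net, h, 1)
  st@Qt[[1]] <- oneHot(c(1, 1, 1, 2, 2, 2), 2)
  upd <- vbUpdateEdgeCounts(st, net)
  # 6 within edges, 0 within non-edges, 0 between edges, 9 between non-edges
  expect_equal(upd@alphaC - h@alphaC0, 6)
  expect_equal(upd@betaC - h@betaC0, 0)
  expect_equal(upd@alphaD - h@alphaD0, 0)
  expect_equal(upd@betaD - h@betaD0, 9)
  # uniform Qt with K = 2: expected within-edge count = |E| / 2
  st@Qt[[1]] <- matrix(0.5, 6, 2)
  updU <- vbUpdateEdgeCounts(st, net)
  expect_equal(updU@alphaC - h@alphaC0, 3)
  # the four increments always partition the T N (N-1) / 2 pairs
  net2 <- randomTinyNet(7, 3, seed = 31)
  st2 <- initState(net2, h, 2)
  upd2 <- vbUpdateEdgeCounts(st2, net2)
  inc <- (upd2@alphaC - h@alphaC0) + (upd2@betaC - h@betaC0) +
         (upd2@alphaD - h@alphaD0) + (upd2@betaD - h@betaD0)
  expect_equal(inc, 3 * 7 * 6 / 2)
})

test_that("free energy matches a term-by-term oracle and stays consistent", {
  net <- randomTinyNet(6, 2, seed = 8)
  h <- defaultHyperparameters(2)
  st <- initState(net, h, 5)
  st <- vbUpdateRootCounts(st)
  for (t in 1:2) st <- vbUpdateTransitionCounts(st, t)
  st <- vbUpdateEdgeCounts(st, net)
  lnB <- function(x) sum(lgamma(x)) - lgamma(sum(x))
  ent <- sum(st@Q * log(st@Q))
  for (t in 1:2) ent <- ent + sum(st@Qt[[t]] * log(st@Qt[[t]]))
  trans <- 0
  for (t in 1:2) for (k in 1:2)
    trans <- trans - (lnB(st@etaTilde[[t]][k, ]) - lnB(h@eta0[k, ]))
  params <- -(lnB(c(st@alphaC, st@betaC)) + lnB(c(st@alphaD, st@betaD)) +
              lnB(st@nTilde) - lnB(c(h@alphaC0, h@betaC0)) -
              lnB(c(h@alphaD0, h@betaD0)) - lnB(h@n0))
  expect_equal(vbFreeEnergy(st), ent + trans + params, tolerance = 1e-12)
})

test_that("free energy is non-increasing and bounds the exact log evidence", {
  h <- defaultHyperparameters(2)
  for (s in 1:3) {
    net <- randomTinyNet(4, 2, p = 0.5, seed = 40 + s)
    fit <- fitMultiNet(net, hyper = h, opts = fitOptions(nRestarts = 4, seed = s))
    f <- fit@freeEnergyTrace
    expect_true(all(diff(f) <= 1e-8 * pmax(abs(f[-length(f)]), 1)))
    ev <- exactLogEvidence(net, h)
    expect_gte(f[length(f)], -ev - 1e-8)
  }
  # monotone also at benchmark scale
  gp <- generatePlantedPartition(synthSpec(64, 2, c(32, 32), 0.35, 0.08, seed = 2))
  fit <- fitMultiNet(gp$net, K = 2, opts = fitOptions(nRestarts = 2, seed = 1))
  f <- fit@freeEnergyTrace
  expect_true(all(diff(f) <= 1e-8 * pmax(abs(f[-length(f)]), 1)))
})

test_that("exact log evidence matches closed forms and a Monte-Carlo oracle", {
  h1 <- defaultHyperparameters(1)
  # single vertex, no pairs: probability 1
  one <- multiNetwork(matrix(0, 1, 1))
  expect_equal(exactLogEvidence(one, h1), 0)
  # N = 2, T = 1, K = 1: one Beta-Bernoulli pair
  A <- matrix(0, 2, 2); A[1, 2] <- A[2, 1] <- 1
  net2 <- multiNetwork(A)
  lnB <- function(x) sum(lgamma(x)) - lgamma(sum(x))
  expect_equal(exactLogEvidence(net2, h1),
               lnB(c(h1@alphaC0 + 1, h1@betaC0)) - lnB(c(h1@alphaC0, h1@betaC0)))
  # N = 4, K = 2, T = 1 vs prior-sampling Monte-Carlo estimate
  h2 <- defaultHyperparameters(2)
  net4 <- randomTinyNet(4, 1, seed = 77)
  ev <- exactLogEvidence(net4, h2)
  set.seed(123)
  nSamp <- 20000
  w <- replicate(nSamp, {
    thC <- rbeta(1, h2@alphaC0, h2@betaC0)
    thD <- rbeta(1, h2@alphaD0, h2@betaD0)
    g <- rgamma(2, h2@n0); pi <- g / sum(g)
    P <- t(apply(h2@eta0, 1, function(r) { g <- rgamma(2, r); g / sum(g) }))
    z <- sample(1:2, 4, TRUE, prob = pi)
    z1 <- vapply(z, function(zi) sample(1:2, 1, prob = P[zi, ]), integer(1))
    A <- adjacencyMatrix(net4, 1)
    ll <- 0
    for (i in 1:4) for (j in 1:4) if (i > j) {
      th <- if (z1[i] == z1[j]) thC else thD
      ll <- ll + if (A[i, j] == 1) log(th) else log(1 - th)
    }
    exp(ll)
  })
  se <- sd(w) / sqrt(nSamp)
  expect_lt(abs(exp(ev) - mean(w)), 3 * se)
  # refusal on instances too large to enumerate
  expect_error(exactLogEvidence(randomTinyNet(10, 3, seed = 1),
                                defaultHyperparameters(4)), "too large")
})

test_that("fitting is deterministic and equivariant under label permutation", {
  net <- randomTinyNet(10, 2, p = 0.4, seed = 55)
  h <- defaultHyperparameters(3)
  opts <- fitOptions(nRestarts = 2, seed = 7)
  f1 <- fitMultiNet(net, hyper = h, opts = opts)
  f2 <- fitMultiNet(net, hyper = h, opts = opts)
  expect_identical(f1@Q, f2@Q)
  expect_identical(f1@freeEnergyTrace, f2@freeEnergyTrace)
  # permuting the initialization's module columns permutes the solution
  perm <- c(3, 1, 2)
  st <- initState(net, h, seed = 9)
  stP <- st
  stP@Q <- st@Q[, perm]
  stP@Qt <- lapply(st@Qt, function(M) M[, perm])
  a <- fitMultiNet(net, hyper = h, init = st, opts = fitOptions(seed = 1))
  b <- fitMultiNet(net, hyper = h, init = stP, opts = fitOptions(seed = 1))
  expect_equal(b@Q, a@Q[, perm], tolerance = 1e-9)
  expect_equal(b@nTilde, a@nTilde[perm], tolerance = 1e-9)
  expect_equal(b@freeEnergyTrace, a@freeEnergyTrace, tolerance = 1e-9)
})

test_that("clean disjoint cliques are recovered exactly across two copies", {
  net1 <- twoCliqueNet()
  net <- multiNetwork(list(adjacencyMatrix(net1, 1), adjacencyMatrix(net1, 1)))
  fit <- fitMultiNet(net, K = 2, opts = fitOptions(nRestarts = 4, seed = 3))
  truth <- partition(c(1, 1, 1, 2, 2, 2), K = 2)
  expect_equal(nmi(truth, hardAssignments(fit, "root")), 1)
  for (t in 1:2) expect_equal(nmi(truth, hardAssignments(fit, t)), 1)
})

test_that("posterior edge probabilities recover the generating parameters", {
  th <- c(0.32, 0.06)
  gp <- generatePlantedPartition(synthSpec(256, 4, rep(64, 4), th[1], th[2],
                                           seed = 17))
  A <- adjacencyMatrix(gp$net, 1)
  net <- multiNetwork(list(A, A, A))  # three exact copies
  fit <- fitMultiNet(net, K = 4, opts = fitOptions(nRestarts = 3, seed = 2))
  postC <- fit@alphaC / (fit@alphaC + fit@betaC)
  postD <- fit@alphaD / (fit@alphaD + fit@betaD)
  expect_lt(abs(postC - th[1]), 0.03)
  expect_lt(abs(postD - th[2]), 0.03)
  # posterior dominance and mass conservation
  h <- fit@hyper
  expect_true(all(fit@nTilde >= h@n0))
  expect_true(fit@alphaC >= h@alphaC0 && fit@betaC >= h@betaC0 &&
              fit@alphaD >= h@alphaD0 && fit@betaD >= h@betaD0)
  for (t in 1:3) {
    expect_true(all(fit@etaTilde[[t]] >= h@eta0))
    expect_equal(sum(fit@etaTilde[[t]] - h@eta0), 256)
  }
})

test_that("free-energy model selection recovers the planted module count", {
  gp <- generatePlantedPartition(synthSpec(128, 4, rep(32, 4),
                                           benchTheta[["thetaC"]],
                                           benchTheta[["thetaD"]], seed = 23))
  sel <- selectK(gp$net, c(2, 4, 8), opts = fitOptions(nRestarts = 3, seed = 5))
  expect_equal(sel$K, 4L)
  selOne <- selectK(gp$net, 3, opts = fitOptions(nRestarts = 1, seed = 1,
                                                 maxIter = 20))
  expect_equal(selOne$K, 3L)
  expect_error(selectK(gp$net, integer(0)), "at least one")
})
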
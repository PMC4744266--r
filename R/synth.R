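#' Edge probabilities from degree targets
#'
#' Solves the planted-partition calibration used throughout the synthetic
#' benchmarks: given a target mean degree and a target mean number of
#' between-module edges per vertex, with equally sized modules, the
#' within- and between-module edge probabilities are
#' \code{thetaC = (avgDegree - avgBetweenDegree) / (moduleSize - 1)} and
#' \code{thetaD = avgBetweenDegree / (N - moduleSize)}.
#'
#' @param avgDegree target mean degree (e.g. 16).
#' @param avgBetweenDegree target mean between-module degree (e.g. 6).
#' @param moduleSize vertices per module.
#' @param N total number of vertices.
#' @return named numeric vector \code{c(thetaC = , thetaD = )}.
#' @examples
#' paramsFromDegreeTargets(16, 6, 32, 128)  # c(10/31, 6/96)
#' @export
paramsFromDegreeTargets <- function(avgDegree, avgBetweenDegree, moduleSize, N) {
  if (avgBetweenDegree <= 0 || avgBetweenDegree >= avgDegree)
    stop("need 0 < avgBetweenDegree < avgDegree")
  if (moduleSize >= N) stop("moduleSize must be smaller than N")
  thetaC <- (avgDegree - avgBetweenDegree) / (moduleSize - 1)
  thetaD <- avgBetweenDegree / (N - moduleSize)
  if (thetaC < 0 || thetaC > 1 || thetaD < 0 || thetaD > 1)
    stop("degree targets imply an edge probability outside [0, 1]")
  if (thetaD > thetaC)
    stop("degree targets imply thetaD > thetaC (no assortative structure)")
  c(thetaC = thetaC, thetaD = thetaD)
}

#' Specification of a planted-partition generator
#'
#' @param N number of vertices.
#' @param K number of modules.
#' @param moduleSizes K-vector of exact module sizes summing to N, or NULL
#'   to sample labels from a multinomial with \code{assignProbs}.
#' @param thetaC,thetaD within/between-module edge probabilities.
#' @param assignProbs multinomial label probabilities (used only when
#'   \code{moduleSizes} is NULL); defaults to equal weights.
#' @param seed integer seed.
#' @return a validated list.
#' @export
synthSpec <- function(N, K, moduleSizes = NULL, thetaC, thetaD,
                      assignProbs = NULL, seed = 1L) {
  stopifnot(N >= 2, K >= 1, thetaD >= 0, thetaC >= thetaD, thetaC <= 1)
  if (!is.null(moduleSizes)) {
    stopifnot(length(moduleSizes) == K)
    if (sum(moduleSizes) != N) stop("moduleSizes must sum to N")
  }
  if (is.null(assignProbs)) assignProbs <- rep(1 / K, K)
  list(N = as.integer(N), K = as.integer(K), moduleSizes = moduleSizes,
       thetaC = thetaC, thetaD = thetaD, assignProbs = assignProbs,
       seed = as.integer(seed))
}

#' Generate one planted-partition network
#'
#' Vertices receive ground-truth module labels (fixed sizes by default, or
#' multinomial sampling), then every unordered pair is connected
#' independently with probability \code{thetaC} inside a module and
#' \code{thetaD} across modules.
#'
#' @param spec a \code{\link{synthSpec}}.
#' @return list with elements \code{net} (a single-network
#'   \linkS4class{MultiNetwork}) and \code{truth} (the ground-truth
#'   \linkS4class{Partition}).
#' @examples
#' gp <- generatePlantedPartition(synthSpec(20, 2, c(10, 10), 0.8, 0.1, seed = 7))
#' gp$truth
#' @export
generatePlantedPartition <- function(spec) {
  N <- spec$N; K <- spec$K
  set.seed(subSeed(spec$seed, "assign"))
  labels <- if (!is.null(spec$moduleSizes))
    rep(seq_len(K), times = spec$moduleSizes)
  else sample.int(K, N, replace = TRUE, prob = spec$assignProbs)
  set.seed(subSeed(spec$seed, "edges"))
  A <- matrix(0, N, N)
  up <- which(upper.tri(A))
  same <- outer(labels, labels, "==")[up]
  p <- ifelse(same, spec$thetaC, spec$thetaD)
  A[up] <- as.numeric(stats::runif(length(up)) < p)
  A <- A + t(A)
  list(net = multiNetwork(A), truth = partition(labels, K = K))
}

# Internal: edge matrix (m x 2, i < j) of a single-network adjacency.
edgeList <- function(A) {
  idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

#' Degree-preserving Maslov-Sneppen rewiring
#'
#' Randomizes a simple undirected graph while preserving every vertex
#' degree: repeatedly pick two distinct edges (i, j) and (k, l) (with
#' random endpoint orientation) and replace them by (i, l) and (j, k),
#' rejecting the swap whenever it would create a self-loop or an edge that
#' already exists.  \code{fraction} is the fraction of edges rewired: each
#' successful swap rewires two edges, so the quota is
#' \code{round(fraction * |E| / 2)} successful swaps, and only successful
#' swaps count, so the requested noise level is attained deterministically.
#'
#' @param net a single-network \linkS4class{MultiNetwork}.
#' @param fraction fraction of edges to rewire, in [0, 1].
#' @param seed integer seed.
#' @return a rewired single-network \linkS4class{MultiNetwork} with the
#'   same degree sequence and edge count.
#' @export
maslovSneppenRewire <- function(net, fraction, seed = 1L) {
  stopifnot(nNetworks(net) == 1L, fraction >= 0, fraction <= 1)
  A <- net@adjacency[[1L]]
  E <- edgeList(A)
  m <- nrow(E)
  quota <- round(fraction * m / 2)
  if (quota == 0L) return(net)
  if (m < 2L) stop("need at least two edges to rewire")
  set.seed(subSeed(seed, "rewire"))
  done <- 0L; proposals <- 0L; guard <- 1000 * quota
  while (done < quota) {
    proposals <- proposals + 1L
    if (proposals > guard)
      stop(sprintf("rewiring failed to reach %d swaps after %d proposals",
                   quota, proposals - 1L))
    e <- sample.int(m, 2L)
    e1 <- E[e[1L], ]; e2 <- E[e[2L], ]
    if (stats::runif(1) < 0.5) e1 <- rev(e1)
    if (stats::runif(1) < 0.5) e2 <- rev(e2)
    i <- e1[1L]; j <- e1[2L]; k <- e2[1L]; l <- e2[2L]
    # proposed crossing: i-l and j-k
    if (i == l || j == k) next
    if (A[i, l] == 1 || A[j, k] == 1) next
    A[i, j] <- A[j, i] <- 0; A[k, l] <- A[l, k] <- 0
    A[i, l] <- A[l, i] <- 1; A[j, k] <- A[k, j] <- 1
    E[e[1L], ] <- sort(c(i, l)); E[e[2L], ] <- sort(c(j, k))
    done <- done + 1L
  }
  multiNetwork(A, vertexIds = vertexIds(net))
}

#' Graded-noise benchmark: T rewired copies at increasing fractions
#'
#' Draws one planted-partition network and produces T observations by
#' independently rewiring it at fractions growing linearly from 5\% to
#' 50\% of the edges (for the default \code{T = 10}, fractions 0.05,
#' 0.10, ..., 0.50).
#'
#' @param spec a \code{\link{synthSpec}} for the ground-truth draw.
#' @param T number of noisy observations.
#' @return list with \code{net} (T-network \linkS4class{MultiNetwork}),
#'   \code{truth} (\linkS4class{Partition}) and \code{fractions}.
#' @export
generateExperimentOne <- function(spec, T = 10L) {
  fractions <- seq(0.05, 0.50, length.out = T)
  gp <- generatePlantedPartition(spec)
  nets <- lapply(seq_len(T), function(t)
    maslovSneppenRewire(gp$net, fractions[t],
                        seed = subSeed(spec$seed, 1000L + t))@adjacency[[1L]])
  list(net = multiNetwork(nets, vertexIds = vertexIds(gp$net)),
       truth = gp$truth, fractions = fractions)
}

#' Constant-noise benchmark: T independent rewired copies
#'
#' Draws one planted-partition network and produces T observations by
#' independently rewiring the same constant fraction (default 25\%) of its
#' edges, so every observation carries the same noise level.
#'
#' @param spec a \code{\link{synthSpec}} for the ground-truth draw.
#' @param T number of noisy observations.
#' @param fraction fraction of edges rewired in each observation.
#' @return list with \code{net}, \code{truth} and \code{fractions}.
#' @export
generateExperimentTwo <- function(spec, T = 10L, fraction = 0.25) {
  gp <- generatePlantedPartition(spec)
  nets <- lapply(seq_len(T), function(t)
    maslovSneppenRewire(gp$net, fraction,
                        seed = subSeed(spec$seed, 2000L + t))@adjacency[[1L]])
  list(net = multiNetwork(nets, vertexIds = vertexIds(gp$net)),
       truth = gp$truth, fractions = rep(fraction, T))
}
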
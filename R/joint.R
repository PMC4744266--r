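#' Joint log-probability of networks and assignments
#'
#' Log of the complete-data likelihood of the multiple-network stochastic
#' block model: over unordered pairs i > j of each network, edges occur
#' with probability theta_c when the instantaneous labels agree and
#' theta_d otherwise; each vertex's instantaneous label arises from its
#' root label through the network's transition matrix; root labels are
#' multinomial with probabilities pi.
#'
#' @param net a \linkS4class{MultiNetwork} with T networks.
#' @param root \linkS4class{Partition} of root labels z.
#' @param instant list of T \linkS4class{Partition}s of instantaneous
#'   labels z(t).
#' @param thetaC,thetaD within/between-module edge probabilities, strictly
#'   inside (0, 1).
#' @param pi K-vector of root assignment probabilities (sums to 1).
#' @param P list of T row-stochastic K x K transition matrices.
#' @return the joint log-probability (may be \code{-Inf} when a structural
#'   zero of \code{pi} or \code{P} is used by the assignments).
#' @examples
#' a <- matrix(1, 3, 3) - diag(3)
#' net <- multiNetwork(a)
#' z <- partition(c(1, 1, 1), K = 1)
#' jointLogProb(net, z, list(z), 0.5, 0.1, 1, list(matrix(1, 1, 1)))
#' @export
jointLogProb <- function(net, root, instant, thetaC, thetaD, pi, P) {
  Tn <- nNetworks(net); N <- nVertices(net); K <- root@K
  if (thetaC <= 0 || thetaC >= 1 || thetaD <= 0 || thetaD >= 1)
    stop("thetaC and thetaD must lie strictly inside (0, 1)")
  if (length(instant) != Tn || length(P) != Tn)
    stop("need one instantaneous partition and one transition matrix per network")
  if (length(root@labels) != N || length(pi) != K)
    stop("dimension mismatch between network, root partition and pi")
  cp <- cm <- dp <- dm <- 0
  upper <- upper.tri(matrix(0, N, N))
  for (t in seq_len(Tn)) {
    zt <- instant[[t]]@labels
    if (length(zt) != N) stop(sprintf("instant[[%d]] has wrong length", t))
    same <- outer(zt, zt, "==")[upper]
    a <- net@adjacency[[t]][upper]
    cp <- cp + sum(a[same]);        cm <- cm + sum(same) - sum(a[same])
    dp <- dp + sum(a[!same]);       dm <- dm + sum(!same) - sum(a[!same])
  }
  edgeTerm <- cp * log(thetaC) + cm * log1p(-thetaC) +
              dp * log(thetaD) + dm * log1p(-thetaD)
  transTerm <- 0
  for (t in seq_len(Tn)) {
    Pt <- P[[t]]
    if (!all(dim(Pt) == K)) stop(sprintf("P[[%d]] must be %d x %d", t, K, K))
    transTerm <- transTerm + sum(log(Pt[cbind(root@labels, instant[[t]]@labels)]))
  }
  nk <- tabulate(root@labels, K)
  rootTerm <- sum(ifelse(nk > 0, nk * log(pi), 0))
  edgeTerm + transTerm + rootTerm
}

#' Hard module assignments from a variational state
#'
#' Assigns every vertex to the module maximizing its posterior assignment
#' probability, at the root level or for one network.  Ties are broken by
#' the lowest module index so results are reproducible.
#'
#' @param state a \linkS4class{VariationalState}.
#' @param level \code{"root"} for the root assignment Q, or a network
#'   index t for the instantaneous assignment Q(t).
#' @return a \linkS4class{Partition}.
#' @export
hardAssignments <- function(state, level = "root") {
  M <- if (identical(level, "root")) state@Q
  else {
    t <- suppressWarnings(as.integer(level))
    if (is.na(t) || t < 1L || t > length(state@Qt))
      stop("level must be \"root\" or a network index")
    state@Qt[[t]]
  }
  # max.col with ties.method = "first" == argmax with lowest-index tie-break
  partition(max.col(M, ties.method = "first"), K = state@hyper@K,
            vertexIds = state@details$vertexIds %||% character())
}
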
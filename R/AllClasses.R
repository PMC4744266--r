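#' @import methods
NULL

#' Multiple networks on a shared vertex set
#'
#' Container for T undirected, simple, binary networks observed on the same
#' N vertices, stored as symmetric 0/1 adjacency matrices with zero
#' diagonals.  An optional per-network observation mask marks which vertex
#' pairs enter the likelihood; pairs with \code{FALSE} are treated as
#' missing (held out), not as non-edges.
#'
#' @slot adjacency list of T symmetric binary N x N matrices.
#' @slot vertexIds character vector of N vertex labels, shared by all
#'   networks in the same order.
#' @slot mask list of length 0 (all pairs observed) or T symmetric logical
#'   N x N matrices with \code{FALSE} diagonals.
#' @export
setClass("MultiNetwork",
  representation(adjacency = "list", vertexIds = "character", mask = "list"))

setValidity("MultiNetwork", function(object) {
  A <- object@adjacency
  if (length(A) < 1L) return("at least one network required")
  N <- length(object@vertexIds)
  if (anyDuplicated(object@vertexIds)) return("duplicated vertex ids")
  for (t in seq_along(A)) {
    a <- A[[t]]
    if (!is.matrix(a) || !all(dim(a) == N))
      return(sprintf("network %d: adjacency must be %d x %d", t, N, N))
    if (!all(a %in% c(0, 1))) return(sprintf("network %d: entries not in {0,1}", t))
    if (!isTRUE(all.equal(a, t(a)))) return(sprintf("network %d: not symmetric", t))
    if (any(diag(a) != 0)) return(sprintf("network %d: nonzero diagonal", t))
  }
  if (length(object@mask) > 0L) {
    if (length(object@mask) != length(A))
      return("mask must have one entry per network")
    for (t in seq_along(object@mask)) {
      m <- object@mask[[t]]
      if (!is.matrix(m) || !is.logical(m) || !all(dim(m) == N))
        return(sprintf("mask %d: must be a logical %d x %d matrix", t, N, N))
      if (!identical(m, t(m))) return(sprintf("mask %d: not symmetric", t))
      if (any(diag(m))) return(sprintf("mask %d: diagonal must be FALSE", t))
    }
  }
  TRUE
})

#' Prior hyperparameters of the multiple-network stochastic block model
#'
#' Conjugate prior pseudo-counts: a Dirichlet prior on the root module
#' proportions pi, Beta priors on the within- (theta_c) and between-module
#' (theta_d) edge probabilities, and a shared Dirichlet prior on each row of
#' every transition matrix P(t).
#'
#' @slot K number of modules.
#' @slot n0 K-vector of positive Dirichlet pseudo-counts for pi.
#' @slot alphaC0,betaC0 positive Beta parameters for theta_c.
#' @slot alphaD0,betaD0 positive Beta parameters for theta_d.
#' @slot eta0 K x K matrix of positive Dirichlet pseudo-counts; row k is the
#'   prior for row k of every transition matrix.
#' @export
setClass("Hyperparameters",
  representation(K = "integer", n0 = "numeric",
                 alphaC0 = "numeric", betaC0 = "numeric",
                 alphaD0 = "numeric", betaD0 = "numeric",
                 eta0 = "matrix"))

setValidity("Hyperparameters", function(object) {
  K <- object@K
  if (K < 1L) return("K must be >= 1")
  if (length(object@n0) != K || any(object@n0 <= 0)) return("n0 must be K positive values")
  for (nm in c("alphaC0", "betaC0", "alphaD0", "betaD0"))
    if (length(slot(object, nm)) != 1L || slot(object, nm) <= 0)
      return(sprintf("%s must be a single positive value", nm))
  if (!all(dim(object@eta0) == K) || any(object@eta0 <= 0))
    return("eta0 must be a K x K matrix of positive values")
  TRUE
})

#' Variational posterior state
#'
#' The mean-field posterior of the multiple-network SBM: soft assignment
#' matrices for the root partition (Q) and each instantaneous partition
#' (Qt), together with the posterior pseudo-counts of all conjugate
#' parameter posteriors and the free-energy trace of the fit.
#'
#' @slot Q N x K row-stochastic matrix, row i = q(z_i = k).
#' @slot Qt list of T N x K row-stochastic matrices, q(z_i^(t) = k).
#' @slot nTilde posterior Dirichlet counts for pi.
#' @slot etaTilde list of T K x K posterior Dirichlet count matrices for
#'   the transition rows.
#' @slot alphaC,betaC,alphaD,betaD posterior Beta parameters of theta_c
#'   and theta_d.
#' @slot freeEnergyTrace free energy after each full iteration.
#' @slot hyper the \linkS4class{Hyperparameters} the state was fitted under.
#' @slot details list of fit metadata (seed, restart index, convergence).
#' @export
setClass("VariationalState",
  representation(Q = "matrix", Qt = "list", nTilde = "numeric",
                 etaTilde = "list", alphaC = "numeric", betaC = "numeric",
                 alphaD = "numeric", betaD = "numeric",
                 freeEnergyTrace = "numeric", hyper = "Hyperparameters",
                 details = "list"))

setValidity("VariationalState", function(object) {
  K <- object@hyper@K
  rowTol <- 1e-10
  checkRows <- function(M, what) {
    if (ncol(M) != K) return(sprintf("%s must have K = %d columns", what, K))
    if (any(M < 0)) return(sprintf("%s has negative entries", what))
    if (max(abs(rowSums(M) - 1)) > rowTol)
      return(sprintf("rows of %s must sum to 1 within %g", what, rowTol))
    TRUE
  }
  ok <- checkRows(object@Q, "Q"); if (!isTRUE(ok)) return(ok)
  for (t in seq_along(object@Qt)) {
    ok <- checkRows(object@Qt[[t]], sprintf("Qt[[%d]]", t))
    if (!isTRUE(ok)) return(ok)
  }
  h <- object@hyper
  tol <- 1e-8
  if (any(object@nTilde < h@n0 - tol)) return("nTilde below its prior")
  if (object@alphaC < h@alphaC0 - tol || object@betaC < h@betaC0 - tol ||
      object@alphaD < h@alphaD0 - tol || object@betaD < h@betaD0 - tol)
    return("Beta posterior parameter below its prior")
  for (t in seq_along(object@etaTilde))
    if (any(object@etaTilde[[t]] < h@eta0 - tol))
      return(sprintf("etaTilde[[%d]] below its prior", t))
  f <- object@freeEnergyTrace
  if (length(f) > 1L) {
    rel <- diff(f) / pmax(abs(f[-length(f)]), 1)
    if (any(rel > 1e-8)) return("free-energy trace increases beyond tolerance")
  }
  TRUE
})

#' Hard module assignment of N vertices
#'
#' @slot labels integer vector of module labels in 1..K.
#' @slot K number of modules the labels are drawn from.
#' @slot vertexIds character vector of vertex labels (may be empty).
#' @export
setClass("Partition",
  representation(labels = "integer", K = "integer", vertexIds = "character"))

setValidity("Partition", function(object) {
  if (any(object@labels < 1L) || any(object@labels > object@K))
    return("labels must lie in 1..K")
  if (length(object@vertexIds) > 0L &&
      length(object@vertexIds) != length(object@labels))
    return("vertexIds length must match labels")
  TRUE
})

#' A collection of vertex-id sets (reference or predicted complexes)
#'
#' @slot complexes list of non-empty character vectors of vertex ids;
#'   overlaps between sets are permitted.
#' @slot name label for the collection.
#' @export
setClass("ComplexSet",
  representation(complexes = "list", name = "character"))

setValidity("ComplexSet", function(object) {
  if (length(object@complexes) < 1L) return("at least one complex required")
  for (i in seq_along(object@complexes)) {
    v <- object@complexes[[i]]
    if (!is.character(v) || length(v) == 0L)
      return(sprintf("complex %d must be a non-empty character vector", i))
    if (anyDuplicated(v)) return(sprintf("complex %d has duplicated members", i))
  }
  TRUE
})

#' Reference-by-predicted overlap counts
#'
#' Entry (i, j) counts vertices shared by reference complex i and predicted
#' complex j; used by the Sn/PPV/Acc and Sep metrics.
#'
#' @slot counts n x m matrix of non-negative integers.
#' @slot refSizes sizes of the n reference complexes.
#' @export
setClass("ContingencyTable",
  representation(counts = "matrix", refSizes = "numeric"))

setValidity("ContingencyTable", function(object) {
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (length(object@refSizes) != nrow(object@counts))
    return("refSizes must match the number of rows")
  TRUE
})

#' Held-out edge-prediction split for one network
#'
#' @slot trainMask symmetric logical N x N matrix of observed pairs
#'   (FALSE diagonal); FALSE entries are removed from the likelihood.
#' @slot testPairs data.frame with columns i, j (i > j) and label in {0,1}.
#' @slot network index of the network the split applies to.
#' @slot trainRatio fraction of edges kept for training.
#' @slot seed integer seed the split was drawn with.
#' @export
setClass("HoldoutSplit",
  representation(trainMask = "matrix", testPairs = "data.frame",
                 network = "integer", trainRatio = "numeric", seed = "integer"))

setValidity("HoldoutSplit", function(object) {
  m <- object@trainMask
  if (!is.logical(m) || !identical(m, t(m)) || any(diag(m)))
    return("trainMask must be symmetric logical with FALSE diagonal")
  tp <- object@testPairs
  if (!all(c("i", "j", "label") %in% names(tp)))
    return("testPairs needs columns i, j, label")
  if (nrow(tp) > 0L) {
    if (any(tp$i <= tp$j)) return("testPairs must be in canonical i > j order")
    if (!all(tp$label %in% c(0, 1))) return("labels must be 0/1")
    pos <- tp$label == 1
    if (any(m[cbind(tp$i[pos], tp$j[pos])]))
      return("a held-out edge is still marked observed")
  }
  if (object@trainRatio <= 0 || object@trainRatio >= 1)
    return("trainRatio must be in (0, 1)")
  TRUE
})
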
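#' Construct a MultiNetwork
#'
#' @param adjacency a single symmetric binary matrix or a list of them, all
#'   of the same dimension. Dimnames, if any, are ignored; vertex identity
#'   comes from \code{vertexIds}.
#' @param vertexIds optional character vector of vertex labels; defaults to
#'   \code{v001, v002, ...}.
#' @param mask optional list of symmetric logical matrices (one per
#'   network) marking observed pairs; omit for fully observed networks.
#' @return a \linkS4class{MultiNetwork}.
#' @examples
#' a <- matrix(0, 3, 3); a[1, 2] <- a[2, 1] <- 1
#' multiNetwork(list(a, a))
#' @export
multiNetwork <- function(adjacency, vertexIds = NULL, mask = list()) {
  if (is.matrix(adjacency)) adjacency <- list(adjacency)
  adjacency <- lapply(adjacency, function(a) {
    a <- unname(as.matrix(a)); storage.mode(a) <- "double"; a
  })
  N <- nrow(adjacency[[1L]])
  if (is.null(vertexIds)) vertexIds <- sprintf("v%03d", seq_len(N))
  if (length(mask) > 0L) mask <- lapply(mask, function(m) unname(m))
  new("MultiNetwork", adjacency = adjacency,
      vertexIds = as.character(vertexIds), mask = mask)
}

#' Number of vertices / networks
#' @param x a \linkS4class{MultiNetwork}.
#' @return integer count.
#' @export
nVertices <- function(x) length(x@vertexIds)

#' @rdname nVertices
#' @export
nNetworks <- function(x) length(x@adjacency)

#' Extract one adjacency matrix
#' @param x a \linkS4class{MultiNetwork}.
#' @param t network index.
#' @return the N x N adjacency matrix of network \code{t}.
#' @export
adjacencyMatrix <- function(x, t = 1L) x@adjacency[[t]]

#' Vertex labels of a MultiNetwork
#' @param x a \linkS4class{MultiNetwork}.
#' @export
vertexIds <- function(x) x@vertexIds

#' Observation mask of one network
#'
#' @param x a \linkS4class{MultiNetwork}.
#' @param t network index.
#' @return symmetric logical matrix of observed pairs (FALSE diagonal);
#'   all-TRUE off-diagonal when no mask is set.
#' @export
observedMask <- function(x, t = 1L) {
  N <- nVertices(x)
  if (length(x@mask) == 0L) {
    m <- matrix(TRUE, N, N); diag(m) <- FALSE; m
  } else x@mask[[t]]
}

#' Restrict a network's likelihood to observed pairs
#'
#' Attaches an observation mask to network \code{t}; masked-out pairs are
#' excluded from every likelihood sum during fitting (missing at random),
#' not treated as non-edges.
#'
#' @param x a \linkS4class{MultiNetwork}.
#' @param t network index.
#' @param mask symmetric logical matrix, FALSE marking held-out pairs.
#' @return the updated \linkS4class{MultiNetwork}.
#' @export
setObservedMask <- function(x, t, mask) {
  N <- nVertices(x)
  if (length(x@mask) == 0L)
    x@mask <- replicate(nNetworks(x), {
      m <- matrix(TRUE, N, N); diag(m) <- FALSE; m
    }, simplify = FALSE)
  x@mask[[t]] <- unname(mask)
  validObject(x)
  x
}

#' Default prior hyperparameters
#'
#' Encodes the two structural biases of the model: the Beta priors favour a
#' larger within-module than between-module edge probability
#' (theta_c > theta_d a priori), and the transition-row Dirichlet priors
#' put extra mass on the diagonal so instantaneous assignments tend to
#' agree with the root assignment.  Magnitudes are engineering defaults;
#' every value is overridable.
#'
#' @param K number of modules.
#' @param n0 Dirichlet pseudo-counts for pi (scalar recycled to length K).
#' @param alphaC0,betaC0 Beta prior for the within-module edge probability.
#' @param alphaD0,betaD0 Beta prior for the between-module edge probability.
#' @param etaDiag,etaOff diagonal and off-diagonal entries of the
#'   transition-row Dirichlet prior.
#' @return a \linkS4class{Hyperparameters}.
#' @examples
#' defaultHyperparameters(4)
#' @export
defaultHyperparameters <- function(K, n0 = 1, alphaC0 = 2, betaC0 = 1,
                                   alphaD0 = 1, betaD0 = 2,
                                   etaDiag = 5, etaOff = 1) {
  K <- as.integer(K)
  eta0 <- matrix(etaOff, K, K); diag(eta0) <- etaDiag
  new("Hyperparameters", K = K, n0 = rep_len(as.numeric(n0), K),
      alphaC0 = as.numeric(alphaC0), betaC0 = as.numeric(betaC0),
      alphaD0 = as.numeric(alphaD0), betaD0 = as.numeric(betaD0),
      eta0 = eta0)
}

#' Construct a Partition
#' @param labels integer module labels in 1..K.
#' @param K number of modules (defaults to \code{max(labels)}).
#' @param vertexIds optional vertex labels.
#' @export
partition <- function(labels, K = max(labels), vertexIds = character()) {
  new("Partition", labels = as.integer(labels), K = as.integer(K),
      vertexIds = as.character(vertexIds))
}

#' Construct a ComplexSet
#' @param complexes list of character vectors of vertex ids.
#' @param name label for the collection.
#' @export
complexSet <- function(complexes, name = "complexes") {
  new("ComplexSet", complexes = lapply(complexes, as.character),
      name = name)
}

#' Fit options for the variational Bayes algorithms
#'
#' @param maxIter maximum number of full update sweeps per restart.
#' @param relTol convergence threshold on the relative free-energy change.
#' @param nRestarts number of random initializations; the restart with the
#'   lowest final free energy is returned. The posterior is multi-modal, so
#'   production runs should use many restarts (default 100).
#' @param seed integer seed; every restart derives its own sub-seed.
#' @param recordTrace keep the per-iteration free-energy trace.
#' @param warmup number of initial sweeps during which the edge-probability
#'   posteriors are held at their priors.  The assortative prior
#'   (theta_c > theta_d) then drives the assignment updates while module
#'   structure organizes; without this the expected edge counts of a still
#'   unstructured assignment equalize the two posteriors after the first
#'   sweep and the edge signal vanishes.  Warm-up sweeps are part of the
#'   (deterministic, seeded) initialization; the free-energy trace starts
#'   after them.
#' @return a list of validated options.
#' @export
fitOptions <- function(maxIter = 500L, relTol = 1e-6, nRestarts = 100L,
                       seed = 1L, recordTrace = TRUE, warmup = 10L) {
  stopifnot(maxIter >= 1L, relTol > 0, nRestarts >= 1L, warmup >= 0L)
  list(maxIter = as.integer(maxIter), relTol = relTol,
       nRestarts = as.integer(nRestarts), seed = as.integer(seed),
       recordTrace = isTRUE(recordTrace), warmup = as.integer(warmup))
}

#' @export
setMethod("show", "MultiNetwork", function(object) {
  edges <- vapply(object@adjacency, function(a) sum(a) / 2, numeric(1))
  cat(sprintf("MultiNetwork: %d networks on %d shared vertices\n",
              nNetworks(object), nVertices(object)))
  cat("  edges per network:", paste(edges, collapse = ", "), "\n")
  if (length(object@mask) > 0L)
    cat("  observation masks present (held-out pairs excluded from likelihood)\n")
})

setMethod("show", "Hyperparameters", function(object) {
  cat(sprintf("Hyperparameters (K = %d)\n", object@K))
  cat(sprintf("  pi ~ Dirichlet(n0); n0[1] = %g\n", object@n0[1]))
  cat(sprintf("  theta_c ~ Beta(%g, %g); theta_d ~ Beta(%g, %g)\n",
              object@alphaC0, object@betaC0, object@alphaD0, object@betaD0))
  cat(sprintf("  transition rows ~ Dirichlet(diag %g, off-diag %g)\n",
              object@eta0[1, 1], if (object@K > 1) object@eta0[1, 2] else NA))
})

setMethod("show", "VariationalState", function(object) {
  f <- object@freeEnergyTrace
  cat(sprintf("VariationalState: N = %d, K = %d, T = %d networks\n",
              nrow(object@Q), object@hyper@K, length(object@Qt)))
  if (length(f) > 0L)
    cat(sprintf("  free energy %.4f after %d iterations\n", f[length(f)], length(f)))
  if (length(object@details) > 0L && !is.null(object@details$converged))
    cat(sprintf("  converged: %s (restart %s)\n", object@details$converged,
                object@details$restart %||% NA))
})

setMethod("show", "Partition", function(object) {
  tab <- tabulate(object@labels, object@K)
  cat(sprintf("Partition of %d vertices into K = %d modules (%d occupied)\n",
              length(object@labels), object@K, sum(tab > 0)))
  cat("  module sizes:", paste(tab, collapse = ", "), "\n")
})

setMethod("show", "ComplexSet", function(object) {
  sizes <- lengths(object@complexes)
  cat(sprintf("ComplexSet '%s': %d complexes, sizes %d-%d (median %g)\n",
              object@name, length(sizes), min(sizes), max(sizes),
              stats::median(sizes)))
})
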
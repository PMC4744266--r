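#' Normalized mutual information between two partitions
#'
#' Mutual information of the empirical joint label distribution (natural
#' logarithm), normalized by the larger of the two marginal entropies.
#' Returns 0 when both partitions are single-cluster (MI and both
#' entropies are 0; the 0/0 is defined as 0).
#'
#' @param truth,pred \linkS4class{Partition}s (or plain label vectors) of
#'   equal length.
#' @return NMI in [0, 1].
#' @examples
#' nmi(c(1, 1, 2, 2), c(1, 1, 2, 2))  # 1
#' nmi(c(1, 1, 2, 2), c(1, 2, 1, 2))  # 0
#' @export
nmi <- function(truth, pred) {
  a <- if (is(truth, "Partition")) truth@labels else as.integer(truth)
  b <- if (is(pred, "Partition")) pred@labels else as.integer(pred)
  if (length(a) != length(b)) stop("partitions must have equal length")
  n <- length(a)
  joint <- table(a, b) / n
  pa <- rowSums(joint); pb <- colSums(joint)
  mi <- sum(ifelse(joint > 0, joint * log(joint / outer(pa, pb)), 0))
  H <- function(p) -sum(ifelse(p > 0, p * log(p), 0))
  denom <- max(H(pa), H(pb))
  if (denom == 0) return(0)
  mi / denom
}

#' Overlap score between two vertex sets
#'
#' \code{omega(V1, V2) = |intersection|^2 / (|V1| |V2|)}; equals 0.25 when
#' two equally sized sets share half of their members, the conventional
#' match threshold for protein complexes.
#'
#' @param v1,v2 non-empty vectors of vertex ids.
#' @return the overlap score in [0, 1].
#' @export
overlapScore <- function(v1, v2) {
  if (length(v1) == 0L || length(v2) == 0L) stop("sets must be non-empty")
  length(intersect(v1, v2))^2 / (length(v1) * length(v2))
}

#' Fraction of reference complexes matched by a prediction
#'
#' A reference complex counts as matched when at least one predicted
#' complex overlaps it with score strictly greater than \code{threshold}.
#'
#' @param reference,predicted \linkS4class{ComplexSet}s.
#' @param threshold overlap-score threshold (default 0.25).
#' @return fraction of matched reference complexes.
#' @export
fracMatched <- function(reference, predicted, threshold = 0.25) {
  matched <- vapply(reference@complexes, function(r)
    any(vapply(predicted@complexes, function(p)
      overlapScore(r, p) > threshold, logical(1))), logical(1))
  mean(matched)
}

#' Reference-by-predicted contingency table
#'
#' @param reference,predicted \linkS4class{ComplexSet}s.
#' @return a \linkS4class{ContingencyTable} whose entry (i, j) counts
#'   vertices shared by reference complex i and predicted complex j.
#' @export
complexContingency <- function(reference, predicted) {
  counts <- outer(seq_along(reference@complexes),
                  seq_along(predicted@complexes),
                  Vectorize(function(i, j)
                    length(intersect(reference@complexes[[i]],
                                     predicted@complexes[[j]]))))
  new("ContingencyTable", counts = counts,
      refSizes = lengths(reference@complexes))
}

#' Module-wise sensitivity, positive predictive value and accuracy
#'
#' \code{Sn = sum_i max_j t_ij / sum_i n_i}; \code{PPV = sum_j max_i t_ij
#' / sum_ij t_ij}; \code{Acc = sqrt(Sn * PPV)} (geometric mean).
#'
#' @param table a \linkS4class{ContingencyTable}.
#' @return named vector \code{c(Sn, PPV, Acc)}.
#' @export
complexAccuracy <- function(table) {
  t <- table@counts
  if (sum(t) == 0) stop("contingency table is all zero")
  Sn <- sum(apply(t, 1L, max)) / sum(table@refSizes)
  PPV <- sum(apply(t, 2L, max)) / sum(t)
  c(Sn = Sn, PPV = PPV, Acc = sqrt(Sn * PPV))
}

#' Module-wise separation
#'
#' Products of the row-wise and column-wise relative frequencies of the
#' contingency table, aggregated over the predicted side (Sep_ref, divided
#' by the number of predicted complexes m) and the reference side
#' (Sep_inf, divided by n), combined by geometric mean.  Rows or columns
#' with zero sum contribute 0.
#'
#' @param table a \linkS4class{ContingencyTable}.
#' @return named vector \code{c(SepRef, SepInf, Sep)}.
#' @export
complexSeparation <- function(table) {
  t <- table@counts
  if (sum(t) == 0) stop("contingency table is all zero")
  rs <- rowSums(t); cs <- colSums(t)
  Fr <- sweep(t, 1L, ifelse(rs > 0, rs, 1), "/")
  Fc <- sweep(t, 2L, ifelse(cs > 0, cs, 1), "/")
  Sep <- Fr * Fc
  sepRef <- sum(Sep) / ncol(t)
  sepInf <- sum(Sep) / nrow(t)
  c(SepRef = sepRef, SepInf = sepInf, Sep = sqrt(sepRef * sepInf))
}

#' Convert a hard partition to a complex set
#'
#' Groups vertices by module label, dropping modules smaller than
#' \code{minSize} (empty modules disappear automatically).
#'
#' @param p a \linkS4class{Partition}.
#' @param minSize smallest complex to keep (default 1).
#' @param vertexIds vertex labels; defaults to the partition's own ids or
#'   \code{v001, ...}.
#' @return a \linkS4class{ComplexSet}.
#' @export
partitionToComplexes <- function(p, minSize = 1L, vertexIds = NULL) {
  if (is.null(vertexIds))
    vertexIds <- if (length(p@vertexIds) > 0L) p@vertexIds
                 else sprintf("v%03d", seq_along(p@labels))
  groups <- split(vertexIds, p@labels)
  groups <- groups[lengths(groups) >= minSize]
  complexSet(unname(groups), name = "modules")
}
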
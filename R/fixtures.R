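#' Write the deterministic fixture bundle used by the test suite
#'
#' Produces tiny self-contained instances on disk: a two-clique network
#' (two disjoint triangles), an N = 4, K = 2, T = 2 instance small enough
#' for \code{\link{exactLogEvidence}}, the 4-point AUC hand example, a
#' small contingency example (a reference complex split across two
#' predictions) and the size-8 half-overlap pair attaining the 0.25
#' overlap-score threshold.  Byte-stable for a given seed.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed for the random N = 4 instance.
#' @return invisibly, the named vector of written paths.
#' @export
makeFixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  # two disjoint triangles on 6 vertices
  ids6 <- sprintf("v%03d", 1:6)
  tri <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))
  p <- file.path(dir, "two_cliques.txt")
  writeLines(paste(ids6[tri[, 1]], ids6[tri[, 2]], sep = "\t"), p)
  paths["two_cliques"] <- p
  p <- file.path(dir, "two_cliques_universe.txt")
  writeLines(ids6, p); paths["two_cliques_universe"] <- p
  p <- file.path(dir, "two_cliques_truth.tsv")
  writeLines(paste(ids6, rep(1:2, each = 3), sep = "\t"), p)
  paths["two_cliques_truth"] <- p
  # random N = 4, T = 2 instance (enumerable: 2^12 assignment combos)
  set.seed(subSeed(seed, "fixtures"))
  ids4 <- sprintf("v%03d", 1:4)
  for (t in 1:2) {
    A <- matrix(0, 4, 4)
    up <- which(upper.tri(A))
    A[up] <- as.numeric(stats::runif(length(up)) < 0.5)
    A <- A + t(A)
    E <- edgeList(A)
    p <- file.path(dir, sprintf("tiny_n4_network_%d.txt", t))
    writeLines(paste(ids4[E[, 1]], ids4[E[, 2]], sep = "\t"), p)
    paths[sprintf("tiny_n4_network_%d", t)] <- p
  }
  p <- file.path(dir, "tiny_n4_universe.txt")
  writeLines(ids4, p); paths["tiny_n4_universe"] <- p
  # 4-point AUC hand example: scores 0.9, 0.8, 0.4, 0.3, labels 1 0 1 0
  p <- file.path(dir, "auc_four_points.tsv")
  writeLines(c("score\tlabel", "0.9\t1", "0.8\t0", "0.4\t1", "0.3\t0"), p)
  paths["auc_four_points"] <- p
  # one size-8 reference split into two size-4 predictions
  ids8 <- sprintf("p%02d", 1:8)
  p <- file.path(dir, "complexes_reference.txt")
  writeLines(paste(ids8, collapse = "\t"), p)
  paths["complexes_reference"] <- p
  p <- file.path(dir, "complexes_predicted.txt")
  writeLines(c(paste(ids8[1:4], collapse = "\t"),
               paste(ids8[5:8], collapse = "\t")), p)
  paths["complexes_predicted"] <- p
  # two size-8 sets sharing exactly half their members (overlap score 0.25)
  p <- file.path(dir, "overlap_half_sets.txt")
  writeLines(c(paste(sprintf("p%02d", 1:8), collapse = "\t"),
               paste(sprintf("p%02d", 5:12), collapse = "\t")), p)
  paths["overlap_half_sets"] <- p
  invisible(paths)
}
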
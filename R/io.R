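# Plain-text I/O: edge lists (two whitespace-separated vertex-id columns),
# partitions (vertex_id TAB module_label) and complex sets (one complex per
# line, tab-separated vertex ids).

#' Read networks from edge-list files
#'
#' Each file holds one undirected network, one edge per line, two
#' whitespace- or tab-separated vertex-id columns.  Self edges and
#' duplicate edges (in either orientation) are rejected.  A vertex
#' universe fixes N and the vertex order, and keeps vertices that are
#' isolated in some networks; without one, the sorted union of ids across
#' all files is used.
#'
#' @param files character vector of edge-list paths, one per network.
#' @param universe optional path to a file with one vertex id per line, or
#'   a character vector of ids.
#' @return a \linkS4class{MultiNetwork}.
#' @export
readMultiNetwork <- function(files, universe = NULL) {
  edges <- lapply(files, function(f) {
    if (!file.exists(f)) stop(sprintf("edge-list file not found: %s", f))
    df <- utils::read.table(f, header = FALSE, colClasses = "character")
    if (ncol(df) < 2L) stop(sprintf("%s: need two vertex-id columns", f))
    if (any(df[[1L]] == df[[2L]]))
      stop(sprintf("%s: self edges are not allowed", f))
    key <- paste(pmin(df[[1L]], df[[2L]]), pmax(df[[1L]], df[[2L]]))
    if (anyDuplicated(key))
      stop(sprintf("%s: duplicate edges are not allowed", f))
    df
  })
  ids <- if (is.null(universe)) {
    sort(unique(unlist(lapply(edges, function(df) c(df[[1L]], df[[2L]])))))
  } else if (length(universe) == 1L && file.exists(universe)) {
    readLines(universe)
  } else as.character(universe)
  ids <- ids[nzchar(ids)]
  if (anyDuplicated(ids)) stop("vertex universe contains duplicate ids")
  N <- length(ids)
  adj <- lapply(edges, function(df) {
    i <- match(df[[1L]], ids); j <- match(df[[2L]], ids)
    if (anyNA(i) || anyNA(j))
      stop("edge references a vertex absent from the universe")
    A <- matrix(0, N, N)
    A[cbind(i, j)] <- 1; A[cbind(j, i)] <- 1
    A
  })
  multiNetwork(adj, vertexIds = ids)
}

#' Write one network as an edge list
#'
#' @param net a \linkS4class{MultiNetwork}.
#' @param t network index.
#' @param file output path.
#' @export
writeEdgeList <- function(net, t, file) {
  E <- edgeList(net@adjacency[[t]])
  ids <- vertexIds(net)
  writeLines(paste(ids[E[, 1L]], ids[E[, 2L]], sep = "\t"), file)
}

#' Read / write a partition file (vertex_id TAB module_label)
#'
#' @param file path to a two-column tab-separated file.
#' @param universe optional vertex ordering; defaults to file order.
#' @return a \linkS4class{Partition}.
#' @export
readPartition <- function(file, universe = NULL) {
  df <- utils::read.table(file, header = FALSE, sep = "\t",
                          colClasses = c("character", "integer"))
  if (!is.null(universe)) {
    idx <- match(universe, df[[1L]])
    if (anyNA(idx)) stop("partition file missing vertices of the universe")
    df <- df[idx, ]
  }
  partition(df[[2L]], K = max(df[[2L]]), vertexIds = df[[1L]])
}

#' @rdname readPartition
#' @param p a \linkS4class{Partition}.
#' @param vertexIds labels to write when the partition carries none.
#' @export
writePartition <- function(p, file, vertexIds = NULL) {
  ids <- if (length(p@vertexIds) > 0L) p@vertexIds
         else vertexIds %||% sprintf("v%03d", seq_along(p@labels))
  writeLines(paste(ids, p@labels, sep = "\t"), file)
}

#' Read / write complex sets (one complex per line, tab-separated ids)
#'
#' @param file path.
#' @param name label for the collection.
#' @return a \linkS4class{ComplexSet}.
#' @export
readComplexSet <- function(file, name = basename(file)) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  complexSet(strsplit(lines, "\t", fixed = TRUE), name = name)
}

#' @rdname readComplexSet
#' @param x a \linkS4class{ComplexSet}.
#' @export
writeComplexSet <- function(x, file) {
  writeLines(vapply(x@complexes, paste, character(1), collapse = "\t"), file)
}
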
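#' Number of unique connections among a set of nodes
#'
#' For \code{n} nodes there are \code{n * (n - 1) / 2} undirected
#' node pairs (edges); e.g. the 100-node cortical parcellation yields
#' 4,950 functional connections.
#'
#' @param nNodes Number of nodes (>= 2).
#' @return Integer edge count.
#' @examples
#' nConnections(100) # 4950
#' @export
nConnections <- function(nNodes) {
  if (length(nNodes) != 1L || !is.finite(nNodes) || nNodes < 2)
    stop("'nNodes' must be a single integer >= 2")
  nNodes <- as.integer(nNodes)
  as.integer(nNodes * (nNodes - 1L) / 2L)
}

#' Edge index table for an undirected graph
#'
#' Enumerates the strict upper triangle of an \code{n x n} symmetric matrix
#' in row-major order. Flat indices are 1-based; the convention is recorded
#' in every serialized sidecar so that runs are exactly reproducible.
#'
#' @param nNodes Number of nodes.
#' @return data.frame with columns \code{edge} (flat index), \code{i},
#'   \code{j} (node indices, \code{i < j}).
#' @export
edgeIndexTable <- function(nNodes) {
  nNodes <- as.integer(nNodes)
  if (nNodes < 2) stop("'nNodes' must be >= 2")
  i <- rep.int(seq_len(nNodes - 1L), times = (nNodes - 1L):1L)
  j <- sequence((nNodes - 1L):1L) + i
  data.frame(edge = seq_along(i), i = i, j = j)
}

edgeConvention <- function() "upper-triangle, row-major, 1-based"

#' Vectorize the upper triangle of a symmetric matrix
#'
#' @param mat Symmetric numeric matrix.
#' @return Numeric vector of length \code{n(n-1)/2} in row-major
#'   upper-triangle order.
#' @seealso [edgesToMatrix()] for the inverse.
#' @export
matrixToEdges <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat))
    stop("'mat' must be a square matrix")
  t(mat)[lower.tri(mat)]
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' @param edges Edge vector in row-major upper-triangle order.
#' @param nNodes Number of nodes.
#' @param diagValue Value placed on the diagonal (default 0; the diagonal of
#'   a Fisher-z FC matrix is undefined).
#' @return Symmetric \code{nNodes x nNodes} matrix.
#' @export
edgesToMatrix <- function(edges, nNodes, diagValue = 0) {
  nNodes <- as.integer(nNodes)
  if (length(edges) != nConnections(nNodes))
    stop("edge vector length does not match 'nNodes'")
  m <- matrix(diagValue, nNodes, nNodes)
  et <- edgeIndexTable(nNodes)
  m[cbind(et$i, et$j)] <- edges
  m[cbind(et$j, et$i)] <- edges
  m
}

# flat edge indices for all pairs among 'nodes' (logical or integer)
edgesAmongNodes <- function(nodes, nNodes) {
  et <- edgeIndexTable(nNodes)
  if (is.logical(nodes)) nodes <- which(nodes)
  which(et$i %in% nodes & et$j %in% nodes)
}
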
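maskFromEdges <- function(edgeIdx, nE, provenance) {
  mask <- logical(nE)
  mask[edgeIdx] <- TRUE
  ConnectionSelection(mask, provenance)
}

#' Whole-brain selection (all connections)
#'
#' @param atlas A [NodeAtlas-class].
#' @return A [ConnectionSelection-class] covering every edge.
#' @export
wholeBrainSelection <- function(atlas) {
  ConnectionSelection(rep(TRUE, nEdges(atlas)), "whole_brain")
}

#' Within- and between-network connection selections
#'
#' \code{withinNetworkEdges} selects edges with both endpoints in one
#' network (m member nodes yield m(m-1)/2 edges);
#' \code{betweenNetworkEdges} selects edges with one endpoint in each of
#' two distinct networks (a x b edges).
#'
#' @param net,a,b Network labels present in the atlas.
#' @param atlas A [NodeAtlas-class].
#' @return A [ConnectionSelection-class].
#' @export
withinNetworkEdges <- function(net, atlas) {
  stopifnot(net %in% networks(atlas))
  et <- edgeIndexTable(nNodes(atlas))
  lab <- networks(atlas)
  maskFromEdges(which(lab[et$i] == net & lab[et$j] == net), nEdges(atlas),
                paste0("within:", net))
}

#' @rdname withinNetworkEdges
#' @export
betweenNetworkEdges <- function(a, b, atlas) {
  stopifnot(a %in% networks(atlas), b %in% networks(atlas))
  if (a == b) stop("'a' and 'b' must be distinct networks")
  et <- edgeIndexTable(nNodes(atlas))
  lab <- networks(atlas)
  hit <- (lab[et$i] == a & lab[et$j] == b) |
    (lab[et$i] == b & lab[et$j] == a)
  nets <- sort(c(a, b))
  maskFromEdges(which(hit), nEdges(atlas),
                paste0("between:", nets[1], "-", nets[2]))
}

#' Enumerate all network-based connection selections
#'
#' For an atlas with m networks, returns \code{1 + m + C(m,2) + m + m}
#' selections: (i) whole brain; (ii) within each network; (iii) between
#' each network pair; (iv) all connections except those touching one
#' network; (v) all within- and between-network connections of one
#' network. For the canonical seven networks this yields 43 selections,
#' hence 10 states x 43 selections = 430 model configurations per
#' intelligence component.
#'
#' @param atlas A [NodeAtlas-class] with every node labeled.
#' @return Named list of [ConnectionSelection-class] objects.
#' @export
enumerateNetworkSelections <- function(atlas) {
  nets <- sort(unique(networks(atlas)))
  et <- edgeIndexTable(nNodes(atlas))
  lab <- networks(atlas)
  out <- list(whole_brain = wholeBrainSelection(atlas))
  for (net in nets)
    out[[paste0("within:", net)]] <- withinNetworkEdges(net, atlas)
  if (length(nets) >= 2) {
    pairs <- utils::combn(nets, 2)
    for (p in seq_len(ncol(pairs))) {
      sel <- betweenNetworkEdges(pairs[1, p], pairs[2, p], atlas)
      out[[provenance(sel)]] <- sel
    }
  }
  for (net in nets) {
    touches <- lab[et$i] == net | lab[et$j] == net
    out[[paste0("exclude:", net)]] <-
      maskFromEdges(which(!touches), nEdges(atlas), paste0("exclude:", net))
    out[[paste0("network_all:", net)]] <-
      maskFromEdges(which(touches), nEdges(atlas),
                    paste0("network_all:", net))
  }
  out
}

#' Theory-driven connection selection by nearest-node mapping
#'
#' For each theory-proposed cluster coordinate, selects the atlas node
#' with the smallest Euclidean distance to it (deduplicated; distance ties
#' resolved by the lowest node id, with a message); the selection contains
#' all edges among the selected nodes.
#'
#' @param coordinates Numeric matrix (clusters x 3) of coordinates in mm.
#' @param atlas A [NodeAtlas-class] with centroids.
#' @param name Theory name recorded in the provenance.
#' @return A [ConnectionSelection-class] whose \code{details} provenance is
#'   \code{theory:<name>}; the selected nodes are stored in the attribute
#'   \code{nodes}.
#' @export
theorySelection <- function(coordinates, atlas, name = "theory") {
  coordinates <- as.matrix(coordinates)
  if (nrow(coordinates) < 1) stop("coordinate list must be non-empty")
  if (ncol(coordinates) != 3) stop("coordinates must have 3 columns (mm)")
  cen <- centroids(atlas)
  if (nrow(cen) == 0) stop("atlas has no centroids")
  nodes <- vapply(seq_len(nrow(coordinates)), function(k) {
    d <- sqrt(colSums((t(cen) - coordinates[k, ])^2))
    hits <- which(d <= min(d) + 1e-12)
    if (length(hits) > 1)
      message("distance tie for coordinate ", k,
              "; resolved by lowest node id")
    hits[1]
  }, integer(1))
  nodes <- sort(unique(nodes))
  sel <- maskFromEdges(edgesAmongNodes(nodes, nNodes(atlas)),
                       nEdges(atlas), paste0("theory:", name))
  attr(sel, "nodes") <- nodes
  sel
}

#' Random-edge and random-node null selections
#'
#' \code{randomEdgeSelection} samples k edges uniformly without
#' replacement; \code{randomNodeSelection} samples m nodes uniformly and
#' selects all C(m,2) edges among them. Both are deterministic per seed
#' and serve as null references for theory-driven and relevance-based
#' selections.
#'
#' @param k Number of edges.
#' @param m Number of nodes.
#' @param atlas A [NodeAtlas-class].
#' @param seed Integer seed.
#' @return A [ConnectionSelection-class].
#' @export
randomEdgeSelection <- function(k, atlas, seed) {
  nE <- nEdges(atlas)
  if (k < 1 || k > nE) stop("'k' out of range")
  .withSeed(seed, maskFromEdges(sample.int(nE, k), nE,
                                paste0("random_edges:", k, ":seed=",
                                       seed)))
}

#' @rdname randomEdgeSelection
#' @export
randomNodeSelection <- function(m, atlas, seed) {
  nN <- nNodes(atlas)
  if (m < 2 || m > nN) stop("'m' out of range")
  nodes <- .withSeed(seed, sort(sample.int(nN, m)))
  sel <- maskFromEdges(edgesAmongNodes(nodes, nN), nEdges(atlas),
                       paste0("random_nodes:", m, ":seed=", seed))
  attr(sel, "nodes") <- nodes
  sel
}

#' Node count whose complete graph has about k edges
#'
#' Smallest m with C(m,2) >= k; used to size random-node selections
#' matched to a random-edge selection.
#'
#' @param k Edge count.
#' @return Integer node count.
#' @export
nodesForEdgeCount <- function(k) {
  m <- ceiling((1 + sqrt(1 + 8 * k)) / 2)
  while (nConnections(m) >= k && m > 2 && nConnections(m - 1) >= k)
    m <- m - 1
  as.integer(m)
}

#' Top-k most relevant connection selection
#'
#' Selects the k edges ranked most relevant by a [RelevanceMap-class]:
#' the stepwise priority ordering when present, otherwise by relevance
#' magnitude (configurable to signed), ties broken by edge index.
#'
#' @param relevanceMap A [RelevanceMap-class].
#' @param k Number of edges.
#' @param by "absolute" (default) or "signed" ranking of relevance
#'   values. With the default, an explicit priority ordering (e.g. from
#'   [stepwiseLRP()]) takes precedence; "signed" always ranks the raw
#'   relevance values.
#' @return A [ConnectionSelection-class].
#' @export
topKSelection <- function(relevanceMap, k, by = c("absolute", "signed")) {
  by <- match.arg(by)
  if (by == "absolute" && length(relevanceMap@ranking)) {
    ord <- relevanceMap@ranking
    nE <- max(length(relevanceMap@relevance), length(ord))
  } else {
    rel <- relevanceMap@relevance
    if (!length(rel))
      stop("signed ranking requires relevance values")
    if (any(!is.finite(rel))) stop("relevance contains non-finite values")
    key <- if (by == "absolute") abs(rel) else rel
    ord <- order(key, seq_along(key) * -1, decreasing = TRUE)
    nE <- length(rel)
  }
  if (k < 1 || k > length(ord))
    stop("'k' exceeds the number of ranked edges")
  maskFromEdges(ord[seq_len(k)], nE,
                paste0("top_relevant:", k))
}
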
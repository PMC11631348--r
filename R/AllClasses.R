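#' Node atlas: network labels and optional centroid coordinates
#'
#' Describes the brain parcellation: one row per node, a functional-network
#' label per node (canonically the seven cortical networks: visual,
#' somatomotor, dorsal attention, ventral attention, limbic, control,
#' default mode), and optional centroid coordinates in millimetres used for
#' theory-driven node mapping.
#'
#' @slot network character, network label per node.
#' @slot centroids numeric matrix with one row per node and columns x, y, z
#'   (mm), or a 0-row matrix when coordinates are unavailable.
#' @export
setClass("NodeAtlas",
  representation(network = "character", centroids = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (length(object@network) < 2L)
      msg <- c(msg, "atlas must contain at least two nodes")
    if (anyNA(object@network) || any(!nzchar(object@network)))
      msg <- c(msg, "every node must carry a network label")
    if (nrow(object@centroids) > 0L) {
      if (nrow(object@centroids) != length(object@network))
        msg <- c(msg, "centroids must have one row per node")
      if (ncol(object@centroids) != 3L)
        msg <- c(msg, "centroids must have 3 columns (x, y, z)")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Construct a NodeAtlas
#'
#' @param network Character vector of network labels, one per node.
#' @param centroids Optional numeric matrix (nodes x 3) of centroid
#'   coordinates in mm.
#' @return A [NodeAtlas-class] object.
#' @examples
#' atlas <- NodeAtlas(rep(c("VIS", "DMN"), each = 5))
#' nNodes(atlas)
#' @export
NodeAtlas <- function(network, centroids = NULL) {
  if (is.null(centroids))
    centroids <- matrix(numeric(0), nrow = 0, ncol = 3,
                        dimnames = list(NULL, c("x", "y", "z")))
  centroids <- as.matrix(centroids)
  if (nrow(centroids) > 0 && is.null(colnames(centroids)))
    colnames(centroids) <- c("x", "y", "z")
  new("NodeAtlas", network = as.character(network), centroids = centroids)
}

#' Multi-state connectome container
#'
#' A \linkS4class{SummarizedExperiment} whose assays are edge-by-subject
#' matrices of Fisher-z functional connectivity, one assay per cognitive
#' state. \code{rowData} carries the edge index (node pair i < j and the
#' network pair); \code{colData} carries the cohort table (family ids,
#' confounds, cognitive measures). Metadata records the atlas, the edge
#' vectorization convention, the generator seed, and (for synthetic data)
#' the planted ground truth.
#'
#' @export
setClass("ConnectomeSet", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- NULL
    at <- metadata(object)$atlas
    if (is.null(at))
      msg <- c(msg, "metadata must contain the node atlas")
    else if (nrow(object) != nConnections(length(at@network)))
      msg <- c(msg, "row count must equal the atlas edge count n(n-1)/2")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a ConnectomeSet
#'
#' @param edgeAssays Named list of edge-by-subject matrices (one per state),
#'   edges in row-major upper-triangle order.
#' @param atlas A [NodeAtlas-class].
#' @param cohort data.frame of per-subject covariates (one row per subject,
#'   must contain an \code{id} column).
#' @param truth Optional ground-truth list for synthetic data.
#' @param seed Optional generator seed, recorded in metadata.
#' @return A [ConnectomeSet-class].
#' @export
ConnectomeSet <- function(edgeAssays, atlas, cohort, truth = NULL,
                          seed = NULL) {
  stopifnot(is.list(edgeAssays), length(edgeAssays) >= 1L,
            !is.null(names(edgeAssays)))
  nN <- length(atlas@network)
  et <- edgeIndexTable(nN)
  rd <- DataFrame(i = et$i, j = et$j,
                  network_i = atlas@network[et$i],
                  network_j = atlas@network[et$j])
  cd <- DataFrame(cohort, check.names = FALSE)
  rownames(cd) <- cohort$id
  edgeAssays <- lapply(edgeAssays, function(m) {
    colnames(m) <- cohort$id
    m
  })
  se <- SummarizedExperiment(assays = edgeAssays, rowData = rd, colData = cd)
  metadata(se) <- list(atlas = atlas, edgeConvention = edgeConvention(),
                       seed = seed, truth = truth)
  new("ConnectomeSet", se)
}

#' Connection selection: a boolean edge mask with provenance
#'
#' A reproducible selection of functional connections. The provenance
#' string (e.g. \code{"within:DMN"}, \code{"random_edges:45:seed=7"},
#' \code{"theory:P-FIT"}) together with the atlas and seed fully determines
#' the mask.
#'
#' @slot mask logical vector over edge indices.
#' @slot provenance character(1) describing how the mask was produced.
#' @export
setClass("ConnectionSelection",
  representation(mask = "logical", provenance = "character"),
  validity = function(object) {
    msg <- NULL
    if (anyNA(object@mask)) msg <- c(msg, "mask must not contain NA")
    if (length(object@provenance) != 1L)
      msg <- c(msg, "provenance must be a single string")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a ConnectionSelection
#'
#' @param mask Logical edge mask.
#' @param provenance Provenance string.
#' @return A [ConnectionSelection-class].
#' @export
ConnectionSelection <- function(mask, provenance) {
  new("ConnectionSelection", mask = as.logical(mask),
      provenance = as.character(provenance))
}

#' Cross-validated prediction result
#'
#' Out-of-fold predictions together with performance metrics (Pearson r
#' between observed and predicted scores; MSE, RMSE, MAE on
#' range-normalized scores), per-fold chosen hyperparameters, and the
#' training-derived artifacts needed for leakage audits.
#'
#' @slot predictions data.frame: subject, repetition, fold, observed
#'   (deconfounded target), predicted.
#' @slot metrics data.frame: one row per repetition with r, mse, rmse, mae.
#' @slot artifacts list of per-(repetition, fold) training artifacts
#'   (deconfounder coefficients, standardization parameters, chosen
#'   architecture, early-stop trace).
#' @slot info list of run metadata (selection provenance, seeds, target).
#' @export
setClass("PredictionResult",
  representation(predictions = "data.frame", metrics = "data.frame",
                 artifacts = "list", info = "list"),
  validity = function(object) {
    need <- c("subject", "repetition", "fold", "observed", "predicted")
    if (!all(need %in% names(object@predictions)))
      return(paste("predictions must contain columns:",
                   paste(need, collapse = ", ")))
    dup <- anyDuplicated(object@predictions[, c("subject", "repetition")])
    if (dup) return("each subject must be predicted exactly once per repetition")
    TRUE
  })

#' Construct a PredictionResult
#'
#' @param predictions,metrics,artifacts,info See
#'   [PredictionResult-class].
#' @return A [PredictionResult-class].
#' @export
PredictionResult <- function(predictions, metrics, artifacts = list(),
                             info = list()) {
  new("PredictionResult", predictions = predictions, metrics = metrics,
      artifacts = artifacts, info = info)
}

#' Per-edge relevance attribution map
#'
#' Signed per-edge relevance values (aggregated over folds/repetitions)
#' and/or a priority ranking of edges (best first), as produced by
#' [lrpAttribute()] aggregation or [stepwiseLRP()].
#'
#' @slot relevance numeric per-edge relevance (signed); may be NA when only
#'   a ranking is available.
#' @slot ranking integer vector of edge indices, most relevant first.
#' @slot details list of provenance metadata.
#' @export
setClass("RelevanceMap",
  representation(relevance = "numeric", ranking = "integer",
                 details = "list"),
  validity = function(object) {
    if (length(object@ranking) &&
        anyDuplicated(object@ranking))
      return("ranking must not contain duplicate edges")
    TRUE
  })

#' Construct a RelevanceMap
#'
#' When only relevance values are given, the ranking defaults to
#' decreasing relevance magnitude.
#'
#' @param relevance Numeric per-edge relevance.
#' @param ranking Integer edge priority (most relevant first).
#' @param details Provenance list.
#' @return A [RelevanceMap-class].
#' @export
RelevanceMap <- function(relevance = numeric(0), ranking = integer(0),
                         details = list()) {
  if (!length(ranking) && length(relevance))
    ranking <- order(abs(relevance), decreasing = TRUE)
  new("RelevanceMap", relevance = as.numeric(relevance),
      ranking = as.integer(ranking), details = details)
}
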
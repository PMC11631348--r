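#' @rdname conniq-accessors
#' @export
setMethod("nNodes", "NodeAtlas", function(x) length(x@network))

#' @rdname conniq-accessors
#' @export
setMethod("nEdges", "NodeAtlas", function(x) nConnections(length(x@network)))

#' @rdname conniq-accessors
#' @export
setMethod("networks", "NodeAtlas", function(x) x@network)

#' @rdname conniq-accessors
#' @export
setMethod("centroids", "NodeAtlas", function(x) x@centroids)

#' @rdname conniq-accessors
#' @export
setMethod("atlas", "ConnectomeSet", function(x) metadata(x)$atlas)

#' @rdname conniq-accessors
#' @export
setMethod("nNodes", "ConnectomeSet",
          function(x) length(metadata(x)$atlas@network))

#' @rdname conniq-accessors
#' @export
setMethod("nEdges", "ConnectomeSet", function(x) nrow(x))

#' @rdname conniq-accessors
#' @export
setMethod("states", "ConnectomeSet", function(x) assayNames(x))

#' @rdname conniq-accessors
#' @export
setMethod("cohort", "ConnectomeSet",
          function(x) as.data.frame(colData(x)))

#' @rdname conniq-accessors
#' @export
setMethod("groundTruth", "ConnectomeSet", function(x) metadata(x)$truth)

#' Extract one subject's FC matrix for one state
#'
#' @param x A [ConnectomeSet-class].
#' @param subject Subject id or column index.
#' @param state State name.
#' @return Symmetric Fisher-z FC matrix (diagonal 0).
#' @export
fcMatrix <- function(x, subject, state) {
  stopifnot(is(x, "ConnectomeSet"))
  v <- assay(x, state)[, subject]
  edgesToMatrix(v, nNodes(x))
}

#' Feature matrix (subjects x selected edges) for a state
#'
#' @param x A [ConnectomeSet-class].
#' @param state State name.
#' @param selection Optional [ConnectionSelection-class]; default all edges.
#' @return Numeric matrix, subjects in rows, selected edges in columns.
#' @export
selectionFeatures <- function(x, state, selection = NULL) {
  m <- assay(x, state)
  if (!is.null(selection)) {
    if (length(selection@mask) != nrow(m))
      stop("selection mask length does not match edge count")
    if (!any(selection@mask)) stop("empty connection selection")
    m <- m[selection@mask, , drop = FALSE]
  }
  t(m)
}

#' @rdname conniq-accessors
#' @export
setMethod("selectionMask", "ConnectionSelection", function(x) x@mask)

#' @rdname conniq-accessors
#' @export
setMethod("selectionSize", "ConnectionSelection", function(x) sum(x@mask))

#' @rdname conniq-accessors
#' @export
setMethod("provenance", "ConnectionSelection", function(x) x@provenance)

#' @rdname conniq-accessors
#' @export
setMethod("nEdges", "ConnectionSelection", function(x) length(x@mask))

#' @rdname conniq-accessors
#' @export
setMethod("predictions", "PredictionResult", function(x) x@predictions)

#' @rdname conniq-accessors
#' @export
setMethod("metrics", "PredictionResult", function(x) x@metrics)

#' @rdname conniq-accessors
#' @export
setMethod("foldArtifacts", "PredictionResult", function(x) x@artifacts)

#' @rdname conniq-accessors
#' @export
setMethod("relevance", "RelevanceMap", function(x) x@relevance)

#' @rdname conniq-accessors
#' @export
setMethod("ranking", "RelevanceMap", function(x) x@ranking)

setMethod("show", "NodeAtlas", function(object) {
  cat("NodeAtlas:", nNodes(object), "nodes,",
      length(unique(object@network)), "networks\n")
  tb <- table(object@network)
  cat(paste0("  ", names(tb), " (", as.integer(tb), ")", collapse = "\n"),
      "\n")
  if (nrow(object@centroids) > 0) cat("  centroids: yes (mm)\n")
})

setMethod("show", "ConnectomeSet", function(object) {
  cat("ConnectomeSet:", ncol(object), "subjects x", nrow(object),
      "edges (", nNodes(object), "nodes )\n")
  cat("  states:", paste(states(object), collapse = ", "), "\n")
  cat("  edge convention:", metadata(object)$edgeConvention, "\n")
  if (!is.null(metadata(object)$truth))
    cat("  synthetic: planted ground truth attached\n")
})

setMethod("show", "ConnectionSelection", function(object) {
  cat("ConnectionSelection [", object@provenance, "]: ",
      sum(object@mask), " / ", length(object@mask), " edges\n", sep = "")
})

setMethod("show", "PredictionResult", function(object) {
  cat("PredictionResult:", nrow(object@predictions), "out-of-fold",
      "predictions,", nrow(object@metrics), "repetition(s)\n")
  if (nrow(object@metrics)) {
    cat(sprintf("  mean r = %.3f, MSE = %.4f, RMSE = %.4f, MAE = %.4f\n",
                mean(object@metrics$r), mean(object@metrics$mse),
                mean(object@metrics$rmse), mean(object@metrics$mae)))
  }
})

setMethod("show", "RelevanceMap", function(object) {
  cat("RelevanceMap:", max(length(object@relevance),
                           length(object@ranking)), "edges")
  if (length(object@ranking))
    cat("; top edges:", paste(head(object@ranking, 5), collapse = ", "))
  cat("\n")
})
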
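#' @name conniq-accessors
#' @title Accessors for conniq classes
#' @description Accessor generics for [NodeAtlas-class],
#'   [ConnectomeSet-class], [ConnectionSelection-class],
#'   [PredictionResult-class] and [RelevanceMap-class].
#' @param x,object An object.
#' @param ... Further arguments (unused).
NULL

#' @rdname conniq-accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname conniq-accessors
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @rdname conniq-accessors
#' @export
setGeneric("networks", function(x) standardGeneric("networks"))

#' @rdname conniq-accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname conniq-accessors
#' @export
setGeneric("atlas", function(x) standardGeneric("atlas"))

#' @rdname conniq-accessors
#' @export
setGeneric("states", function(x) standardGeneric("states"))

#' @rdname conniq-accessors
#' @export
setGeneric("cohort", function(x) standardGeneric("cohort"))

#' @rdname conniq-accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname conniq-accessors
#' @export
setGeneric("selectionMask", function(x) standardGeneric("selectionMask"))

#' @rdname conniq-accessors
#' @export
setGeneric("selectionSize", function(x) standardGeneric("selectionSize"))

#' @rdname conniq-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname conniq-accessors
#' @export
setGeneric("predictions", function(x) standardGeneric("predictions"))

#' @rdname conniq-accessors
#' @export
setGeneric("metrics", function(x) standardGeneric("metrics"))

#' @rdname conniq-accessors
#' @export
setGeneric("foldArtifacts", function(x) standardGeneric("foldArtifacts"))

#' @rdname conniq-accessors
#' @export
setGeneric("relevance", function(x) standardGeneric("relevance"))

#' @rdname conniq-accessors
#' @export
setGeneric("ranking", function(x) standardGeneric("ranking"))
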
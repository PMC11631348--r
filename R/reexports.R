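#' Re-exported generics
#'
#' Generics from SummarizedExperiment and S4Vectors that apply directly
#' to [ConnectomeSet-class] objects, re-exported for convenience.
#'
#' @name reexports
#' @keywords internal
NULL

#' @rdname reexports
#' @importFrom SummarizedExperiment assay
#' @export assay
#' @usage NULL
NULL

#' @rdname reexports
#' @importFrom SummarizedExperiment assays
#' @export assays
#' @usage NULL
NULL

#' @rdname reexports
#' @importFrom SummarizedExperiment assayNames
#' @export assayNames
#' @usage NULL
NULL

#' @rdname reexports
#' @importFrom SummarizedExperiment rowData
#' @export rowData
#' @usage NULL
NULL

#' @rdname reexports
#' @importFrom SummarizedExperiment colData
#' @export colData
#' @usage NULL
NULL

#' @rdname reexports
#' @importFrom S4Vectors metadata
#' @export metadata
#' @usage NULL
NULL
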
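#' Read and write delimited-text tables
#'
#' Cohort, score, and result tables are serialized as tab-delimited text
#' with a header row.
#'
#' @param x data.frame to write.
#' @param path File path.
#' @return \code{readTable} returns a data.frame.
#' @export
writeTableTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTableTsv
#' @export
readTableTsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Serialize a connection selection to JSON
#'
#' Stores the provenance and the explicit edge index list so any run is
#' exactly reproducible.
#'
#' @param selection A [ConnectionSelection-class].
#' @param path File path.
#' @export
writeSelection <- function(selection, path) {
  jsonlite::write_json(
    list(provenance = selection@provenance,
         nEdgesTotal = length(selection@mask),
         edgeConvention = edgeConvention(),
         edges = which(selection@mask)),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeSelection
#' @export
readSelection <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  maskFromEdges(s$edges, s$nEdgesTotal, s$provenance)
}

#' Write / read a ConnectomeSet as a text array container
#'
#' One tab-delimited edge-by-subject matrix per state plus a JSON sidecar
#' carrying the atlas (network labels, centroids), state names, edge
#' index convention, and generator seed; the cohort table is written as
#' delimited text alongside.
#'
#' @param x A [ConnectomeSet-class].
#' @param dir Output directory (created if missing).
#' @export
writeConnectomeSet <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  at <- atlas(x)
  for (st in states(x)) {
    utils::write.table(assay(x, st), file.path(dir, paste0("fc_", st,
                                                           ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = TRUE)
  }
  writeTableTsv(cohort(x), file.path(dir, "cohort.tsv"))
  sidecar <- list(states = states(x),
                  nNodes = nNodes(x),
                  edgeConvention = metadata(x)$edgeConvention,
                  seed = metadata(x)$seed,
                  atlas = list(network = networks(at)))
  if (nrow(centroids(at)) > 0)
    sidecar$atlas$centroids <- unname(centroids(at))
  jsonlite::write_json(sidecar, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeConnectomeSet
#' @export
readConnectomeSet <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "sidecar.json"),
                                 simplifyVector = TRUE)
  cen <- sidecar$atlas$centroids
  if (!is.null(cen) && !is.matrix(cen))
    cen <- do.call(rbind, lapply(cen, unlist))
  at <- NodeAtlas(sidecar$atlas$network, cen)
  ch <- readTableTsv(file.path(dir, "cohort.tsv"))
  assaysList <- lapply(sidecar$states, function(st)
    as.matrix(utils::read.table(file.path(dir, paste0("fc_", st, ".tsv")),
                                header = TRUE, sep = "\t",
                                check.names = FALSE)))
  names(assaysList) <- sidecar$states
  ConnectomeSet(assaysList, at, ch, seed = sidecar$seed)
}

#' Write a relevance map as delimited text
#'
#' One row per edge: node pair, network pair, mean relevance, rank; the
#' producing run's provenance is written as a JSON sidecar.
#'
#' @param map A [RelevanceMap-class].
#' @param atlasObj The [NodeAtlas-class] of the producing run.
#' @param path Output file (a \code{.json} sidecar is written next to
#'   it).
#' @export
writeRelevanceMap <- function(map, atlasObj, path) {
  nE <- max(length(map@relevance), length(map@ranking))
  et <- edgeIndexTable(nNodes(atlasObj))
  rk <- rep(NA_integer_, nE)
  if (length(map@ranking)) rk[map@ranking] <- seq_along(map@ranking)
  df <- data.frame(edge = seq_len(nE), i = et$i, j = et$j,
                   network_i = networks(atlasObj)[et$i],
                   network_j = networks(atlasObj)[et$j],
                   relevance = if (length(map@relevance)) map@relevance
                   else NA_real_,
                   rank = rk)
  writeTableTsv(df, path)
  jsonlite::write_json(map@details, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
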
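#' Synthetic atlas with seven functional networks
#'
#' Assigns nodes round-robin-in-blocks to the seven canonical cortical
#' networks and places node centroids uniformly in a brain-sized box
#' (+-70, +-90, +-60 mm), so that theory-driven nearest-node selection can
#' be exercised. Deterministic per seed.
#'
#' @param nNodes Number of nodes (default 100).
#' @param networkNames Network labels (default the seven canonical ones).
#' @param seed Integer seed for centroid placement.
#' @return A [NodeAtlas-class].
#' @export
syntheticAtlas <- function(nNodes = 100,
                           networkNames = c("VIS", "SMN", "DAN", "VAN",
                                            "LIM", "CON", "DMN"),
                           seed = 1) {
  .withSeed(seed, {
    labels <- sort(rep_len(networkNames, nNodes))
    centroids <- cbind(x = stats::runif(nNodes, -70, 70),
                       y = stats::runif(nNodes, -90, 90),
                       z = stats::runif(nNodes, -60, 60))
    NodeAtlas(labels, centroids)
  })
}

#' Default cognitive states and their signal scales
#'
#' Eight measured states (rest plus seven in-scanner tasks) with
#' state-varying signal strength: cognitively demanding states (working
#' memory, language) carry the strongest component signal, the emotion
#' task the weakest, emulating the observed state dependence of
#' prediction performance.
#'
#' @return Named numeric vector of per-state signal scales.
#' @export
defaultStates <- function() {
  c(rest = 0.6, wm = 1.0, gambling = 0.5, motor = 0.4, language = 1.0,
    social = 0.8, relational = 0.6, emotion = 0.25)
}

#' Configuration for the synthetic connectome generator
#'
#' @param states Named numeric vector of per-state signal scales (see
#'   [defaultStates()]).
#' @param nRelevant Number of planted relevant edges.
#' @param blockSize Planted edges are grouped into redundancy blocks of
#'   this size; edges in a block share one incident hub node and a common
#'   block latent, so removing a block leaves predictive information in
#'   the others (partial redundancy).
#' @param redundancyNoise Proportion of block-latent variance that is
#'   block-specific noise rather than the target component (0 = perfectly
#'   redundant blocks).
#' @param component Which latent component the planted edges track
#'   ("g", "gc" or "gf").
#' @param effectRange Range of per-edge signal coefficients (Fisher-z units
#'   per SD of the component, before state scaling).
#' @param meanWithin,meanBetween Mean Fisher-z FC for within- and
#'   between-network edges.
#' @param meanSD SD of per-edge base means.
#' @param noiseSD Residual SD of edge values.
#' @param confoundLeakSD SD of the per-edge, per-confound leakage
#'   coefficients (confounds enter edge values additively, so linear
#'   deconfounding has a true target).
#' @return List of class \code{connectomeConfig}.
#' @export
connectomeConfig <- function(states = defaultStates(), nRelevant = 60,
                             blockSize = 8, redundancyNoise = 0.3,
                             component = "g",
                             effectRange = c(0.08, 0.15),
                             meanWithin = 0.55, meanBetween = 0.22,
                             meanSD = 0.12, noiseSD = 0.25,
                             confoundLeakSD = 0.02) {
  cfg <- list(states = states, nRelevant = nRelevant, blockSize = blockSize,
              redundancyNoise = redundancyNoise, component = component,
              effectRange = effectRange, meanWithin = meanWithin,
              meanBetween = meanBetween, meanSD = meanSD, noiseSD = noiseSD,
              confoundLeakSD = confoundLeakSD)
  class(cfg) <- "connectomeConfig"
  cfg
}

# planted edges in hub-sharing blocks: each block picks a hub node and
# blockSize partner nodes; the block's edges all touch the hub
plantRelevantEdges <- function(nNodes, nRelevant, blockSize) {
  nE <- nConnections(nNodes)
  if (nRelevant > nE) stop("more relevant edges requested than exist")
  nBlocks <- ceiling(nRelevant / blockSize)
  if (nBlocks > nNodes) stop("too many redundancy blocks for this atlas")
  hubs <- sample.int(nNodes, nBlocks)
  et <- edgeIndexTable(nNodes)
  edges <- integer(0)
  block <- integer(0)
  for (b in seq_len(nBlocks)) {
    size <- min(blockSize, nRelevant - length(edges))
    pool <- which((et$i == hubs[b] | et$j == hubs[b]) &
                    !(seq_len(nE) %in% edges))
    take <- sample(pool, size)
    edges <- c(edges, take)
    block <- c(block, rep(b, size))
  }
  list(edges = edges, block = block, hubs = hubs)
}

#' Generate synthetic multi-state connectomes with planted edge effects
#'
#' Builds symmetric, zero-diagonal Fisher-z FC matrices for every state in
#' the configuration. Planted relevant edges carry a linear dependence on
#' the designated intelligence component scaled by the state's signal
#' parameter, organized in partially redundant hub-sharing blocks;
#' confounds leak additively into edge values; all other variation is
#' independent Gaussian noise around network-structured base means.
#' Deterministic per seed.
#'
#' @param truth Ground-truth list from [generateCohort()].
#' @param cohortTable Cohort data.frame (confounds are read from it; it is
#'   attached as \code{colData}).
#' @param atlas A [NodeAtlas-class].
#' @param config A [connectomeConfig()].
#' @param seed Integer seed.
#' @return A [ConnectomeSet-class] whose metadata ground truth gains
#'   \code{relevant_edges}, \code{relevant_block}, \code{effect_sizes}, and
#'   the generator config.
#' @export
generateConnectomes <- function(truth, cohortTable, atlas,
                                config = connectomeConfig(), seed) {
  stopifnot(inherits(config, "connectomeConfig"), is(atlas, "NodeAtlas"))
  if (!length(names(config$states)))
    stop("states must be a named numeric vector of signal scales")
  n <- nrow(cohortTable)
  if (n != length(truth$true_g))
    stop("cohort table and ground truth disagree on subject count")
  nN <- nNodes(atlas)
  nE <- nConnections(nN)
  .withSeed(seed, {

  et <- edgeIndexTable(nN)
  within <- networks(atlas)[et$i] == networks(atlas)[et$j]
  baseMean <- stats::rnorm(nE, ifelse(within, config$meanWithin,
                                      config$meanBetween), config$meanSD)

  planted <- plantRelevantEdges(nN, config$nRelevant, config$blockSize)
  beta <- numeric(nE)
  beta[planted$edges] <- stats::runif(length(planted$edges),
                                      config$effectRange[1],
                                      config$effectRange[2])

  confNames <- c("age", "sex", "handedness", "mean_fd", "spike_prop")
  C <- scale(as.matrix(cohortTable[, confNames]))
  leak <- matrix(stats::rnorm(nE * ncol(C), 0, config$confoundLeakSD),
                 nE, ncol(C))
  leakTerm <- tcrossprod(leak, C)          # edges x subjects

  comp <- switch(config$component, g = truth$true_g, gc = truth$true_gc,
                 gf = truth$true_gf,
                 stop("unknown component: ", config$component))
  comp <- as.numeric(scale(comp))
  tau <- config$redundancyNoise
  nBlocks <- max(planted$block)

  assaysList <- lapply(names(config$states), function(st) {
    sc <- config$states[[st]]
    # block latents: shared component part + block-specific noise, per state
    blockNoise <- matrix(stats::rnorm(nBlocks * n), nBlocks, n)
    blockLatent <- sqrt(1 - tau) * matrix(comp, nBlocks, n, byrow = TRUE) +
      sqrt(tau) * blockNoise
    signal <- matrix(0, nE, n)
    signal[planted$edges, ] <- beta[planted$edges] *
      blockLatent[planted$block, , drop = FALSE] * sc
    noise <- matrix(stats::rnorm(nE * n, 0, config$noiseSD), nE, n)
    baseMean + signal + leakTerm + noise
  })
  names(assaysList) <- names(config$states)

  truth$relevant_edges <- planted$edges
  truth$relevant_block <- planted$block
  truth$effect_sizes <- beta[planted$edges]
  truth$connectomeConfig <- config
  truth$connectomeSeed <- as.integer(seed)
  ConnectomeSet(assaysList, atlas, cohortTable, truth = truth,
                seed = as.integer(seed))
  })
}

#' One-call synthetic study
#'
#' Convenience wrapper: generate a cohort, apply motion exclusion, and
#' generate connectomes for the excluded-subjects-removed cohort.
#'
#' @param cohortCfg A [cohortConfig()].
#' @param connCfg A [connectomeConfig()].
#' @param atlas A [NodeAtlas-class].
#' @param seed Integer seed (cohort uses \code{seed}, connectomes
#'   \code{seed + 1}).
#' @param motionExclusion Apply the default motion criteria first?
#' @return A [ConnectomeSet-class].
#' @export
simulateStudy <- function(cohortCfg = cohortConfig(),
                          connCfg = connectomeConfig(),
                          atlas = syntheticAtlas(), seed = 1,
                          motionExclusion = TRUE) {
  sim <- generateCohort(cohortCfg, seed = seed)
  keep <- seq_len(nrow(sim$cohort))
  if (motionExclusion) {
    kept <- excludeByMotion(sim$cohort)
    keep <- match(kept$id, sim$cohort$id)
  }
  truth <- sim$truth
  for (f in c("true_g", "true_gc", "true_gf", "u_fluid", "u_crystallized"))
    truth[[f]] <- truth[[f]][keep]
  generateConnectomes(truth, sim$cohort[keep, , drop = FALSE], atlas,
                      connCfg, seed = seed + 1L)
}
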
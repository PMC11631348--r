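permP <- function(nExtreme, m) (nExtreme + 1) / (m + 1)

#' Permutation test of prediction performance
#'
#' Builds the null distribution by rerunning the full prediction pipeline
#' on randomly shuffled target scores (random assignment between subjects
#' and scores; shuffling happens before deconfounding and fold
#' construction so the null preserves the entire pipeline) and compares
#' the observed performance on the Fisher-z scale. The p-value uses the
#' bias-avoiding plus-one estimator \eqn{(b + 1)/(m + 1)} and is therefore
#' never exactly zero.
#'
#' @param runner Function \code{f(target)} that executes the pipeline for
#'   a target vector and returns the performance correlation r (e.g. the
#'   mean over repetitions).
#' @param target Observed target scores.
#' @param m Number of permutations (default 100).
#' @param seed Integer seed.
#' @param observed Optional precomputed observed r; if NULL,
#'   \code{runner(target)} is called.
#' @return List of class \code{permutationResult}: observed, null
#'   (length m), p, transform.
#' @export
permutationTestPerformance <- function(runner, target, m = 100, seed = 1,
                                       observed = NULL) {
  if (m < 1) stop("'m' must be at least 1")
  if (is.null(observed)) observed <- runner(target)
  # draw all permutations up front: runners may reset the RNG internally
  # (seeded folds, weight initialization), which must not make successive
  # shuffles dependent
  perms <- .withSeed(seed, lapply(seq_len(m), function(i)
    sample.int(length(target))))
  nullVals <- vapply(perms, function(ix) runner(target[ix]), numeric(1))
  zObs <- atanh(pmin(pmax(observed, -1 + 1e-12), 1 - 1e-12))
  zNull <- atanh(pmin(pmax(nullVals, -1 + 1e-12), 1 - 1e-12))
  p <- permP(sum(zNull >= zObs), m)
  structure(list(observed = observed, null = nullVals, p = p, m = m,
                 transform = "Fisher z", seed = as.integer(seed)),
            class = "permutationResult")
}

#' Permutation test of a performance difference between two models
#'
#' The observed statistic is the difference in prediction performance
#' (Fisher-z transformed r) between two pipeline configurations trained
#' on the correct scores; the null pairs both pipelines on the same
#' shuffled targets. Two-sided by default.
#'
#' @param runnerA,runnerB Functions \code{f(target)} returning performance
#'   r for the two configurations (same subjects and targets).
#' @param target Observed target scores.
#' @param m Number of permutations.
#' @param seed Integer seed.
#' @param observedA,observedB Optional precomputed observed r values.
#' @param alternative "two.sided" (default) or "greater" (A > B).
#' @return A \code{permutationResult} (observed = zA - zB).
#' @export
modelDifferenceTest <- function(runnerA, runnerB, target, m = 100, seed = 1,
                                observedA = NULL, observedB = NULL,
                                alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (m < 1) stop("'m' must be at least 1")
  z <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  if (is.null(observedA)) observedA <- runnerA(target)
  if (is.null(observedB)) observedB <- runnerB(target)
  obs <- z(observedA) - z(observedB)
  perms <- .withSeed(seed, lapply(seq_len(m), function(i)
    sample.int(length(target))))
  nullVals <- vapply(perms, function(ix) {
    ys <- target[ix]
    z(runnerA(ys)) - z(runnerB(ys))
  }, numeric(1))
  p <- if (alternative == "greater") permP(sum(nullVals >= obs), m)
  else min(1, 2 * min(permP(sum(nullVals >= obs), m),
                      permP(sum(nullVals <= obs), m)))
  structure(list(observed = obs, observedA = observedA,
                 observedB = observedB, null = nullVals, p = p, m = m,
                 transform = "Fisher z", alternative = alternative,
                 seed = as.integer(seed)),
            class = "permutationResult")
}

#' @export
print.permutationResult <- function(x, ...) {
  cat("Permutation test (", x$m, " permutations, ", x$transform,
      " scale)\n", sep = "")
  cat(sprintf("  observed = %.4f, p = %.4f\n", x$observed, x$p))
  invisible(x)
}

#' Paired t-test on performance vectors
#'
#' Standard paired t statistic with n - 1 degrees of freedom, used to
#' compare averaged prediction performance between intelligence
#' components or cognitive states. Zero-variance differences (all
#' differences identical and nonzero) are flagged as degenerate with an
#' infinite t.
#'
#' @param a,b Paired numeric vectors (length >= 3).
#' @return List: t, df, p, meanDiff, degenerate flag.
#' @export
pairedTTest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  d <- a - b
  if (stats::sd(d) < .Machine$double.eps) {
    if (all(abs(d) < .Machine$double.eps))
      return(list(t = 0, df = length(d) - 1, p = 1, meanDiff = 0,
                  degenerate = FALSE))
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1, p = 0,
                meanDiff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, meanDiff = mean(d), degenerate = FALSE)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up false-discovery-rate control at level q.
#'
#' @param p Numeric p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return List: \code{adjusted} p-values and logical \code{significant}
#'   flags (monotone in p).
#' @export
fdrCorrect <- function(p, q = 0.05) {
  if (!length(p)) stop("empty p-value vector")
  if (any(p <= 0 | p > 1)) stop("p-values must be in (0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  list(adjusted = adj, significant = adj <= q)
}

#' Within-module degree z-score
#'
#' For each node, the within-module degree (sum of connection weights to
#' nodes of its own module) standardized against the distribution of
#' within-module degrees in that module: \eqn{z_i = (\kappa_i -
#' \bar\kappa_{m(i)}) / \sigma_{\kappa_{m(i)}}}. Computed on weighted
#' matrices by default; pass a binarized matrix for the binary variant.
#' When a module's within-degree SD is zero, z is defined as 0 (flagged
#' via attribute).
#'
#' @param W Symmetric connectivity matrix, zero diagonal.
#' @param membership Module label per node (partition covering all
#'   nodes).
#' @return Numeric per-node z-score.
#' @export
withinModuleDegreeZ <- function(W, membership) {
  W <- as.matrix(W)
  n <- nrow(W)
  stopifnot(ncol(W) == n, length(membership) == n, !anyNA(membership))
  z <- numeric(n)
  flagged <- integer(0)
  for (mod in unique(membership)) {
    idx <- which(membership == mod)
    kappa <- rowSums(W[idx, idx, drop = FALSE])
    s <- stats::sd(kappa)
    if (is.na(s) || s < .Machine$double.eps) {
      z[idx] <- 0
      flagged <- c(flagged, idx)
    } else {
      z[idx] <- (kappa - mean(kappa)) / s
    }
  }
  if (length(flagged)) attr(z, "flagged") <- flagged
  z
}

#' Participation coefficient
#'
#' \eqn{PC_i = 1 - \sum_s (\kappa_{is} / k_i)^2}, where \eqn{\kappa_{is}}
#' is node i's connection strength to module s and \eqn{k_i} its total
#' strength: 0 for a node confined to one module, approaching
#' \eqn{1 - 1/m} for strength spread evenly over m modules. Weighted by
#' default; zero-strength nodes get PC = 0 (flagged via attribute).
#'
#' @inheritParams withinModuleDegreeZ
#' @return Numeric per-node participation coefficient.
#' @export
participationCoefficient <- function(W, membership) {
  W <- as.matrix(W)
  n <- nrow(W)
  stopifnot(ncol(W) == n, length(membership) == n, !anyNA(membership))
  mods <- unique(membership)
  k <- rowSums(W)
  frac2 <- numeric(n)
  for (mod in mods) {
    ks <- rowSums(W[, membership == mod, drop = FALSE])
    frac2 <- frac2 + ifelse(k > 0, (ks / k)^2, 0)
  }
  pc <- 1 - frac2
  zero <- which(k <= .Machine$double.eps)
  pc[zero] <- 0
  if (length(zero)) attr(pc, "flagged") <- zero
  pc
}

#' Occurrence-weighted node statistic of an edge selection
#'
#' Average of products of each node's occurrence count among the selected
#' edges and a per-node metric (e.g. participation coefficient or
#' within-module degree z), normalized by the total occurrence count;
#' used to characterize the endpoints of relevant connections.
#'
#' @param edgeIdx Selected edge indices.
#' @param nodeMetric Numeric per-node metric.
#' @param nNodesTotal Number of nodes.
#' @return Weighted mean of the node metric.
#' @export
nodeOccurrenceStat <- function(edgeIdx, nodeMetric, nNodesTotal) {
  et <- edgeIndexTable(nNodesTotal)
  occ <- tabulate(c(et$i[edgeIdx], et$j[edgeIdx]), nbins = nNodesTotal)
  sum(occ * nodeMetric) / sum(occ)
}

#' Compare properties of a selected edge set with random edge sets
#'
#' For each property, compares the statistic of the selected edges with
#' its distribution over \code{nPerm} equally sized uniformly random edge
#' sets; the two-sided permutation p-value uses the plus-one estimator on
#' each tail (doubled, capped at 1). Properties are given either as
#' per-edge numeric vectors (statistic = mean over selected edges, e.g. a
#' confound correlation or retest ICC per edge) or as functions
#' \code{f(edgeIdx)} returning a scalar (e.g. an occurrence-weighted
#' graph metric).
#'
#' @param selection A [ConnectionSelection-class] (or edge index vector).
#' @param properties Named list of per-edge numeric vectors and/or
#'   functions of edge indices.
#' @param nEdgesTotal Total edge pool size.
#' @param nPerm Number of random edge sets (default 1000).
#' @param seed Integer seed.
#' @return data.frame: property, observed, p.
#' @export
relevantVsRandomEdgeComparison <- function(selection, properties,
                                           nEdgesTotal, nPerm = 1000,
                                           seed = 1) {
  edgeIdx <- if (is(selection, "ConnectionSelection"))
    which(selection@mask) else as.integer(selection)
  k <- length(edgeIdx)
  if (k > nEdgesTotal) stop("selection larger than the edge pool")
  statOf <- function(prop, idx) {
    if (is.function(prop)) prop(idx) else mean(prop[idx])
  }
  obs <- vapply(properties, statOf, numeric(1), idx = edgeIdx)
  draws <- .withSeed(seed, lapply(seq_len(nPerm), function(i)
    sample.int(nEdgesTotal, k)))
  nullMat <- vapply(draws, function(idx)
    vapply(properties, statOf, numeric(1), idx = idx),
    numeric(length(properties)))
  nullMat <- matrix(nullMat, nrow = length(properties))
  p <- vapply(seq_along(properties), function(j) {
    up <- permP(sum(nullMat[j, ] >= obs[j]), nPerm)
    lo <- permP(sum(nullMat[j, ] <= obs[j]), nPerm)
    min(1, 2 * min(up, lo))
  }, numeric(1))
  data.frame(property = names(properties), observed = unname(obs), p = p,
             stringsAsFactors = FALSE)
}
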
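#' Layer-wise relevance propagation (epsilon rule)
#'
#' Attributes a trained MLP's scalar output to its input features by
#' propagating relevance from the output layer back to the inputs: at each
#' linear layer the relevance of an output neuron is distributed to its
#' inputs in proportion to their contribution \eqn{a_i w_{ij}} to the
#' pre-activation \eqn{z_j}, stabilized by \eqn{\epsilon\,\mathrm{sign}(z_j)}.
#' For a bias-free network the per-sample relevances sum to the model
#' output up to epsilon-controlled leakage. Dropout is inactive at
#' attribution time.
#'
#' @param model An \code{mlpModel} with rectified-linear hidden layers.
#' @param X Input feature matrix (samples x features), finite.
#' @param epsilon Stabilizer of the epsilon rule.
#' @return Matrix of per-sample, per-feature relevance (samples x
#'   features), signed.
#' @export
lrpAttribute <- function(model, X, epsilon = 1e-6) {
  stopifnot(inherits(model, "mlpModel"))
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("inputs must be finite")
  nLayers <- length(model$W)
  A <- vector("list", nLayers + 1L)
  A[[1L]] <- X
  for (l in seq_len(nLayers)) {
    Z <- sweep(A[[l]] %*% model$W[[l]], 2, model$b[[l]], "+")
    A[[l + 1L]] <- if (l < nLayers) pmax(Z, 0) else Z
  }
  R <- A[[nLayers + 1L]]            # samples x 1: output relevance
  for (l in nLayers:1) {
    Z <- sweep(A[[l]] %*% model$W[[l]], 2, model$b[[l]], "+")
    Zs <- Z + epsilon * ifelse(Z >= 0, 1, -1)
    S <- R / Zs
    R <- (S %*% t(model$W[[l]])) * A[[l]]
  }
  R
}

#' Stepwise layer-wise relevance propagation
#'
#' Produces a full priority ordering of features (edges) by iteratively
#' training a model on all remaining features, attributing relevance on
#' the training data, recording and removing the current most relevant
#' block, and retraining on the remainder. Blocks are ordered by removal
#' round; within a block, features are ordered by relevance. If the
#' removal schedule does not exhaust the features, a final model ranks
#' the remainder.
#'
#' @param X Feature matrix (samples x features), typically deconfounded
#'   training-fold data (attribution never sees test subjects).
#' @param y Target.
#' @param schedule Integer vector of per-round removal counts; its sum
#'   must not exceed the feature count. Default: geometric rounds removing
#'   the top 1\% of remaining features (minimum 10) until exhausted.
#' @param hidden Architecture used for the per-round models.
#' @param familyId Optional family ids for the early-stopping split.
#' @param epsilon LRP stabilizer.
#' @param rankBy "absolute" (default) or "signed" mean relevance.
#' @param seed Integer seed.
#' @param ... Passed to [mlpTrain()] (e.g. \code{maxEpochs},
#'   \code{patience}).
#' @return A [RelevanceMap-class] whose \code{ranking} is the priority
#'   ordering (most relevant first) and whose \code{relevance} holds the
#'   mean signed relevance each feature had in the round it was removed.
#' @export
stepwiseLRP <- function(X, y, schedule = NULL, hidden = c(10),
                        familyId = NULL, epsilon = 1e-6,
                        rankBy = c("absolute", "signed"), seed = 1, ...) {
  rankBy <- match.arg(rankBy)
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(schedule)) {
    schedule <- integer(0)
    left <- p
    while (left > 0) {
      s <- min(left, max(10L, ceiling(0.01 * left)))
      schedule <- c(schedule, s)
      left <- left - s
    }
  }
  if (sum(schedule) > p) stop("removal schedule exceeds feature count")
  remaining <- seq_len(p)
  ordering <- integer(0)
  removedRel <- numeric(p)
  round_ <- 0L
  rankKey <- function(v) if (rankBy == "absolute") abs(v) else v
  for (s in schedule) {
    if (!length(remaining)) stop("no features left before schedule end")
    round_ <- round_ + 1L
    m <- mlpTrain(X[, remaining, drop = FALSE], y, hidden = hidden,
                  familyId = familyId, seed = seed + round_, ...)
    rel <- colMeans(lrpAttribute(m, X[, remaining, drop = FALSE], epsilon))
    top <- order(rankKey(rel), -seq_along(rel), decreasing = TRUE)[
      seq_len(min(s, length(remaining)))]
    ordering <- c(ordering, remaining[top])
    removedRel[remaining[top]] <- rel[top]
    remaining <- remaining[-top]
  }
  if (length(remaining)) {
    round_ <- round_ + 1L
    m <- mlpTrain(X[, remaining, drop = FALSE], y, hidden = hidden,
                  familyId = familyId, seed = seed + round_, ...)
    rel <- colMeans(lrpAttribute(m, X[, remaining, drop = FALSE], epsilon))
    ord <- order(rankKey(rel), -seq_along(rel), decreasing = TRUE)
    ordering <- c(ordering, remaining[ord])
    removedRel[remaining] <- rel
  }
  RelevanceMap(relevance = removedRel, ranking = ordering,
               details = list(schedule = schedule, hidden = hidden,
                              seed = seed, rankBy = rankBy,
                              method = "stepwise LRP"))
}

#' Aggregate relevance over folds and repetitions
#'
#' Averages per-edge relevance values across runs; when the inputs carry
#' explicit priority orderings (stepwise LRP), edges are aggregated by
#' mean rank instead. Deterministic and invariant to run order.
#'
#' @param maps List of [RelevanceMap-class] objects (or numeric relevance
#'   vectors) over identical edge sets.
#' @return A single [RelevanceMap-class].
#' @export
aggregateRelevance <- function(maps) {
  stopifnot(length(maps) >= 1L)
  maps <- lapply(maps, function(m)
    if (is(m, "RelevanceMap")) m else RelevanceMap(relevance = m))
  nE <- unique(vapply(maps, function(m)
    max(length(m@relevance), length(m@ranking)), numeric(1)))
  if (length(nE) != 1L) stop("mismatched edge sets")
  hasRanking <- all(vapply(maps, function(m) length(m@ranking) > 0,
                           logical(1)))
  relMat <- vapply(maps, function(m) {
    if (length(m@relevance)) m@relevance else rep(NA_real_, nE)
  }, numeric(nE))
  meanRel <- rowMeans(relMat)
  if (hasRanking) {
    rankMat <- vapply(maps, function(m) {
      r <- integer(nE)
      r[m@ranking] <- seq_along(m@ranking)
      as.numeric(r)
    }, numeric(nE))
    meanRank <- rowMeans(rankMat)
    ord <- order(meanRank, seq_len(nE))
    RelevanceMap(relevance = meanRel, ranking = ord,
                 details = list(aggregated = length(maps),
                                by = "mean rank"))
  } else {
    RelevanceMap(relevance = meanRel,
                 details = list(aggregated = length(maps),
                                by = "mean relevance"))
  }
}

#' Percentage overlap between two equally sized edge sets
#'
#' @param a,b Edge index vectors (or [ConnectionSelection-class] objects)
#'   of equal size k.
#' @return Overlap percentage, \code{100 * |a intersect b| / k}.
#' @export
overlapFraction <- function(a, b) {
  if (is(a, "ConnectionSelection")) a <- which(a@mask)
  if (is(b, "ConnectionSelection")) b <- which(b@mask)
  if (length(a) != length(b)) stop("edge sets must have equal size")
  100 * length(intersect(a, b)) / length(a)
}
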
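#' Fisher-z functional connectivity from node time series
#'
#' Computes Pearson correlations between all node pairs and applies the
#' Fisher z-transform (atanh). Correlations with \eqn{|r| \ge 1 - 10^{-7}}
#' are clipped to that bound before the transform (with a warning), since
#' atanh diverges at +-1.
#'
#' @param ts Numeric matrix, nodes x time (>= 3 time points).
#' @param clip Clip bound for \eqn{|r|}.
#' @return Symmetric Fisher-z matrix with zero diagonal.
#' @examples
#' ts <- matrix(rnorm(5 * 50), 5)
#' z <- timeseriesToFC(ts)
#' all.equal(z, t(z))
#' @export
timeseriesToFC <- function(ts, clip = 1 - 1e-7) {
  ts <- as.matrix(ts)
  if (ncol(ts) < 3) stop("need at least 3 time points")
  sds <- apply(ts, 1, stats::sd)
  if (any(sds < .Machine$double.eps))
    stop("constant time series for node(s): ",
         paste(which(sds < .Machine$double.eps), collapse = ", "))
  r <- stats::cor(t(ts))
  diag(r) <- 0
  if (any(abs(r) >= clip)) {
    warning("correlation(s) with |r| >= ", format(clip),
            " clipped before Fisher transform")
    r <- pmin(pmax(r, -clip), clip)
  }
  z <- atanh(r)
  diag(z) <- 0
  z
}

#' Average two phase-encoding runs on the Fisher-z scale
#'
#' FC is computed for the two phase-encoding directions separately and
#' averaged afterward; the average is elementwise on the z scale.
#'
#' @param fcA,fcB Fisher-z matrices (or edge vectors) of equal shape.
#' @return Elementwise mean.
#' @export
averagePhaseRuns <- function(fcA, fcB) {
  if (!identical(dim(fcA), dim(fcB)) || length(fcA) != length(fcB))
    stop("run matrices must have identical shape")
  (fcA + fcB) / 2
}

#' Connection-wise latent FC across states
#'
#' For each edge independently, fits a one-factor model across states
#' (observations = subjects) and returns standardized latent edge scores
#' per subject plus the per-state loadings. Two canonical modes mirror the
#' study design: a latent FC across resting state and all task states, and
#' one across task states only.
#'
#' Estimation is maximum likelihood with a principal-axis fallback on
#' non-convergence; the factor sign is fixed so that the mean loading is
#' positive. Edges whose across-subject variance vanishes in some state
#' are flagged and receive the documented fallback: the standardized
#' state-mean edge value.
#'
#' @param x A [ConnectomeSet-class], or a 3-d array edges x states x
#'   subjects.
#' @param mode "rest+tasks" (all states) or "tasks-only" (drops
#'   \code{restState}). Ignored when \code{states} is given.
#' @param restState Name of the resting state (default "rest").
#' @param states Optional explicit state subset.
#' @return List of class \code{latentFCFit}: \code{scores} (edges x
#'   subjects), \code{loadings} (edges x states), \code{flagged} (edge
#'   indices that used the fallback), \code{states}.
#' @export
latentFC <- function(x, mode = c("rest+tasks", "tasks-only"),
                     restState = "rest", states = NULL) {
  mode <- match.arg(mode)
  if (is(x, "ConnectomeSet")) {
    stateNames <- assayNames(x)
    arr <- simplify2array(as.list(assays(x)))   # edges x subjects x states
    arr <- aperm(arr, c(1, 3, 2))
  } else {
    arr <- x
    stateNames <- dimnames(arr)[[2]]
    if (is.null(stateNames)) stateNames <- paste0("state", seq_len(dim(arr)[2]))
  }
  if (is.null(states)) {
    states <- if (mode == "tasks-only")
      setdiff(stateNames, restState) else stateNames
  }
  sIdx <- match(states, stateNames)
  if (anyNA(sIdx)) stop("unknown state(s): ",
                        paste(states[is.na(sIdx)], collapse = ", "))
  if (length(sIdx) < 3) stop("need at least 3 states for a latent FC")
  nE <- dim(arr)[1]
  nSub <- dim(arr)[3]
  scores <- matrix(NA_real_, nE, nSub)
  loadings <- matrix(NA_real_, nE, length(sIdx),
                     dimnames = list(NULL, states))
  flagged <- integer(0)
  for (e in seq_len(nE)) {
    D <- t(arr[e, sIdx, , drop = TRUE])        # subjects x states
    sds <- apply(D, 2, stats::sd)
    if (any(sds < 1e-10)) {
      flagged <- c(flagged, e)
      m <- rowMeans(D)
      scores[e, ] <- if (stats::sd(m) > 0) as.numeric(scale(m)) else 0
      next
    }
    f <- .oneFactorScores(D)
    scores[e, ] <- f$scores
    loadings[e, ] <- f$loadings
  }
  structure(list(scores = scores, loadings = loadings, flagged = flagged,
                 states = states), class = "latentFCFit")
}

# one-factor ML fit of a subjects x variables matrix; principal-axis
# fallback; regression scores standardized; mean loading forced positive
.oneFactorScores <- function(D) {
  R <- stats::cor(D)
  fit <- tryCatch(stats::factanal(factors = 1, covmat = R, n.obs = nrow(D),
                                  rotation = "none"),
                  error = function(e) NULL)
  if (is.null(fit)) {
    ev <- eigen(R, symmetric = TRUE)
    L <- ev$vectors[, 1] * sqrt(max(ev$values[1], 0))
  } else {
    L <- as.numeric(stats::loadings(fit))
  }
  if (mean(L) < 0) L <- -L
  w <- solve(R + diag(1e-8, ncol(R)), L)
  s <- scale(D) %*% w
  sds <- stats::sd(s)
  list(scores = if (sds > 0) as.numeric(s / sds) else as.numeric(s),
       loadings = L)
}

#' Append latent-FC states to a ConnectomeSet
#'
#' Adds two assays, \code{latent} (across rest and all task states) and
#' \code{latent_task} (task states only), holding the per-edge latent
#' scores.
#'
#' @param x A [ConnectomeSet-class] of measured states.
#' @param restState Name of the resting state.
#' @return The input with two additional assays.
#' @export
appendLatentStates <- function(x, restState = "rest") {
  la <- latentFC(x, mode = "rest+tasks")
  lt <- latentFC(x, mode = "tasks-only", restState = restState)
  a <- as.list(assays(x))
  a$latent <- la$scores
  a$latent_task <- lt$scores
  a <- lapply(a, function(m) { colnames(m) <- cohort(x)$id; m })
  ConnectomeSet(a, atlas(x), cohort(x), truth = groundTruth(x),
                seed = metadata(x)$seed)
}

#' Per-edge test-retest intraclass correlation between two runs
#'
#' ICC(2,1): two-way random effects, absolute agreement, single
#' measurement, computed per edge from paired run measurements.
#'
#' @param run1,run2 Edge x subject matrices (or vectors) of paired
#'   measurements.
#' @return Numeric per-edge ICC; edges with zero between-subject variance
#'   are returned as NA with a warning.
#' @export
iccRetest <- function(run1, run2) {
  if (is.null(dim(run1))) run1 <- matrix(run1, nrow = 1)
  if (is.null(dim(run2))) run2 <- matrix(run2, nrow = 1)
  if (!identical(dim(run1), dim(run2)))
    stop("run matrices must have identical shape")
  n <- ncol(run1)
  k <- 2
  if (n < 3) stop("need at least 3 subjects")
  subjMean <- (run1 + run2) / 2
  grandMean <- rowMeans(subjMean)
  colMean1 <- rowMeans(run1)
  colMean2 <- rowMeans(run2)
  ssR <- k * rowSums((subjMean - grandMean)^2)
  ssC <- n * ((colMean1 - grandMean)^2 + (colMean2 - grandMean)^2)
  ssTot <- rowSums((run1 - grandMean)^2) + rowSums((run2 - grandMean)^2)
  ssE <- ssTot - ssR - ssC
  msR <- ssR / (n - 1)
  msC <- ssC / (k - 1)
  msE <- ssE / ((n - 1) * (k - 1))
  icc <- (msR - msE) / (msR + (k - 1) * msE + k * (msC - msE) / n)
  zeroVar <- msR < .Machine$double.eps
  if (any(zeroVar)) {
    warning(sum(zeroVar), " edge(s) with zero between-subject variance; ",
            "ICC undefined (NA)")
    icc[zeroVar] <- NA_real_
  }
  icc
}
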
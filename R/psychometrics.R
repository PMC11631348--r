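# Maximum-likelihood EFA with a graceful fallback. factanal() fails on
# (near-)singular correlation matrices and occasionally does not converge;
# in that case principal-axis loadings (eigenvectors scaled by root
# eigenvalues) are used and flagged.
.efaLoadings <- function(R, nFactors, nObs) {
  fit <- tryCatch(
    stats::factanal(factors = nFactors, covmat = R, n.obs = nObs,
                    rotation = "none"),
    error = function(e) e)
  if (inherits(fit, "error")) {
    ev <- eigen(R, symmetric = TRUE)
    L <- ev$vectors[, seq_len(nFactors), drop = FALSE] %*%
      diag(sqrt(pmax(ev$values[seq_len(nFactors)], 0)), nFactors)
    rownames(L) <- rownames(R)
    return(list(loadings = L, method = "principal-axis fallback",
                message = conditionMessage(fit)))
  }
  list(loadings = unclass(stats::loadings(fit)), method = "ml")
}

# regression (Thurstone) factor scores, standardized; a tiny ridge keeps
# the correlation-matrix inverse defined in degenerate rank-deficient cases
.regressionScores <- function(Xstd, R, L) {
  ridge <- 1e-8 * mean(diag(R))
  S <- Xstd %*% solve(R + diag(ridge, nrow(R)), L)
  apply(S, 2, function(s) {
    sds <- stats::sd(s)
    if (sds < .Machine$double.eps) s else s / sds
  })
}

#' Estimate general intelligence (g) via an exploratory bifactor model
#'
#' Two-stage exploratory bifactor analysis with Schmid-Leiman
#' orthogonalization: (1) maximum-likelihood EFA with \code{nGroup} factors
#' and an oblique (promax) rotation; (2) a single second-order factor of
#' the factor inter-correlations; (3) Schmid-Leiman transformation into
#' one general factor loading on all measures plus orthogonal group
#' factors. Factor scores are computed by the regression (Thurstone)
#' method and standardized. The sign convention forces the majority of
#' general-factor loadings to be non-negative.
#'
#' @param measures Numeric matrix, subjects x measures (>= 12 measures
#'   recommended, no missing values).
#' @param nGroup Number of group factors in the first-stage EFA
#'   (default 4).
#' @return List of class \code{bifactorFit}: \code{g} (standardized
#'   scores), \code{loadings} (measures x [general, groups]), \code{scores}
#'   (all factor scores), \code{rotation}, \code{heywood} flag,
#'   \code{method}.
#' @export
estimateGBifactor <- function(measures, nGroup = 4) {
  X <- as.matrix(measures)
  if (anyNA(X)) stop("measures must not contain missing values; drop ",
                     "subjects with incomplete measures first")
  if (nrow(X) <= ncol(X))
    stop("need more subjects than measures")
  Xstd <- scale(X)
  if (any(attr(Xstd, "scaled:scale") < .Machine$double.eps))
    stop("zero-variance measure(s): ",
         paste(colnames(X)[attr(Xstd, "scaled:scale") <
                             .Machine$double.eps], collapse = ", "))
  R <- stats::cor(X)

  # degenerate rank-1 battery: the general factor is the common vector
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] < 1e-8 * ev[1]) {
    h <- sqrt(pmax(rowMeans(R), 0))
    g <- .regressionScores(Xstd, R, matrix(h, ncol = 1))[, 1]
    return(structure(list(g = as.numeric(g),
                          loadings = cbind(general = h),
                          scores = cbind(g = as.numeric(g)),
                          rotation = "none (rank-1 battery)",
                          heywood = FALSE, method = "rank-1"),
                     class = "bifactorFit"))
  }

  first <- .efaLoadings(R, nGroup, nrow(X))
  L0 <- first$loadings
  if (nGroup > 1) {
    pro <- stats::promax(L0)
    L <- unclass(pro$loadings)
    U <- pro$rotmat
    Phi <- solve(crossprod(U))
    Phi <- stats::cov2cor((Phi + t(Phi)) / 2)
  } else {
    L <- L0
    Phi <- matrix(1, 1, 1)
  }
  # orient each group factor so its salient loadings are positive
  flip <- sign(colSums(L^3))
  flip[flip == 0] <- 1
  L <- sweep(L, 2, flip, "*")
  Phi <- diag(flip) %*% Phi %*% diag(flip)

  # second-order general factor from the factor inter-correlations
  if (nGroup >= 3) {
    g2 <- .efaLoadings(Phi, 1, nrow(X))
    gamma <- as.numeric(g2$loadings)
  } else if (nGroup == 2) {
    gamma <- rep(sqrt(max(min(Phi[1, 2], 1 - 1e-6), 0)), 2)
  } else {
    gamma <- 1
  }
  gamma <- pmin(pmax(gamma, 0), 1 - 1e-6)

  # Schmid-Leiman orthogonalization
  general <- as.numeric(L %*% gamma)
  groups <- L %*% diag(sqrt(1 - gamma^2), nGroup)
  if (mean(general >= 0) < 0.5) {
    general <- -general
  }
  Lsl <- cbind(general = general, groups)
  colnames(Lsl) <- c("general", paste0("group", seq_len(nGroup)))
  communality <- rowSums(Lsl^2)
  heywood <- any(communality > 1 + 1e-6)

  scores <- .regressionScores(Xstd, R, Lsl)
  g <- scores[, 1]
  if (stats::cor(g, Xstd %*% general) < 0) g <- -g   # guard score sign
  structure(list(g = as.numeric(g), loadings = Lsl, scores = scores,
                 rotation = "promax (oblique first stage)",
                 heywood = heywood, method = first$method),
            class = "bifactorFit")
}

#' Estimate fluid intelligence (gF) via single-factor EFA
#'
#' Maximum-likelihood exploratory factor analysis with one factor on the
#' designated fluid measures; with a single factor the configured oblique
#' rotation is a no-op but its name is recorded. Scores by the regression
#' method, standardized, oriented so the mean loading is positive.
#'
#' @param measures Numeric matrix, subjects x fluid measures (canonically
#'   the seven fluid-defining tasks).
#' @param rotation Rotation name recorded in the fit (default "oblimin").
#' @return List of class \code{efaFit}: \code{gf} (standardized scores),
#'   \code{loadings}, \code{rotation}, \code{method}.
#' @export
estimateGfEfa <- function(measures, rotation = "oblimin") {
  X <- as.matrix(measures)
  if (anyNA(X)) stop("measures must not contain missing values")
  Xstd <- scale(X)
  if (any(attr(Xstd, "scaled:scale") < .Machine$double.eps))
    stop("zero-variance measure(s)")
  R <- stats::cor(X)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] < 1e-8 * ev[1]) {
    h <- sqrt(pmax(rowMeans(R), 0))
    fit <- list(loadings = matrix(h, ncol = 1), method = "rank-1")
  } else {
    fit <- .efaLoadings(R, 1, nrow(X))
  }
  L <- matrix(as.numeric(fit$loadings), ncol = 1)
  if (mean(L) < 0) L <- -L
  gf <- .regressionScores(Xstd, R, L)[, 1]
  structure(list(gf = as.numeric(gf), loadings = L,
                 rotation = paste(rotation, "(no-op for one factor)"),
                 method = fit$method),
            class = "efaFit")
}

#' Crystallized intelligence composite (gC)
#'
#' Sum of the standardized picture-vocabulary and reading-recognition
#' scores.
#'
#' @param vocab,reading Numeric score vectors of equal length.
#' @return Numeric gC scores (sum of two z-scores; SD about sqrt(2) for
#'   independent inputs).
#' @export
computeGcComposite <- function(vocab, reading) {
  if (length(vocab) != length(reading))
    stop("input vectors must have equal length")
  if (anyNA(vocab) || anyNA(reading) || !all(is.finite(c(vocab, reading))))
    stop("inputs must be finite")
  if (stats::sd(vocab) < .Machine$double.eps ||
      stats::sd(reading) < .Machine$double.eps)
    stop("zero-variance input vector")
  as.numeric(scale(vocab)) + as.numeric(scale(reading))
}

#' Score the three intelligence components for a cohort
#'
#' Listwise-deletes subjects with incomplete measures, then estimates
#' g (bifactor), gF (single-factor EFA on the fluid measures), and gC
#' (standardized two-test composite).
#'
#' @param cohortTable Cohort data.frame containing the measure columns.
#' @param measureMap List with elements \code{all}, \code{fluid},
#'   \code{crystallized} naming the measure columns (see
#'   [defaultMeasureMap()]).
#' @param nGroup Group-factor count for the bifactor model.
#' @return data.frame: id, g, gc, gf (standardized units).
#' @export
scoreIntelligence <- function(cohortTable, measureMap = defaultMeasureMap(),
                              nGroup = 4) {
  X <- as.matrix(cohortTable[, measureMap$all])
  complete <- stats::complete.cases(X)
  X <- X[complete, , drop = FALSE]
  ids <- cohortTable$id[complete]
  bf <- estimateGBifactor(X, nGroup = nGroup)
  ef <- estimateGfEfa(X[, measureMap$fluid, drop = FALSE])
  gc <- computeGcComposite(X[, measureMap$crystallized[1]],
                           X[, measureMap$crystallized[2]])
  data.frame(id = ids, g = bf$g, gc = gc, gf = ef$gf,
             stringsAsFactors = FALSE)
}
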
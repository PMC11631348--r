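#' Fit an out-of-sample deconfounding model on training data
#'
#' Regresses the confounds out of the target and every feature column via
#' ordinary least squares fitted on the training sample only, then
#' z-standardizes the residuals; the regression coefficients and the
#' standardization mean and SD are stored so that test data can be
#' transformed with training parameters only (no leakage).
#'
#' @param target Numeric training target.
#' @param features Numeric training feature matrix (subjects x features),
#'   or NULL to deconfound the target only.
#' @param confounds Numeric training confound matrix (subjects x
#'   confounds), full column rank.
#' @return List of class \code{deconfoundModel}.
#' @export
fitDeconfounder <- function(target, features, confounds) {
  C <- cbind(`(Intercept)` = 1, as.matrix(confounds))
  qrC <- qr(C)
  if (qrC$rank < ncol(C))
    stop("confound matrix is rank deficient on the training data")
  fitOne <- function(y) qr.coef(qrC, y)
  coefTarget <- fitOne(target)
  resT <- target - drop(C %*% coefTarget)
  sdT <- stats::sd(resT)
  if (sdT < .Machine$double.eps) {
    # target fully explained by confounds: keep residuals on their raw
    # (all-zero) scale rather than dividing by a zero SD
    sdT <- 1
  }
  mT <- mean(resT)
  out <- list(coefTarget = coefTarget, targetMean = mT, targetSD = sdT,
              confoundNames = colnames(C))
  if (!is.null(features)) {
    X <- as.matrix(features)
    coefX <- qr.coef(qrC, X)
    resX <- X - C %*% coefX
    mX <- colMeans(resX)
    sX <- apply(resX, 2, stats::sd)
    sX[sX < .Machine$double.eps] <- 1
    out$coefFeatures <- coefX
    out$featureMean <- mX
    out$featureSD <- sX
  }
  class(out) <- "deconfoundModel"
  out
}

#' Apply a fitted deconfounding model
#'
#' Transforms target and/or features of new data using the training-fitted
#' regression coefficients and standardization parameters.
#'
#' @param model A \code{deconfoundModel} from [fitDeconfounder()].
#' @param confounds Confound matrix of the data to transform.
#' @param target Optional target vector.
#' @param features Optional feature matrix; must have the same columns the
#'   model was fitted on.
#' @return List with the transformed \code{target} and/or \code{features}.
#' @export
applyDeconfounder <- function(model, confounds, target = NULL,
                              features = NULL) {
  stopifnot(inherits(model, "deconfoundModel"))
  C <- cbind(`(Intercept)` = 1, as.matrix(confounds))
  if (ncol(C) != length(model$coefTarget))
    stop("confound columns differ from those present at fit time")
  out <- list()
  if (!is.null(target)) {
    res <- target - drop(C %*% model$coefTarget)
    out$target <- (res - model$targetMean) / model$targetSD
  }
  if (!is.null(features)) {
    if (is.null(model$coefFeatures))
      stop("model was fitted without features")
    X <- as.matrix(features)
    if (ncol(X) != ncol(model$coefFeatures))
      stop("feature columns differ from those present at fit time")
    res <- X - C %*% model$coefFeatures
    out$features <- sweep(sweep(res, 2, model$featureMean), 2,
                          model$featureSD, "/")
  }
  out
}
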
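#' Prediction performance metrics
#'
#' Pearson correlation between observed and predicted scores, plus MSE,
#' RMSE, and MAE computed after dividing both vectors by the range of the
#' observed scores (range-normalized error metrics).
#'
#' @param y Observed scores (length >= 3, non-constant).
#' @param yhat Predicted scores.
#' @return Named numeric: r, mse, rmse, mae.
#' @examples
#' performanceMetrics(c(0, 1, 2), c(0, 0, 3))
#' @export
performanceMetrics <- function(y, yhat) {
  if (length(y) < 3) stop("need at least 3 observations")
  rng <- diff(range(y))
  if (rng < .Machine$double.eps) stop("observed scores are constant")
  r <- stats::cor(y, yhat)
  yn <- y / rng
  yhn <- yhat / rng
  e <- yhn - yn
  c(r = r, mse = mean(e^2), rmse = sqrt(mean(e^2)), mae = mean(abs(e)))
}

# default control parameters of the prediction pipeline; tests and
# desk-scale runs shrink maxEpochs / patience / grid
#' Control parameters for [crossValidatedPredict()]
#'
#' @param grid Architecture grid (list of hidden-width vectors).
#' @param lr Learning rate.
#' @param dropout Dropout probability.
#' @param maxEpochs,patience Early-stopping parameters.
#' @param valFraction Outer early-stopping validation fraction.
#' @param innerFolds Inner hyperparameter-search folds.
#' @return List of class \code{predictControl}.
#' @export
predictControl <- function(grid = defaultArchitectureGrid(), lr = 0.01,
                           dropout = 0.25, maxEpochs = 20000,
                           patience = 100, valFraction = 0.2,
                           innerFolds = 3) {
  structure(list(grid = grid, lr = lr, dropout = dropout,
                 maxEpochs = maxEpochs, patience = patience,
                 valFraction = valFraction, innerFolds = innerFolds),
            class = "predictControl")
}

# one outer fold: deconfound (train-fit), tune, train, predict the test
# fold; everything training-derived depends on training rows only
.runFold <- function(X, y, C, fam, trainIdx, testIdx, control, seed) {
  dec <- fitDeconfounder(y[trainIdx], X[trainIdx, , drop = FALSE],
                         C[trainIdx, , drop = FALSE])
  tr <- applyDeconfounder(dec, C[trainIdx, , drop = FALSE],
                          target = y[trainIdx],
                          features = X[trainIdx, , drop = FALSE])
  tune <- tuneHyperparameters(tr$features, tr$target, grid = control$grid,
                              familyId = fam[trainIdx],
                              innerFolds = control$innerFolds, seed = seed,
                              lr = control$lr, dropout = control$dropout,
                              maxEpochs = control$maxEpochs,
                              patience = control$patience)
  model <- mlpTrain(tr$features, tr$target, hidden = tune$hidden,
                    valFraction = control$valFraction,
                    familyId = fam[trainIdx], lr = control$lr,
                    dropout = control$dropout,
                    maxEpochs = control$maxEpochs,
                    patience = control$patience, seed = seed + 7L)
  te <- applyDeconfounder(dec, C[testIdx, , drop = FALSE],
                          target = y[testIdx],
                          features = X[testIdx, , drop = FALSE])
  list(observed = te$target, predicted = predict(model, te$features),
       artifacts = list(deconfounder = dec, hidden = tune$hidden,
                        innerLoss = tune$innerLoss, trainLog = model$log,
                        weights = model$W))
}

#' Cross-validated intelligence prediction
#'
#' The full prediction pipeline for one feature set: family-aware
#' stratified k-fold cross-validation in which, per outer fold, confounds
#' are regressed out of target and features with training-fitted
#' parameters (out-of-sample deconfounding), the network architecture is
#' chosen by an inner 3-fold search, an MLP is trained with early
#' stopping, and the withheld fold is predicted. Optionally repeated over
#' several fold seeds ("varying stratified folds"), reporting per-
#' repetition and mean metrics.
#'
#' @param features Numeric matrix, subjects x features (e.g. from
#'   [selectionFeatures()]).
#' @param target Numeric score per subject.
#' @param confounds Numeric matrix of confounds.
#' @param familyId Family id per subject.
#' @param nFolds Outer folds (default 5).
#' @param foldSeeds Integer vector; one repetition of fresh stratified
#'   folds per seed (default a single repetition).
#' @param folds Optional fixed integer fold assignment per subject; when
#'   given it is used for every repetition instead of building stratified
#'   folds from the target (useful for leakage audits, where the fold
#'   layout must not depend on corrupted test targets).
#' @param control A [predictControl()].
#' @param keepArtifacts Keep per-fold training artifacts (deconfounder,
#'   chosen architecture, early-stop trace, weights) for leakage audits?
#' @return A [PredictionResult-class]. The \code{observed} column holds
#'   the deconfounded test-fold target (transformed with training
#'   parameters), which is what predictions are correlated against.
#' @export
crossValidatedPredict <- function(features, target, confounds, familyId,
                                  nFolds = 5, foldSeeds = 1L, folds = NULL,
                                  control = predictControl(),
                                  keepArtifacts = FALSE) {
  X <- as.matrix(features)
  C <- as.matrix(confounds)
  n <- nrow(X)
  stopifnot(length(target) == n, nrow(C) == n, length(familyId) == n)
  if (ncol(X) < 1) stop("empty connection selection")
  predList <- list()
  metricsList <- list()
  artifacts <- list()
  for (rep_ in seq_along(foldSeeds)) {
    fs <- foldSeeds[rep_]
    repFolds <- if (is.null(folds))
      makeFolds(familyId, target, nFolds = nFolds, seed = fs)$fold
    else folds
    obs <- numeric(n)
    pred <- numeric(n)
    for (f in seq_len(nFolds)) {
      testIdx <- which(repFolds == f)
      trainIdx <- which(repFolds != f)
      res <- .runFold(X, target, C, familyId, trainIdx, testIdx, control,
                      seed = fs * 1000L + f)
      obs[testIdx] <- res$observed
      pred[testIdx] <- res$predicted
      if (keepArtifacts)
        artifacts[[paste0("rep", rep_, "_fold", f)]] <- res$artifacts
    }
    predList[[rep_]] <- data.frame(subject = seq_len(n), repetition = rep_,
                                   fold = repFolds, observed = obs,
                                   predicted = pred)
    metricsList[[rep_]] <- c(repetition = rep_, performanceMetrics(obs, pred))
  }
  PredictionResult(do.call(rbind, predList),
                   as.data.frame(do.call(rbind, metricsList)),
                   artifacts = artifacts,
                   info = list(nFolds = nFolds, foldSeeds = foldSeeds))
}

#' Mean prediction performance over repetitions
#'
#' @param result A [PredictionResult-class].
#' @param metric Metric name ("r", "mse", "rmse", "mae").
#' @return Mean metric value across repetitions.
#' @export
meanPerformance <- function(result, metric = "r") {
  mean(metrics(result)[[metric]])
}

#' Train a final model on a full sample
#'
#' Fits the deconfounder, tunes the architecture, and trains one MLP on
#' the complete sample (with a family-aware early-stopping split); the
#' returned bundle can be applied to an external cohort without
#' refitting.
#'
#' @inheritParams crossValidatedPredict
#' @param seed Integer seed.
#' @return List of class \code{modelBundle}.
#' @export
trainFullModel <- function(features, target, confounds, familyId,
                           control = predictControl(), seed = 1) {
  X <- as.matrix(features)
  C <- as.matrix(confounds)
  dec <- fitDeconfounder(target, X, C)
  tr <- applyDeconfounder(dec, C, target = target, features = X)
  tune <- tuneHyperparameters(tr$features, tr$target, grid = control$grid,
                              familyId = familyId,
                              innerFolds = control$innerFolds, seed = seed,
                              lr = control$lr, dropout = control$dropout,
                              maxEpochs = control$maxEpochs,
                              patience = control$patience)
  model <- mlpTrain(tr$features, tr$target, hidden = tune$hidden,
                    valFraction = control$valFraction, familyId = familyId,
                    lr = control$lr, dropout = control$dropout,
                    maxEpochs = control$maxEpochs,
                    patience = control$patience, seed = seed + 7L)
  structure(list(deconfounder = dec, model = model, hidden = tune$hidden),
            class = "modelBundle")
}

#' Apply trained models to an external cohort
#'
#' Applies a training cohort's deconfounder and predictor to a second
#' cohort without any refitting (lockbox validation / external
#' replication). Requires identical edge convention and feature columns.
#'
#' @param bundle A \code{modelBundle} from [trainFullModel()].
#' @param features,target,confounds External-cohort data.
#' @return A [PredictionResult-class] with a single repetition.
#' @export
transferPredict <- function(bundle, features, target, confounds) {
  stopifnot(inherits(bundle, "modelBundle"))
  te <- applyDeconfounder(bundle$deconfounder, as.matrix(confounds),
                          target = target, features = as.matrix(features))
  pred <- predict(bundle$model, te$features)
  m <- performanceMetrics(te$target, pred)
  PredictionResult(
    data.frame(subject = seq_along(target), repetition = 1L, fold = 1L,
               observed = te$target, predicted = pred),
    data.frame(repetition = 1, r = m["r"], mse = m["mse"],
               rmse = m["rmse"], mae = m["mae"], row.names = NULL),
    info = list(transfer = TRUE, hidden = bundle$hidden))
}

#' Correlation between two per-selection performance patterns
#'
#' Used to compare main-sample and lockbox/external performance vectors
#' over a common set of selections.
#'
#' @param rA,rB Numeric performance vectors (paired over selections).
#' @return Pearson correlation.
#' @export
performancePatternCor <- function(rA, rB) {
  stopifnot(length(rA) == length(rB))
  stats::cor(rA, rB)
}
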
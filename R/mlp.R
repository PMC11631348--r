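#' Train a feedforward ReLU network for score regression
#'
#' A small dense multilayer perceptron: 1-3 hidden layers of rectified
#' linear units, linear scalar output, mean-squared-error loss, dropout on
#' the hidden activations, trained by (full-batch) gradient descent at
#' learning rate 0.01. Early stopping monitors the loss on a held-out
#' validation subset: training stops when the validation loss has not
#' improved on its best value within the last \code{patience} epochs, or
#' at \code{maxEpochs}; the weights of the best validation epoch are
#' restored. The training log records the stop epoch and reason.
#'
#' @param X Numeric feature matrix (subjects x features), typically
#'   deconfounded and standardized.
#' @param y Numeric target.
#' @param hidden Integer vector of hidden-layer widths (e.g. \code{c(50)}
#'   or \code{c(100, 100, 100)}).
#' @param valIdx Logical or integer index of validation subjects used for
#'   early stopping; if NULL a seeded random \code{valFraction} split is
#'   drawn (family-aware if \code{familyId} is given).
#' @param valFraction Validation fraction when \code{valIdx} is NULL.
#' @param familyId Optional family ids for a family-aware validation
#'   split.
#' @param lr Learning rate.
#' @param dropout Dropout probability on hidden activations.
#' @param maxEpochs Maximum number of training epochs.
#' @param patience Early-stopping patience (epochs without a new best
#'   validation loss).
#' @param seed Integer seed (weight initialization, dropout masks,
#'   validation split).
#' @return List of class \code{mlpModel}: weights \code{W}, biases
#'   \code{b}, \code{hidden}, and \code{log} (epochs, bestEpoch,
#'   stopReason, train/validation loss at the best epoch).
#' @export
mlpTrain <- function(X, y, hidden = c(10), valIdx = NULL, valFraction = 0.2,
                     familyId = NULL, lr = 0.01, dropout = 0.25,
                     maxEpochs = 20000, patience = 100, seed = 1) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("features and target must be finite")
  n <- nrow(X)
  stopifnot(length(y) == n, n >= 5)
  .withSeed(seed, {
  if (is.null(valIdx)) {
    valIdx <- if (is.null(familyId))
      seq_len(n) %in% sample.int(n, max(2L, round(valFraction * n)))
    else validationSplit(familyId, valFraction,
                         seed = sample.int(.Machine$integer.max, 1))
  }
  if (is.numeric(valIdx)) valIdx <- seq_len(n) %in% valIdx
  if (sum(valIdx) < 2 || sum(!valIdx) < 3)
    stop("validation split leaves too few subjects")
  Xtr <- X[!valIdx, , drop = FALSE]; ytr <- y[!valIdx]
  Xva <- X[valIdx, , drop = FALSE]; yva <- y[valIdx]

  sizes <- c(ncol(X), hidden, 1L)
  nLayers <- length(sizes) - 1L
  W <- vector("list", nLayers)
  b <- vector("list", nLayers)
  for (l in seq_len(nLayers)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L]) *
                       sqrt(2 / sizes[l]), sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }

  forward <- function(Xin, Wl, bl, train = FALSE) {
    A <- vector("list", nLayers + 1L)
    A[[1L]] <- Xin
    masks <- vector("list", nLayers)
    for (l in seq_len(nLayers)) {
      Z <- sweep(A[[l]] %*% Wl[[l]], 2, bl[[l]], "+")
      if (l < nLayers) {
        Act <- pmax(Z, 0)
        if (train && dropout > 0) {
          m <- matrix(stats::runif(length(Act)) >= dropout, nrow(Act))
          Act <- Act * m / (1 - dropout)
          masks[[l]] <- m
        }
        A[[l + 1L]] <- Act
      } else A[[l + 1L]] <- Z
    }
    list(A = A, masks = masks)
  }

  ntr <- nrow(Xtr)
  best <- list(loss = Inf, W = W, b = b, epoch = 0L)
  stopReason <- "max epochs reached"
  epoch <- 0L
  while (epoch < maxEpochs) {
    epoch <- epoch + 1L
    fw <- forward(Xtr, W, b, train = TRUE)
    yhat <- drop(fw$A[[nLayers + 1L]])
    if (!all(is.finite(yhat)))
      stop("training diverged (non-finite loss) at epoch ", epoch)
    delta <- matrix(2 * (yhat - ytr) / ntr, ncol = 1)
    for (l in nLayers:1) {
      gW <- crossprod(fw$A[[l]], delta)
      gB <- colSums(delta)
      if (l > 1L) {
        delta <- delta %*% t(W[[l]])
        act <- fw$A[[l]]
        delta <- delta * (act > 0)
        if (!is.null(fw$masks[[l - 1L]]))
          delta <- delta * fw$masks[[l - 1L]] / (1 - dropout)
      }
      W[[l]] <- W[[l]] - lr * gW
      b[[l]] <- b[[l]] - lr * gB
    }
    vhat <- drop(forward(Xva, W, b)$A[[nLayers + 1L]])
    vloss <- mean((vhat - yva)^2)
    if (vloss < best$loss - 1e-12) {
      best <- list(loss = vloss, W = W, b = b, epoch = epoch)
    } else if (epoch - best$epoch >= patience) {
      stopReason <- "validation loss plateau (early stop)"
      break
    }
  }
  model <- list(W = best$W, b = best$b, hidden = as.integer(hidden),
                dropout = dropout,
                log = list(epochs = epoch, bestEpoch = best$epoch,
                           stopReason = stopReason,
                           bestValLoss = best$loss))
  class(model) <- "mlpModel"
  model
  })
}

#' Predict from a trained MLP
#'
#' Dropout is inactive at prediction time.
#'
#' @param object An \code{mlpModel}.
#' @param newdata Feature matrix.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.mlpModel <- function(object, newdata, ...) {
  A <- as.matrix(newdata)
  nLayers <- length(object$W)
  for (l in seq_len(nLayers)) {
    A <- sweep(A %*% object$W[[l]], 2, object$b[[l]], "+")
    if (l < nLayers) A <- pmax(A, 0)
  }
  drop(A)
}

#' Count of trainable parameters of an architecture
#' @param nFeatures Input dimension.
#' @param hidden Hidden-layer widths.
#' @return Integer parameter count.
#' @export
mlpParameterCount <- function(nFeatures, hidden) {
  sizes <- c(nFeatures, hidden, 1L)
  sum(sizes[-length(sizes)] * sizes[-1L] + sizes[-1L])
}

#' Architecture grid used for hyperparameter search
#'
#' All combinations of 1-3 hidden layers and 10/50/100 units per layer
#' (widths equal across layers).
#'
#' @param layers Hidden-layer counts.
#' @param widths Units per hidden layer.
#' @return List of hidden-width vectors.
#' @export
defaultArchitectureGrid <- function(layers = 1:3, widths = c(10, 50, 100)) {
  grid <- list()
  for (l in layers) for (w in widths)
    grid[[length(grid) + 1L]] <- rep(as.integer(w), l)
  grid
}

#' Choose an architecture by inner cross-validation
#'
#' Evaluates every architecture in the grid with an inner k-fold
#' cross-validation (family-aware folds when family ids are given; 30\%
#' of each inner training fold held out for early stopping) and returns
#' the architecture with the smallest mean inner validation MSE; ties are
#' broken towards the smallest parameter count.
#'
#' @param X,y Training features and target.
#' @param grid List of hidden-width vectors (see
#'   [defaultArchitectureGrid()]).
#' @param familyId Optional family ids.
#' @param innerFolds Number of inner folds (default 3).
#' @param seed Integer seed.
#' @param ... Passed to [mlpTrain()] (e.g. \code{maxEpochs},
#'   \code{patience}).
#' @return List: \code{hidden} (chosen architecture), \code{innerLoss}
#'   (mean validation MSE per grid entry).
#' @export
tuneHyperparameters <- function(X, y, grid = defaultArchitectureGrid(),
                                familyId = NULL, innerFolds = 3, seed = 1,
                                ...) {
  if (!length(grid)) stop("empty architecture grid")
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(grid) == 1L)
    return(list(hidden = grid[[1L]], innerLoss = NA_real_))
  if (n < innerFolds * 4)
    stop("inner folds too small for hyperparameter search")
  fam <- if (is.null(familyId)) as.character(seq_len(n)) else familyId
  folds <- makeFolds(fam, y, nFolds = innerFolds, seed = seed)$fold
  losses <- vapply(seq_along(grid), function(gi) {
    fl <- vapply(seq_len(innerFolds), function(f) {
      tr <- folds != f
      m <- mlpTrain(X[tr, , drop = FALSE], y[tr], hidden = grid[[gi]],
                    valFraction = 0.3, familyId = fam[tr],
                    seed = seed + 1000L * gi + f, ...)
      mean((predict(m, X[!tr, , drop = FALSE]) - y[!tr])^2)
    }, numeric(1))
    mean(fl)
  }, numeric(1))
  pars <- vapply(grid, function(h) mlpParameterCount(ncol(X), h),
                 numeric(1))
  best <- order(losses, pars)[1L]
  list(hidden = grid[[best]], innerLoss = losses)
}
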
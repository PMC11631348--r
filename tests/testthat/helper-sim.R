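# shared fixtures built in code

confoundMatrix <- function(ch) {
  as.matrix(ch[, c("age", "sex", "handedness", "mean_fd", "spike_prop")])
}

# desk-scale training control: single small architecture, shortened
# optimization budget (the vignette documents the problem sizes used)
quickControl <- function(hidden = c(10), maxEpochs = 1500, patience = 40) {
  predictControl(grid = list(hidden), maxEpochs = maxEpochs,
                 patience = patience)
}

# rank-based AUC of planted-edge recovery: probability that a planted
# edge outranks a non-planted one
aucOf <- function(ranking, planted) {
  nE <- length(ranking)
  pos <- match(planted, ranking)
  neg <- match(setdiff(seq_len(nE), planted), ranking)
  mean(outer(pos, neg, "<"))
}

# small study with a single task state and distributed planted signal
smallStudy <- function(seed, nNodes = 21, nSubjects = 300, nRelevant = 20,
                       blockSize = 5, effectRange = c(0.25, 0.4),
                       redundancyNoise = 0.2, states = c(task = 1)) {
  at <- syntheticAtlas(nNodes, seed = seed)
  simulateStudy(cohortConfig(nSubjects = nSubjects),
                connectomeConfig(states = states, nRelevant = nRelevant,
                                 blockSize = blockSize,
                                 redundancyNoise = redundancyNoise,
                                 effectRange = effectRange),
                at, seed = 100 + seed, motionExclusion = FALSE)
}

# deconfounded whole-brain features + target for one state
deconfounded <- function(cset, state = "task", target = NULL) {
  ch <- cohort(cset)
  if (is.null(target)) target <- groundTruth(cset)$true_g
  X <- selectionFeatures(cset, state)
  dec <- fitDeconfounder(target, X, confoundMatrix(ch))
  d <- applyDeconfounder(dec, confoundMatrix(ch), target = target,
                         features = X)
  list(X = d$features, y = d$target, familyId = ch$family_id)
}

# fast linear cross-validated prediction runner built from package
# pieces (deconfounder + OLS); used where permutation-test calibration,
# not the MLP, is under test
linearCvRunner <- function(X, C, familyId, nFolds = 5, foldSeed = 1) {
  force(X); force(C)
  function(y) {
    folds <- makeFolds(familyId, y, nFolds = nFolds, seed = foldSeed)$fold
    obs <- pred <- numeric(length(y))
    for (f in seq_len(nFolds)) {
      tr <- folds != f
      dec <- fitDeconfounder(y[tr], X[tr, , drop = FALSE],
                             C[tr, , drop = FALSE])
      dtr <- applyDeconfounder(dec, C[tr, , drop = FALSE],
                               target = y[tr],
                               features = X[tr, , drop = FALSE])
      beta <- qr.coef(qr(cbind(1, dtr$features)), dtr$target)
      dte <- applyDeconfounder(dec, C[!tr, , drop = FALSE],
                               target = y[!tr],
                               features = X[!tr, , drop = FALSE])
      obs[!tr] <- dte$target
      pred[!tr] <- drop(cbind(1, dte$features) %*% beta)
    }
    stats::cor(obs, pred)
  }
}
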
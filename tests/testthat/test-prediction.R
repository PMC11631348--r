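test_that("performance metrics match hand computation", {
  y <- c(0, 1, 2)
  yhat <- c(0, 0, 3)
  m <- performanceMetrics(y, yhat)
  expect_equal(unname(m["r"]), 0.866, tolerance = 5e-4)
  expect_equal(unname(m["mae"]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(m["mse"]), (0 + 0.25 + 0.25) / 3, tolerance = 1e-12)
  expect_equal(performanceMetrics(y, y),
               c(r = 1, mse = 0, rmse = 0, mae = 0))
  expect_equal(unname(performanceMetrics(y, -y)["r"]), -1)
  expect_error(performanceMetrics(rep(1, 5), rnorm(5)), "constant")
})

test_that("every subject is predicted exactly once per repetition", {
  cset <- smallStudy(2, nNodes = 10, nSubjects = 120, nRelevant = 10,
                     blockSize = 5)
  ch <- cohort(cset)
  X <- selectionFeatures(cset, "task")
  pr <- crossValidatedPredict(X, groundTruth(cset)$true_g,
                              confoundMatrix(ch), ch$family_id,
                              foldSeeds = 1:2,
                              control = quickControl(maxEpochs = 300,
                                                     patience = 20))
  pp <- predictions(pr)
  expect_equal(nrow(pp), 2 * nrow(ch))
  expect_true(all(table(pp$subject, pp$repetition) == 1))
  expect_equal(nrow(metrics(pr)), 2)
  # determinism: identical call, identical result
  pr2 <- crossValidatedPredict(X, groundTruth(cset)$true_g,
                               confoundMatrix(ch), ch$family_id,
                               foldSeeds = 1:2,
                               control = quickControl(maxEpochs = 300,
                                                      patience = 20))
  expect_identical(predictions(pr), predictions(pr2))
})

test_that("planted whole-brain signal beats a small random selection", {
  cset <- smallStudy(3, nNodes = 21, nSubjects = 280, nRelevant = 40,
                     blockSize = 5, effectRange = c(0.15, 0.25))
  ch <- cohort(cset)
  sc <- scoreIntelligence(ch)
  ctrl <- quickControl()
  rWhole <- meanPerformance(crossValidatedPredict(
    selectionFeatures(cset, "task"), sc$g, confoundMatrix(ch),
    ch$family_id, foldSeeds = 1:2, control = ctrl))
  at <- atlas(cset)
  rRand <- mean(sapply(1:2, function(s) meanPerformance(
    crossValidatedPredict(
      selectionFeatures(cset, "task", randomEdgeSelection(20, at, s)),
      sc$g, confoundMatrix(ch), ch$family_id, foldSeeds = 1:2,
      control = ctrl))))
  expect_gt(rWhole, rRand)
  expect_gt(rWhole, 0.2)
})

test_that("a zero-signal cohort predicts at chance", {
  rs <- sapply(1:3, function(s) {
    cset <- smallStudy(10 + s, nNodes = 10, nSubjects = 150,
                       nRelevant = 5, blockSize = 5,
                       effectRange = c(0, 0))
    ch <- cohort(cset)
    meanPerformance(crossValidatedPredict(
      selectionFeatures(cset, "task"), groundTruth(cset)$true_g,
      confoundMatrix(ch), ch$family_id,
      control = quickControl(maxEpochs = 400, patience = 25)))
  })
  expect_lt(abs(mean(rs)), 0.12)
})

test_that("mean performance is monotone in planted effect size", {
  rs <- sapply(c(0, 0.12, 0.3), function(eff) {
    cset <- smallStudy(7, nNodes = 15, nSubjects = 220, nRelevant = 20,
                       blockSize = 5,
                       effectRange = c(eff, eff + 1e-6))
    ch <- cohort(cset)
    meanPerformance(crossValidatedPredict(
      selectionFeatures(cset, "task"), groundTruth(cset)$true_g,
      confoundMatrix(ch), ch$family_id, foldSeeds = 1:2,
      control = quickControl(maxEpochs = 600, patience = 30)))
  })
  expect_true(all(diff(rs) > 0))
})

test_that("transfer applies training-fitted models without refitting", {
  cset <- smallStudy(5, nNodes = 12, nSubjects = 200, nRelevant = 15,
                     blockSize = 5, effectRange = c(0.2, 0.3))
  ch <- cohort(cset)
  sc <- scoreIntelligence(ch)
  X <- selectionFeatures(cset, "task")
  C <- confoundMatrix(ch)
  bundle <- trainFullModel(X, sc$g, C, ch$family_id,
                           control = quickControl(), seed = 2)
  # B = A: identical to in-sample application
  tp <- transferPredict(bundle, X, sc$g, C)
  dtr <- applyDeconfounder(bundle$deconfounder, C, target = sc$g,
                           features = X)
  expect_equal(predictions(tp)$predicted,
               unname(predict(bundle$model, dtr$features)))
  expect_gt(meanPerformance(tp), 0.3)   # in-sample, strong signal
  # permuted target: transfer performance collapses to chance
  set.seed(9)
  tpNull <- transferPredict(bundle, X, sample(sc$g), C)
  expect_lt(abs(meanPerformance(tpNull)), 0.2)
})

test_that("per-selection performance patterns agree between main and lockbox", {
  cset <- smallStudy(21, nNodes = 15, nSubjects = 430, nRelevant = 30,
                     blockSize = 5, effectRange = c(0.2, 0.3))
  ch <- cohort(cset)
  sc <- scoreIntelligence(ch)
  sp <- splitLockbox(ch, fraction = 0.3, seed = 2)
  mainIdx <- match(sp$main$id, ch$id)
  lockIdx <- match(sp$lockbox$id, ch$id)
  at <- atlas(cset)
  sels <- list(whole = wholeBrainSelection(at),
               re30 = randomEdgeSelection(30, at, 4),
               re10 = randomEdgeSelection(10, at, 5),
               rn5 = randomNodeSelection(5, at, 6))
  ctrl <- quickControl(maxEpochs = 800, patience = 30)
  C <- confoundMatrix(ch)
  rMain <- numeric(length(sels))
  rLock <- numeric(length(sels))
  for (k in seq_along(sels)) {
    Xall <- selectionFeatures(cset, "task", sels[[k]])
    rMain[k] <- meanPerformance(crossValidatedPredict(
      Xall[mainIdx, , drop = FALSE], sc$g[mainIdx],
      C[mainIdx, , drop = FALSE], ch$family_id[mainIdx], control = ctrl))
    b <- trainFullModel(Xall[mainIdx, , drop = FALSE], sc$g[mainIdx],
                        C[mainIdx, , drop = FALSE], ch$family_id[mainIdx],
                        control = ctrl, seed = 3)
    rLock[k] <- meanPerformance(transferPredict(
      b, Xall[lockIdx, , drop = FALSE], sc$g[lockIdx],
      C[lockIdx, , drop = FALSE]))
  }
  expect_gt(performancePatternCor(rMain, rLock), 0.5)
})
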
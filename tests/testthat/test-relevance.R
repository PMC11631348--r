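barebonesModel <- function(W, b = NULL) {
  if (is.null(b)) b <- lapply(W, function(w) rep(0, ncol(w)))
  structure(list(W = W, b = b,
                 hidden = if (length(W) > 1)
                   vapply(W[-length(W)], ncol, integer(1)) else integer(0)),
            class = "mlpModel")
}

test_that("LRP is analytic for a single linear layer", {
  m <- barebonesModel(list(matrix(c(2, -1), 2, 1)))
  R <- lrpAttribute(m, matrix(c(3, 4), 1))
  expect_equal(as.numeric(R), c(6, -4), tolerance = 1e-4)
  expect_equal(sum(R), 2, tolerance = 1e-4)
})

test_that("relevance is conserved on bias-free ReLU networks", {
  set.seed(1)
  for (rep_ in 1:5) {
    W <- list(matrix(rnorm(20 * 8), 20, 8), matrix(rnorm(8 * 4), 8, 4),
              matrix(rnorm(4), 4, 1))
    m <- barebonesModel(W)
    X <- matrix(rnorm(40 * 20), 40, 20)
    out <- predict(m, X)
    R <- lrpAttribute(m, X, epsilon = 1e-6)
    relErr <- abs(rowSums(R) - out) / pmax(abs(out), 1e-9)
    expect_lt(max(relErr), 1e-3)
  }
})

test_that("LRP feature ranking agrees with occlusion", {
  set.seed(2)
  sp <- sapply(1:20, function(k) {
    W <- list(matrix(rnorm(10 * 6), 10, 6), matrix(rnorm(6), 6, 1))
    m <- barebonesModel(W)
    X <- matrix(rnorm(200 * 10), 200, 10)
    rel <- colMeans(abs(lrpAttribute(m, X)))
    occ <- vapply(1:10, function(j) {
      X0 <- X
      X0[, j] <- 0
      mean((predict(m, X0) - predict(m, X))^2)
    }, numeric(1))
    cor(rank(rel), rank(occ))
  })
  expect_gt(mean(sp), 0.9)
})

test_that("a single-round schedule reduces stepwise LRP to plain LRP", {
  set.seed(3)
  n <- 150
  X <- matrix(rnorm(n * 12), n, 12)
  y <- X[, 1] - 0.8 * X[, 2] + 0.5 * rnorm(n)
  sw <- stepwiseLRP(X, y, schedule = ncol(X), hidden = c(8), seed = 4,
                    maxEpochs = 600, patience = 40)
  m <- mlpTrain(X, y, hidden = c(8), seed = 4 + 1L, maxEpochs = 600,
                patience = 40)
  rel <- colMeans(lrpAttribute(m, X))
  expect_identical(ranking(sw),
                   order(abs(rel), -seq_along(rel), decreasing = TRUE))
  # and the ordering is byte-reproducible
  sw2 <- stepwiseLRP(X, y, schedule = ncol(X), hidden = c(8), seed = 4,
                     maxEpochs = 600, patience = 40)
  expect_identical(ranking(sw), ranking(sw2))
})

test_that("stepwise LRP recovers planted edges; chance level on null data", {
  aucs <- sapply(1:3, function(s) {
    cset <- smallStudy(s, nSubjects = 250)
    d <- deconfounded(cset)
    sw <- stepwiseLRP(d$X, d$y, schedule = rep(10, 5), hidden = c(10),
                      familyId = d$familyId, seed = s, maxEpochs = 1200,
                      patience = 40)
    aucOf(ranking(sw), groundTruth(cset)$relevant_edges)
  })
  expect_gt(mean(aucs), 0.9)
  aucsNull <- sapply(1:4, function(s) {
    cset <- smallStudy(30 + s, nSubjects = 200, effectRange = c(0, 0))
    d <- deconfounded(cset)
    sw <- stepwiseLRP(d$X, d$y, schedule = rep(20, 3), hidden = c(10),
                      familyId = d$familyId, seed = s, maxEpochs = 400,
                      patience = 25)
    aucOf(ranking(sw), groundTruth(cset)$relevant_edges)
  })
  expect_lt(abs(mean(aucsNull) - 0.5), 0.15)
})

test_that("relevance aggregation averages and is order-invariant", {
  m1 <- RelevanceMap(relevance = c(1, -2, 3))
  m2 <- RelevanceMap(relevance = c(-1, 2, -3))
  agg <- aggregateRelevance(list(m1, m2))
  expect_equal(relevance(agg), c(0, 0, 0))
  # identical maps aggregate to themselves
  aggSame <- aggregateRelevance(list(m1, m1))
  expect_equal(relevance(aggSame), relevance(m1))
  expect_identical(ranking(aggSame), ranking(m1))
  # permutation invariance in run order
  m3 <- RelevanceMap(relevance = c(5, 1, 2))
  expect_equal(aggregateRelevance(list(m1, m2, m3)),
               aggregateRelevance(list(m3, m1, m2)))
  expect_error(aggregateRelevance(list(m1, RelevanceMap(relevance = 1:4))),
               "mismatched")
})

test_that("stepwise rankings aggregate by mean rank", {
  r1 <- RelevanceMap(relevance = c(0.9, 0.5, 0.1, 0.2),
                     ranking = c(1L, 2L, 4L, 3L))
  r2 <- RelevanceMap(relevance = c(0.8, 0.6, 0.3, 0.1),
                     ranking = c(2L, 1L, 3L, 4L))
  agg <- aggregateRelevance(list(r1, r2))
  # mean ranks: e1 = 1.5, e2 = 1.5, e3 = 3.5, e4 = 3.5; index tie-break
  expect_identical(ranking(agg), c(1L, 2L, 3L, 4L))
})

test_that("overlap percentage counts shared edges", {
  expect_equal(overlapFraction(1:4, 1:4), 100)
  expect_equal(overlapFraction(1:4, 5:8), 0)
  expect_equal(overlapFraction(1:4, c(3, 4, 9, 10)), 50)
  expect_error(overlapFraction(1:4, 1:5), "equal size")
})
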
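test_that("permutation p-values follow the plus-one formula", {
  # runner: correlation of the target with a fixed signal-bearing vector
  set.seed(1)
  sig <- rnorm(60)
  y <- sig + 0.3 * rnorm(60)
  runner <- function(yy) cor(yy, sig)
  pt <- permutationTestPerformance(runner, y, m = 100, seed = 2)
  expect_equal(pt$p, 1 / 101, tolerance = 1e-12)  # observed beats all nulls
  expect_length(pt$null, 100)
  expect_gt(pt$p, 0)                               # never exactly zero
  # observed equal to the null median: p about 0.5
  yNull <- rnorm(60)
  ptNull <- permutationTestPerformance(runner, yNull, m = 200, seed = 3,
                                       observed = median(
                                         sapply(1:200, function(i)
                                           cor(sample(yNull), sig))))
  expect_lt(abs(ptNull$p - 0.5), 0.1)
  expect_error(permutationTestPerformance(runner, y, m = 0), "at least 1")
})

test_that("identical configurations give a null model difference", {
  set.seed(2)
  sig <- rnorm(50)
  y <- sig + rnorm(50)
  runner <- function(yy) cor(yy, sig)
  md <- modelDifferenceTest(runner, runner, y, m = 50, seed = 4)
  expect_equal(md$observed, 0)
  expect_equal(md$p, 1)
})

test_that("the model-difference test detects a planted contrast", {
  ps <- sapply(1:6, function(s) {
    set.seed(s)
    n <- 80
    sig <- rnorm(n)
    y <- sig + 0.6 * rnorm(n)
    weak <- 0.15 * sig + rnorm(n)
    runnerA <- function(yy) cor(yy, sig)
    runnerB <- function(yy) cor(yy, weak)
    modelDifferenceTest(runnerA, runnerB, y, m = 99, seed = 10 + s,
                        alternative = "greater")$p
  })
  expect_gt(mean(ps < 0.05), 0.5)
})

test_that("both permutation tests are calibrated under the null", {
  cset <- smallStudy(40, nNodes = 6, nSubjects = 60, nRelevant = 3,
                     blockSize = 3, effectRange = c(0, 0))
  ch <- cohort(cset)
  X <- selectionFeatures(cset, "task")[, 1:5]
  C <- confoundMatrix(ch)
  runner <- linearCvRunner(X, C, ch$family_id)
  runner2 <- linearCvRunner(X[, 1:3, drop = FALSE], C, ch$family_id)
  nRep <- 100
  m <- 19
  set.seed(5)
  seeds <- sample.int(1e6, 2 * nRep)
  rejPerf <- sapply(seq_len(nRep), function(i) {
    y <- rnorm(nrow(X))
    permutationTestPerformance(runner, y, m = m, seed = seeds[i])$p <= 0.05
  })
  # two-sided doubling needs m = 39 for p = 0.05 to be attainable
  rejDiff <- sapply(seq_len(nRep), function(i) {
    y <- rnorm(nrow(X))
    modelDifferenceTest(runner, runner2, y, m = 39,
                        seed = seeds[nRep + i])$p <= 0.05
  })
  expect_lt(abs(mean(rejPerf) - 0.05), 0.05)
  expect_lt(abs(mean(rejDiff) - 0.05), 0.05)
})

test_that("paired t-tests match the textbook formula", {
  a <- c(0.31, 0.29, 0.33, 0.27, 0.35, 0.30, 0.28, 0.34, 0.32, 0.26)
  b <- c(0.27, 0.26, 0.30, 0.28, 0.30, 0.27, 0.25, 0.31, 0.33, 0.24)
  d <- a - b
  tHand <- mean(d) / (sd(d) / sqrt(length(d)))
  res <- pairedTTest(a, b)
  expect_equal(res$t, tHand, tolerance = 1e-12)
  expect_equal(res$df, 9)
  expect_equal(res$p, 2 * pt(-abs(tHand), 9), tolerance = 1e-12)
  # identical vectors
  same <- pairedTTest(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # constant nonzero differences are degenerate
  degen <- pairedTTest(c(1, 2, 3, 4), c(0, 1, 2, 3))
  expect_true(degen$degenerate)
  expect_identical(degen$t, Inf)
})

test_that("BH correction flags the step-up set", {
  res <- fdrCorrect(c(0.01, 0.02, 0.03, 0.5))
  expect_identical(res$significant, c(TRUE, TRUE, TRUE, FALSE))
  expect_true(fdrCorrect(0.01)$significant)
  expect_false(any(fdrCorrect(rep(1, 5))$significant))
  # flags monotone in p
  p <- sort(runif(20))
  fl <- fdrCorrect(p)$significant
  expect_true(all(diff(as.integer(fl)) <= 0))
  expect_error(fdrCorrect(numeric(0)), "empty")
  expect_error(fdrCorrect(c(0.5, 0)), "in \\(0, 1\\]")
})

test_that("graph metrics match closed forms and a direct-summation oracle", {
  # node with all edges inside its module: PC = 0
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1
  W[1, 3] <- W[3, 1] <- 0.5
  memb <- c("A", "A", "A", "B")
  expect_equal(participationCoefficient(W, memb)[1], 0)
  # strength spread evenly across 7 modules: PC = 6/7
  W7 <- matrix(0, 8, 8)
  W7[1, 2:8] <- W7[2:8, 1] <- 1
  memb7 <- c("x", letters[1:7])
  expect_equal(participationCoefficient(W7, memb7)[1], 6 / 7)
  # node at its module's mean within-degree has z = 0
  z <- withinModuleDegreeZ(W, memb)
  kappa <- rowSums(W[1:3, 1:3])
  expect_equal(z[1:3], unname((kappa - mean(kappa)) / sd(kappa)))
  expect_equal(withinModuleDegreeZ(W7, memb7)[4], 0)  # SD-0 fallback
  # oracle: naive double loops on random weighted modular graphs
  set.seed(7)
  for (rep_ in 1:3) {
    n <- 20
    A <- matrix(runif(n * n), n)
    A <- (A + t(A)) / 2
    diag(A) <- 0
    mm <- sample(c("m1", "m2", "m3"), n, replace = TRUE)
    pcO <- sapply(1:n, function(i) {
      k <- sum(A[i, ])
      1 - sum(sapply(unique(mm), function(s)
        (sum(A[i, mm == s]) / k)^2))
    })
    zO <- sapply(1:n, function(i) {
      idx <- which(mm == mm[i])
      kap <- sapply(idx, function(v) sum(A[v, idx]))
      (sum(A[i, idx]) - mean(kap)) / sd(kap)
    })
    expect_equal(participationCoefficient(A, mm), pcO, tolerance = 1e-12)
    expect_equal(withinModuleDegreeZ(A, mm), zO, tolerance = 1e-12)
  }
})

test_that("relevant-vs-random comparison is calibrated and detects contrast", {
  set.seed(8)
  nE <- 300
  icc <- runif(nE)
  # a uniformly random selection: p should not be systematically small
  ps <- sapply(1:40, function(s) {
    set.seed(100 + s)
    idx <- sample.int(nE, 30)
    relevantVsRandomEdgeComparison(idx, list(icc = icc), nE, nPerm = 99,
                                   seed = s)$p
  })
  expect_lt(abs(mean(ps <= 0.05) - 0.05), 0.08)
  # selection built from high-ICC edges is detected
  idxHi <- order(icc, decreasing = TRUE)[1:30]
  resHi <- relevantVsRandomEdgeComparison(idxHi, list(icc = icc), nE,
                                          nPerm = 999, seed = 9)
  expect_lt(resHi$p, 0.05)
  # statistic at the null median: p near 1
  med <- median(icc)
  idxMed <- order(abs(icc - med))[1:30]
  resMed <- relevantVsRandomEdgeComparison(idxMed, list(icc = icc), nE,
                                           nPerm = 199, seed = 10)
  expect_gt(resMed$p, 0.5)
})

test_that("occurrence-weighted node statistics weight by endpoint counts", {
  nodeMetric <- c(1, 2, 3, 4)
  # edges (1,2) and (1,3) in a 4-node graph: node 1 occurs twice
  et <- edgeIndexTable(4)
  e12 <- which(et$i == 1 & et$j == 2)
  e13 <- which(et$i == 1 & et$j == 3)
  expect_equal(nodeOccurrenceStat(c(e12, e13), nodeMetric, 4),
               (2 * 1 + 2 + 3) / 4)
})
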